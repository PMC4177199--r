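test_that("descendants returns the transitive closure, excluding the query", {
  g <- mini_graph()
  mam <- find_by_name(g, "Mammalia")
  expect_setequal(descendants(g, mam),
                  c(find_by_name(g, "Rodentia"), find_by_name(g, "Primates"),
                    find_by_name(g, "Mus")))
  expect_length(descendants(g, find_by_name(g, "Mus")), 0)
  expect_error(descendants(g, "M:9999999"), "M:9999999")
})

test_that("descendants agrees with two independent oracles on random trees", {
  g <- random_tree(200, seed = 7)
  for (id in sample(term_ids(g), 12)) {
    expect_setequal(descendants(g, id), brute_descendants(g, id))
    expect_setequal(descendants(g, id), fixpoint_descendants(g, id))
  }
})

test_that("obsolete terms are excluded from descendants and subsumption", {
  g <- mini_graph()
  g$terms[["M:0000004"]]$is_obsolete <- TRUE
  g$terms[["M:0000004"]]$parent <- NA_character_
  expect_false("M:0000004" %in% descendants(g, "M:0000001"))
  # still queryable by id and name
  expect_identical(get_term(g, "M:0000004")$name, "Mus")
  expect_identical(find_by_name(g, "Mus"), "M:0000004")
})

test_that("is_subsumed_by is reflexive, antisymmetric, and follows parents", {
  g <- mini_graph()
  expect_true(is_subsumed_by(g, "M:0000004", "M:0000001"))
  expect_false(is_subsumed_by(g, "M:0000001", "M:0000004"))
  for (id in term_ids(g)) expect_true(is_subsumed_by(g, id, id))
  expect_error(is_subsumed_by(g, "M:0000001", "nope"), "nope")

  tr <- random_tree(120, seed = 11)
  ids <- sample(term_ids(tr), 15)
  for (x in ids) for (y in ids) {
    if (is_subsumed_by(tr, x, y) && is_subsumed_by(tr, y, x)) {
      expect_identical(x, y)
    }
  }
})

test_that("find_by_name supports rank and ancestor qualification", {
  g <- mini_graph()
  expect_identical(find_by_name(g, "Mus"), "M:0000004")
  expect_length(find_by_name(g, "Nothingia"), 0)

  # homonym: same genus name under two families
  vocab <- default_rank_vocabulary()
  h <- taxonomy_graph()
  h <- add_term(h, taxon_term("H:0000001", "Root"))
  h <- add_term(h, annotate_rank(
    taxon_term("H:0000002", "FamA", parent = "H:0000001"), "family", vocab))
  h <- add_term(h, annotate_rank(
    taxon_term("H:0000003", "FamB", parent = "H:0000001"), "family", vocab))
  h <- add_term(h, annotate_rank(
    taxon_term("H:0000004", "Xus", parent = "H:0000002"), "genus", vocab))
  h <- add_term(h, annotate_rank(
    taxon_term("H:0000005", "Xus", parent = "H:0000003"), "genus", vocab))
  expect_setequal(find_by_name(h, "Xus"), c("H:0000004", "H:0000005"))
  hit <- find_by_name(h, "Xus", within = "H:0000002")
  expect_identical(hit, "H:0000004")
  expect_true(is_subsumed_by(h, hit, "H:0000002"))
  expect_identical(find_by_name(h, "Xus", rank = rank_lookup(vocab, "genus"),
                                within = "H:0000003"), "H:0000005")
})

test_that("name normalization collapses whitespace but keeps case", {
  expect_identical(normalize_name("  Danio   rerio "), "Danio rerio")
  g <- mini_graph()
  expect_identical(find_by_name(g, " Mus  "), "M:0000004")
  expect_length(find_by_name(g, "mus"), 0)
})

test_that("name index is consistent and rebuilds identically", {
  g <- decorate_graph(random_tree(150, seed = 3), seed = 4)
  idx <- name_index(g)
  for (id in sample(term_ids(g), 20)) {
    expect_true(id %in% idx[[normalize_name(g$terms[[id]]$name)]])
  }
  # rebuilding from a re-ordered term map yields the same index
  g2 <- g
  g2$terms <- g2$terms[rev(names(g2$terms))]
  idx2 <- name_index(g2)
  expect_identical(idx[sort(names(idx))],
                   lapply(idx2[sort(names(idx))], identity))
})

test_that("validate reports cycles, orphans, obsolete parents, homonyms", {
  expect_length(validate_taxonomy(mini_graph()), 0)

  g <- mini_graph()
  g$terms[["M:0000001"]]$parent <- "M:0000004"  # Mammalia under Mus: cycle
  rep <- validate_taxonomy(g)
  codes <- vapply(rep, function(f) f$code, character(1))
  expect_true("CYCLE" %in% codes)
  cyc <- rep[[which(codes == "CYCLE")[1]]]
  expect_true(all(c("M:0000001", "M:0000004") %in% cyc$terms))

  g <- mini_graph()
  g$terms[["M:0000004"]]$parent <- "M:0000099"
  codes <- vapply(validate_taxonomy(g), function(f) f$code, character(1))
  expect_true("UNRESOLVED_PARENT" %in% codes)

  g <- mini_graph()
  g$terms[["M:0000004"]]$is_obsolete <- TRUE
  codes <- vapply(validate_taxonomy(g), function(f) f$code, character(1))
  expect_true("OBSOLETE_WITH_PARENT" %in% codes)

  g <- mini_graph()
  g <- add_term(g, taxon_term("M:0000005", "Mus", parent = "M:0000003"))
  codes <- vapply(validate_taxonomy(g), function(f) f$code, character(1))
  expect_true("DUPLICATE_NAME" %in% codes)
})

test_that("validate flags rank inversions against the rank order", {
  vocab <- default_rank_vocabulary()
  g <- taxonomy_graph()
  g <- add_term(g, annotate_rank(taxon_term("R:0000001", "Aus"), "genus",
                                 vocab))
  g <- add_term(g, annotate_rank(
    taxon_term("R:0000002", "Bidae", parent = "R:0000001"), "family",
    vocab))
  rep <- validate_taxonomy(g, vocab)
  codes <- vapply(rep, function(f) f$code, character(1))
  expect_identical(codes, "RANK_INVERSION")
  # the finding is consistent with rank_order: family is HIGHER than genus
  expect_identical(rank_order(vocab, rank_lookup(vocab, "family"),
                              rank_lookup(vocab, "genus")), "HIGHER")
  # the conventional direction is clean
  g2 <- taxonomy_graph()
  g2 <- add_term(g2, annotate_rank(taxon_term("R:0000001", "Bidae"),
                                   "family", vocab))
  g2 <- add_term(g2, annotate_rank(
    taxon_term("R:0000002", "Aus", parent = "R:0000001"), "genus", vocab))
  expect_length(validate_taxonomy(g2, vocab), 0)
})

test_that("validation reports serialize as JSON lines", {
  g <- mini_graph()
  g$terms[["M:0000004"]]$parent <- "M:0000099"
  rep <- validate_taxonomy(g)
  path <- tempfile(fileext = ".jsonl")
  write_validation_report(rep, path)
  lines <- readLines(path)
  expect_length(lines, length(rep))
  parsed <- jsonlite::fromJSON(lines[1])
  expect_named(parsed, c("code", "terms", "message"))
  expect_identical(parsed$code, "UNRESOLVED_PARENT")
})
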