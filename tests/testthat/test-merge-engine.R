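vocab <- default_rank_vocabulary()

ranked_term <- function(id, name, rank = "", parent = NA_character_, ...) {
  annotate_rank(taxon_term(id, name, parent = parent, ...), rank, vocab)
}

has_term_local <- function(g, id) !is.null(g$terms[[id]])

test_that("match_terms pairs unambiguous names and reports homonym clashes", {
  a <- add_term(taxonomy_graph(), taxon_term("A:0000001", "Solo"))
  b <- add_term(taxonomy_graph(), taxon_term("B:0000001", "Solo"))
  m <- match_terms(a, b)
  expect_identical(unname(m$map["B:0000001"]), "A:0000001")
  expect_identical(nrow(m$ambiguous), 0L)

  # a name only in the source is simply absent from the map
  b2 <- add_term(b, taxon_term("B:0000002", "Privata"))
  m2 <- match_terms(a, b2)
  expect_false("B:0000002" %in% names(m2$map))

  # homonym in the backbone, disambiguated by rank: verify against an
  # exhaustive enumeration of name+rank-compatible candidates
  bb <- taxonomy_graph()
  bb <- add_term(bb, taxon_term("A:0000001", "Root"))
  bb <- add_term(bb, ranked_term("A:0000002", "Xus", "genus", "A:0000001"))
  bb <- add_term(bb, ranked_term("A:0000003", "Xus", "subgenus",
                                 "A:0000002"))
  src <- add_term(taxonomy_graph(), ranked_term("S:0000001", "Xus", "genus"))
  m3 <- match_terms(bb, src)
  enum <- Filter(function(id) {
    t <- bb$terms[[id]]
    t$name == "Xus" && identical(t$rank, src$terms[["S:0000001"]]$rank)
  }, term_ids(bb))
  expect_identical(unname(m3$map["S:0000001"]), enum)

  # no rank to disambiguate by: omitted from the map, reported
  src2 <- add_term(taxonomy_graph(), taxon_term("S:0000001", "Xus"))
  m4 <- match_terms(bb, src2)
  expect_false("S:0000001" %in% names(m4$map))
  expect_identical(m4$ambiguous$name, "Xus")
})

test_that("match_terms disambiguates homonyms by shared ancestor name", {
  bb <- taxonomy_graph()
  bb <- add_term(bb, taxon_term("A:0000001", "Root"))
  bb <- add_term(bb, taxon_term("A:0000002", "FamA", parent = "A:0000001"))
  bb <- add_term(bb, taxon_term("A:0000003", "FamB", parent = "A:0000001"))
  bb <- add_term(bb, taxon_term("A:0000004", "Xus", parent = "A:0000002"))
  bb <- add_term(bb, taxon_term("A:0000005", "Xus", parent = "A:0000003"))
  src <- taxonomy_graph()
  src <- add_term(src, taxon_term("S:0000001", "FamB"))
  src <- add_term(src, taxon_term("S:0000002", "Xus", parent = "S:0000001"))
  m <- match_terms(bb, src)
  expect_identical(unname(m$map["S:0000002"]), "A:0000005")
})

test_that("merge_synonyms unions names and provenance, idempotently", {
  t1 <- taxon_term("A:0000001", "Rana catesbeiana",
                   synonyms = synonym_record("Bullfrog", "EXACT",
                                             "COMMONNAME", "x"),
                   xrefs = "NCBI:8")
  donor <- taxon_term("B:0000001", "Lithobates catesbeianus",
                      synonyms = rbind(
                        synonym_record("Rana catesbiana", "EXACT",
                                       "MISSPELLING", "y"),
                        synonym_record("American Bullfrog", "EXACT",
                                       "COMMONNAME", "y")),
                      xrefs = "AWEB:5", is_extinct = FALSE)
  out <- merge_synonyms(t1, donor)
  # two new synonyms carried, plus the differing primary name as EXACT
  expect_setequal(out$synonyms$name,
                  c("Bullfrog", "Rana catesbiana", "American Bullfrog",
                    "Lithobates catesbeianus"))
  expect_identical(
    out$synonyms$scope[out$synonyms$name == "Lithobates catesbeianus"],
    "EXACT")
  expect_setequal(out$xrefs, c("NCBI:8", "AWEB:5"))
  # merging a term with itself changes nothing
  expect_identical(merge_synonyms(out, out)$synonyms, out$synonyms)

  # scope conflicts resolve toward the pre-existing record
  t2 <- taxon_term("A:0000002", "Aus",
                   synonyms = synonym_record("Aussy", "RELATED",
                                             "TAXONOMIC", "x"))
  donor2 <- taxon_term("B:0000002", "Aus",
                       synonyms = synonym_record("Aussy", "EXACT",
                                                 "TAXONOMIC", "y"))
  expect_identical(merge_synonyms(t2, donor2)$synonyms$scope, "RELATED")
  # extinct flag is an OR
  donor3 <- taxon_term("B:0000003", "Aus", is_extinct = TRUE)
  expect_true(merge_synonyms(t2, donor3)$is_extinct)
})

coarse_backbone <- function() {
  g <- taxonomy_graph()
  g <- add_term(g, taxon_term("N:1", "Vertebrata", xrefs = "N:1"))
  g <- add_term(g, ranked_term("N:2", "Amphibia", "class", "N:1",
                               xrefs = "N:2"))
  g <- add_term(g, ranked_term("N:3", "Anura", "order", "N:2",
                               xrefs = "N:3"))
  g <- add_term(g, ranked_term("N:4", "Rana temporaria", "species", "N:3",
                               xrefs = "N:4"))
  g <- add_term(g, ranked_term("N:5", "Oldskoolia", "order", "N:2",
                               xrefs = "N:5"))
  g <- add_term(g, ranked_term("N:6", "Mammalia", "class", "N:1",
                               xrefs = "N:6"))
  g
}

rich_amphibia <- function() {
  s <- taxonomy_graph()
  s <- add_term(s, ranked_term("W:1", "Amphibia", "class", xrefs = "W:1"))
  s <- add_term(s, ranked_term("W:2", "Anura", "order", "W:1",
                               xrefs = "W:2"))
  s <- add_term(s, ranked_term("W:3", "Ranidae", "family", "W:2",
                               xrefs = "W:3"))
  s <- add_term(s, ranked_term("W:4", "Rana", "genus", "W:3",
                               xrefs = "W:4"))
  s <- add_term(s, ranked_term("W:5", "Rana temporaria", "species", "W:4",
                               xrefs = "W:5"))
  s <- add_term(s, ranked_term("W:6", "Caudata", "order", "W:1",
                               xrefs = "W:6"))
  s
}

test_that("graft_replace swaps the subtree, carries names, reports drops", {
  res <- graft_replace(coarse_backbone(), rich_amphibia(), "Amphibia")
  g <- res$graph
  # attachment keeps its backbone identity and location
  amp <- find_by_name(g, "Amphibia")
  expect_identical(amp, "N:2")
  expect_identical(get_term(g, amp)$parent, "N:1")
  expect_true("W:1" %in% get_term(g, amp)$xrefs)
  # the six source terms minus the root live under the attachment
  expect_setequal(descendants(g, amp), c("W:2", "W:3", "W:4", "W:5", "W:6"))
  expect_identical(res$report$terms_added, 5L)
  # removed coarse terms with a name match donate their xrefs
  expect_true("N:3" %in% get_term(g, "W:2")$xrefs)
  expect_true("N:4" %in% get_term(g, "W:5")$xrefs)
  # the unmatched coarse order is reported as dropped
  expect_identical(res$report$dropped, "Oldskoolia")
  expect_identical(res$report$carried, 2L)
})

test_that("graft_replace leaves everything outside the subtree untouched", {
  bb <- coarse_backbone()
  res <- graft_replace(bb, rich_amphibia(), "Amphibia")
  outside <- setdiff(term_ids(bb), c("N:2", descendants(bb, "N:2")))
  for (id in outside) {
    expect_identical(res$graph$terms[[id]], bb$terms[[id]])
  }
})

test_that("replacing a subtree with an identical copy is a no-op", {
  bb <- coarse_backbone()
  sub_ids <- c("N:2", descendants(bb, "N:2"))
  src <- taxonomy_graph()
  for (id in sub_ids) {
    t <- bb$terms[[id]]
    t$id <- sub("^N:", "C:", id)
    if (!is.na(t$parent)) {
      t$parent <- if (t$parent %in% sub_ids) sub("^N:", "C:", t$parent)
                  else NA_character_
    } else t$parent <- NA_character_
    if (id == "N:2") t$parent <- NA_character_
    src <- add_term(src, t)
  }
  res <- graft_replace(bb, src, "Amphibia")
  expect_length(res$report$dropped, 0)
  # same names, same shape: every original name is present exactly once,
  # with the same parent name as before
  nm_before <- sort(unname(vapply(bb$terms, function(t) t$name,
                                  character(1))))
  nm_after <- sort(unname(vapply(res$graph$terms, function(t) t$name,
                                 character(1))))
  expect_identical(nm_before, nm_after)
  pn <- function(g, id) {
    p <- g$terms[[id]]$parent
    if (is.na(p)) NA_character_ else g$terms[[p]]$name
  }
  for (id in term_ids(res$graph)) {
    orig <- find_by_name(bb, res$graph$terms[[id]]$name)
    expect_identical(pn(res$graph, id), pn(bb, orig))
  }
})

test_that("grafting an empty source prunes the subtree and reports drops", {
  src <- add_term(taxonomy_graph(),
                  ranked_term("W:1", "Amphibia", "class"))
  res <- graft_replace(coarse_backbone(), src, "Amphibia")
  expect_identical(find_by_name(res$graph, "Amphibia"), "N:2")
  expect_length(descendants(res$graph, "N:2"), 0)
  expect_setequal(res$report$dropped,
                  c("Anura", "Rana temporaria", "Oldskoolia"))
})

test_that("graft_replace rejects bad attachments and multi-root sources", {
  expect_error(graft_replace(coarse_backbone(), rich_amphibia(), "Nopeia"),
               "resolves to 0")
  multi <- add_term(rich_amphibia(), taxon_term("W:9", "Stray"))
  expect_error(graft_replace(coarse_backbone(), multi, "Amphibia"),
               "2 roots")
  wrong <- add_term(taxonomy_graph(), taxon_term("W:1", "Lissamphibia"))
  expect_error(graft_replace(coarse_backbone(), wrong, "Amphibia"),
               "does not match")
  # but an explicit root mapping accepts the differing root name
  res <- graft_replace(coarse_backbone(), wrong, "Amphibia",
                       root_name = "Lissamphibia")
  expect_true("W:1" %in% get_term(res$graph, "N:2")$xrefs)
})

fossil_fixture <- function(rows) {
  p <- tempfile()
  writeLines(c(paste("taxon_name", "rank", "parent_name", "validity",
                     "senior_name", "material_class", "is_extinct",
                     sep = "\t"), rows), p)
  read_paleodb_table(p)
}

test_that("filter_source removes failing terms and re-parents children", {
  res <- fossil_fixture(c(
    "Bigclade\torder\tVertebrata\tVALID\t\tBODY_DIAGNOSTIC\ttrue",
    "Badfam\tfamily\tBigclade\tINVALID\t\tBODY_DIAGNOSTIC\ttrue",
    "Kid1\tgenus\tBadfam\tVALID\t\tBODY_DIAGNOSTIC\ttrue",
    "Kid2\tgenus\tBadfam\tVALID\t\tBODY_DIAGNOSTIC\ttrue",
    "Trackus\tgenus\tBigclade\tVALID\t\tTRACE\ttrue",
    "Lostus\tgenus\t\tVALID\t\tBODY_DIAGNOSTIC\ttrue"))
  fil <- filter_source(res$graph, res$status)
  g <- fil$graph
  # the invalid mid-level term is gone; children re-parent to grandparent
  expect_length(find_by_name(g, "Badfam"), 0)
  big <- find_by_name(g, "Bigclade")
  for (k in c("Kid1", "Kid2")) {
    expect_identical(get_term(g, find_by_name(g, k))$parent, big)
  }
  # trace material and parentless rows are removed, each reported once
  expect_length(find_by_name(g, "Trackus"), 0)
  expect_length(find_by_name(g, "Lostus"), 0)
  expect_setequal(fil$filtered$name, c("Badfam", "Trackus", "Lostus"))
  expect_identical(sort(fil$filtered$rule),
                   sort(c("EXCLUDE_INVALID", "EXCLUDE_NONDIAGNOSTIC",
                          "EXCLUDE_PARENTLESS")))
})

test_that("filter rules are sound: only failing terms are removed", {
  res <- fossil_fixture(c(
    "Okfam\tfamily\tElsewhere\tVALID\t\tBODY_DIAGNOSTIC\ttrue",
    "Okgen\tgenus\tOkfam\tVALID\t\tBODY_DIAGNOSTIC\ttrue",
    "Eggus\tgenus\tOkfam\tVALID\t\tEGG\ttrue",
    "Disusedia\tgenus\tOkfam\tDISUSED\t\tBODY_DIAGNOSTIC\ttrue"))
  fil <- filter_source(res$graph, res$status)
  # disused terms pass the default filters (they are obsoleted later);
  # non-diagnostic material does not
  expect_length(find_by_name(fil$graph, "Disusedia"), 1)
  expect_identical(fil$filtered$name, "Eggus")
  # custom status rules are available for stricter policies
  fil2 <- filter_source(res$graph, res$status,
                        c(default_filter_rules(),
                          list(filter_rule("CUSTOM_STATUS",
                                           list(validity = "DISUSED")))))
  expect_length(find_by_name(fil2$graph, "Disusedia"), 0)
})

test_that("attach_at_lowest_inclusive walks the ancestry to the first match", {
  target <- coarse_backbone()
  sub <- taxonomy_graph()
  sub <- add_term(sub, ranked_term("P:1", "Extinctus", "genus",
                                   is_extinct = TRUE))
  # nearest ancestor name resolves: becomes a child of that term
  res <- attach_at_lowest_inclusive(target, sub, "P:1",
                                    ancestry = c("Anura", "Amphibia"))
  expect_identical(get_term(res$graph, "P:1")$parent,
                   find_by_name(target, "Anura"))
  expect_false(res$unplaced)
  # nearest name absent, next one present: first resolvable wins
  res2 <- attach_at_lowest_inclusive(target, sub, "P:1",
                                     ancestry = c("Gonefam", "Mammalia"))
  expect_identical(get_term(res2$graph, "P:1")$parent,
                   find_by_name(target, "Mammalia"))
  # fully alien ancestry: attached at the root and reported unplaced
  res3 <- attach_at_lowest_inclusive(target, sub, "P:1",
                                     ancestry = c("Gonefam", "Goneorder"))
  expect_identical(get_term(res3$graph, "P:1")$parent, graph_root(target))
  expect_true(res3$unplaced)
})

test_that("attach merges name-matched subtree terms instead of duplicating", {
  target <- coarse_backbone()
  sub <- taxonomy_graph()
  sub <- add_term(sub, ranked_term("P:1", "Anura", "order", xrefs = "P:1"))
  sub <- add_term(sub, ranked_term("P:2", "Fossilgen", "genus", "P:1",
                                   is_extinct = TRUE, xrefs = "P:2"))
  res <- attach_at_lowest_inclusive(target, sub, "P:1",
                                    ancestry = "Amphibia")
  # no second Anura; the existing term absorbed the fossil row's identity
  expect_length(find_by_name(res$graph, "Anura"), 1)
  anura <- find_by_name(res$graph, "Anura")
  expect_true("P:1" %in% get_term(res$graph, anura)$xrefs)
  expect_identical(get_term(res$graph, "P:2")$parent, anura)
  expect_identical(res$merged, 1L)
})

test_that("obsolete_disused obsoletes terms and reattaches children at root", {
  g <- coarse_backbone()
  g <- add_term(g, ranked_term("N:7", "Deadia", "genus", "N:3",
                               is_extinct = TRUE))
  g <- add_term(g, ranked_term("N:8", "Deadia unus", "species", "N:7",
                               is_extinct = TRUE))
  g <- add_term(g, ranked_term("N:9", "Deadia duo", "species", "N:7",
                               is_extinct = TRUE))
  res <- obsolete_disused(g, "N:7")
  t <- get_term(res$graph, "N:7")
  expect_true(t$is_obsolete)
  expect_true(is.na(t$parent))
  for (id in c("N:8", "N:9")) {
    expect_identical(get_term(res$graph, id)$parent, "N:1")
  }
  expect_setequal(res$reattached, c("N:8", "N:9"))
  # no disused terms: the graph is unchanged
  expect_identical(obsolete_disused(g, character(0))$graph, g)
})

test_that("a disused chain obsoletes both links and reattaches once", {
  g <- add_term(taxonomy_graph(), taxon_term("N:1", "Root"))
  g <- add_term(g, taxon_term("N:2", "A", parent = "N:1"))
  g <- add_term(g, taxon_term("N:3", "B", parent = "N:2"))
  g <- add_term(g, taxon_term("N:4", "C", parent = "N:3"))
  res <- obsolete_disused(g, c("N:2", "N:3"))
  expect_true(get_term(res$graph, "N:2")$is_obsolete)
  expect_true(get_term(res$graph, "N:3")$is_obsolete)
  expect_identical(get_term(res$graph, "N:4")$parent, "N:1")
  expect_identical(res$reattached, "N:4")
  # obsolete hygiene: no obsolete parent edges survive
  expect_length(validate_taxonomy(res$graph), 0)
})

test_that("demote_subspecies turns subspecies into typed synonyms", {
  g <- taxonomy_graph()
  g <- add_term(g, ranked_term("G:1", "Danio", "genus"))
  g <- add_term(g, ranked_term("G:2", "Danio rerio", "species", "G:1",
                               xrefs = "G:2"))
  g <- add_term(g, ranked_term(
    "G:3", "Danio rerio frankei", "subspecies", "G:2", xrefs = "G:3",
    synonyms = synonym_record("leopard danio", "EXACT", "COMMONNAME",
                              "tto")))
  g <- add_term(g, ranked_term("G:4", "Danio rerio tweedei", "subspecies",
                               "G:2"))
  # defective placement: a subspecies directly under the genus
  g <- add_term(g, ranked_term("G:5", "Danio stray strayi", "subspecies",
                               "G:1"))
  res <- demote_subspecies(g)
  sp <- get_term(res$graph, "G:2")
  expect_false(has_term_local(res$graph, "G:3"))
  expect_false(has_term_local(res$graph, "G:4"))
  sub_syn <- sp$synonyms[sp$synonyms$type == "SUBSPECIES", ]
  expect_setequal(sub_syn$name,
                  c("Danio rerio frankei", "Danio rerio tweedei"))
  expect_true(all(sub_syn$scope == "NARROW"))
  # the subspecies' own common name survives on the species
  expect_true("leopard danio" %in% sp$synonyms$name)
  expect_true("G:3" %in% sp$xrefs)
  # the defective subspecies is untouched and reported
  expect_true(has_term_local(res$graph, "G:5"))
  expect_identical(res$skipped, "G:5")
  expect_identical(nrow(res$demoted), 2L)
})

test_that("assign_ids is deterministic, stable, and never reuses ids", {
  g <- taxonomy_graph()
  g <- add_term(g, taxon_term("S:3", "Cus", source = "src"))
  g <- add_term(g, taxon_term("S:1", "Aus", source = "src"))
  g <- add_term(g, taxon_term("S:2", "Bus", parent = "S:1",
                              source = "src"))
  res <- assign_ids(g, "TXO")
  # sequential ids in sorted stable-key order
  key_of <- function(id) {
    paste(res$graph$terms[[id]]$name, "src", sep = "\t")
  }
  expect_identical(unname(res$registry[key_of("TXO:0000001")]),
                   "TXO:0000001")
  expect_setequal(term_ids(res$graph),
                  c("TXO:0000001", "TXO:0000002", "TXO:0000003"))
  expect_identical(res$registry[["Aus\tsrc"]], "TXO:0000001")
  expect_identical(res$registry[["Bus\tsrc"]], "TXO:0000002")
  expect_identical(res$registry[["Cus\tsrc"]], "TXO:0000003")
  # the pre-assignment id is kept as an xref (provenance)
  expect_true("S:1" %in% res$graph$terms[["TXO:0000001"]]$xrefs)

  # rebuild with the registry: identical assignment
  res2 <- assign_ids(g, "TXO", prior = res$registry)
  expect_identical(res2$registry, res$registry)

  # rename one term: old key retired, fresh id after the prior maximum
  g2 <- g
  g2$terms[["S:2"]]$name <- "Busnova"
  res3 <- assign_ids(g2, "TXO", prior = res$registry)
  expect_identical(res3$registry[["Busnova\tsrc"]], "TXO:0000004")
  expect_identical(res3$registry[["Bus\tsrc"]], "TXO:0000002")  # retired
  expect_false("TXO:0000002" %in% term_ids(res3$graph))

  # duplicate ids in the prior registry are rejected
  expect_error(assign_ids(g, "TXO",
                          prior = c(a = "TXO:0000001",
                                    b = "TXO:0000001")),
               "same id")
})
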