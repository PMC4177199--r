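test_that("the generator is deterministic and honors n_species", {
  p <- sim_params(n_species = 10, seed = 1)
  s1 <- generate_taxonomy(p)
  s2 <- generate_taxonomy(p)
  expect_identical(s1$truth, s2$truth)
  expect_true(graph_identical(s1$graph, s2$graph))
  expect_identical(sum(s1$truth$terms$rank == "species"), 10L)
  s3 <- generate_taxonomy(sim_params(n_species = 10, seed = 2))
  expect_false(identical(s1$truth$terms$name, s3$truth$terms$name))
})

test_that("feature rates of zero plant nothing", {
  s <- generate_taxonomy(sim_params(
    n_species = 40, seed = 6, synonym_rate = 0, commonname_rate = 0,
    misspelling_rate = 0, subspecies_rate = 0))
  expect_identical(nrow(s$truth$synonyms), 0L)
  expect_false(any(s$truth$terms$subsp))
  nsyn <- sum(vapply(s$graph$terms, function(t) nrow(t$synonyms),
                     integer(1)))
  expect_identical(nsyn, 0L)
})

test_that("ground-truth synonym counts match an exhaustive graph scan", {
  s <- generate_taxonomy(sim_params(n_species = 100, seed = 3))
  scan <- sum(vapply(s$graph$terms, function(t) nrow(t$synonyms),
                     integer(1)))
  expect_identical(scan, nrow(s$truth$synonyms))
  # every planted record is on the right term with the right tags
  ids <- make_term_id("GT", s$truth$synonyms$idx)
  for (r in seq_len(nrow(s$truth$synonyms))) {
    syn <- s$graph$terms[[ids[r]]]$synonyms
    expect_true(any(syn$name == s$truth$synonyms$name[r] &
                      syn$scope == s$truth$synonyms$scope[r] &
                      syn$type == s$truth$synonyms$type[r]))
  }
})

test_that("probability parameters are validated", {
  expect_error(sim_params(synonym_rate = 1.2), "synonym_rate")
  expect_error(sim_params(n_species = 0), "n_species")
})

test_that("fragmentation writes all sources; no extinct taxa, no fossils", {
  s <- generate_taxonomy(sim_params(n_species = 30, seed = 8,
                                    extinct_fraction = 0))
  expect_false(any(s$truth$terms$extinct))
  d <- tempfile()
  paths <- fragment_into_sources(s, d)
  for (f in c("nodes.dmp", "names.dmp", "tto.obo", "amphibia.tsv",
              "fossils.tsv", "config.yaml")) {
    expect_true(file.exists(file.path(d, f)))
  }
  # fossil table holds only the header
  expect_length(readLines(file.path(d, "fossils.tsv")), 1)
})

test_that("specialist sources overlap the backbone exactly as recorded", {
  s <- generate_taxonomy(sim_params(n_species = 120, seed = 9))
  d <- tempfile()
  fragment_into_sources(s, d)
  bb <- read_ncbi_taxdump(file.path(d, "names.dmp"),
                          file.path(d, "nodes.dmp"))
  tto <- read_obo(file.path(d, "tto.obo"), source = "tto")
  bb_names <- vapply(bb$terms, function(t) t$name, character(1))
  tt <- s$truth$terms
  specialist_private <- tt$name[tt$role == "obo" & !tt$extinct &
                                  !taxograft:::backbone_included(tt)]
  for (id in term_ids(tto)) {
    nm <- tto$terms[[id]]$name
    expect_true(nm %in% bb_names || nm %in% specialist_private)
  }
})

test_that("planted disused taxa are expected obsolete with children at root", {
  found <- FALSE
  for (seed in 1:12) {
    s <- generate_taxonomy(sim_params(n_species = 80, seed = seed,
                                      extinct_fraction = 0.3,
                                      disused_fraction = 0.5))
    tt <- s$truth$terms
    dis <- which(tt$disused)
    if (!length(dis)) next
    kids <- which(tt$parent %in% dis & !tt$disused)
    if (!length(kids)) next
    found <- TRUE
    exp <- s$truth$expected$terms
    for (i in dis) {
      row <- exp[exp$name == tt$name[i], ]
      expect_true(all(row$obsolete))
      expect_true(all(row$parent_name == ""))
    }
    for (i in kids) {
      row <- exp[exp$name == tt$name[i] & !exp$obsolete, ]
      expect_true(all(row$parent_name == "Vertebrata"))
    }
    break
  }
  expect_true(found)
})

test_that("write_simulation produces a buildable directory with ground truth", {
  d <- tempfile()
  out <- write_simulation(sim_params(n_species = 60, seed = 10), d)
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  gt <- jsonlite::fromJSON(file.path(d, "ground_truth.json"))
  expect_identical(gt$params$n_species, 60L)
  expect_identical(gt$n_terms, nrow(out$sim$truth$terms))
  res <- cmd_build(file.path(d, "config.yaml"), quiet = TRUE)
  v <- verify_recovery(res$graph, out$sim)
  expect_true(v$ok)
})
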