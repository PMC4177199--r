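# Fixture builders and independent oracles used across the suite.

# Mammalia/Rodentia/Primates toy hierarchy for subsumption examples.
mini_graph <- function() {
  g <- taxonomy_graph("mini")
  g <- add_term(g, taxon_term("M:0000001", "Mammalia"))
  g <- add_term(g, taxon_term("M:0000002", "Rodentia",
                              parent = "M:0000001"))
  g <- add_term(g, taxon_term("M:0000003", "Primates",
                              parent = "M:0000001"))
  g <- add_term(g, taxon_term("M:0000004", "Mus", parent = "M:0000002"))
  g
}

# Random tree with n terms: parent of term i drawn uniformly among earlier
# terms; a fraction of terms obsolete (parentless). Independent of the
# simulator, used for oracle checks.
random_tree <- function(n, seed, obsolete_frac = 0.05) {
  set.seed(seed)
  g <- taxonomy_graph("random")
  ids <- sprintf("T:%07d", seq_len(n))
  g <- add_term(g, taxon_term(ids[1], "t1"))
  for (i in seq_len(n)[-1]) {
    if (i > 2 && runif(1) < obsolete_frac) {
      g <- add_term(g, taxon_term(ids[i], paste0("t", i),
                                  is_obsolete = TRUE))
    } else {
      p <- ids[sample.int(i - 1L, 1)]
      if (g$terms[[p]]$is_obsolete) p <- ids[1]
      g <- add_term(g, taxon_term(ids[i], paste0("t", i), parent = p))
    }
  }
  g
}

# Brute-force descendants oracle: walk every term's parent chain upward and
# collect those that pass through `id` — an independent code path from the
# package's child-map BFS.
brute_descendants <- function(g, id) {
  out <- character(0)
  for (cand in term_ids(g)) {
    if (cand == id || g$terms[[cand]]$is_obsolete) next
    cur <- g$terms[[cand]]$parent
    while (!is.na(cur)) {
      if (cur == id) {
        out <- c(out, cand)
        break
      }
      cur <- g$terms[[cur]]$parent
    }
  }
  out
}

# Fixed-point oracle: repeated single-step child expansion until stable.
fixpoint_descendants <- function(g, id) {
  p <- vapply(g$terms, function(t) t$parent, character(1))
  obs <- vapply(g$terms, function(t) t$is_obsolete, logical(1))
  acc <- character(0)
  frontier <- id
  repeat {
    step <- names(p)[!is.na(p) & p %in% frontier]
    step <- setdiff(step, acc)
    if (!length(step)) break
    acc <- c(acc, step)
    frontier <- step
  }
  acc[!obs[acc]]
}

# Decorate a graph with random synonyms, xrefs, comments and flags so
# round-trips exercise every serialized field.
decorate_graph <- function(g, seed) {
  set.seed(seed)
  scopes <- c("EXACT", "RELATED", "BROAD", "NARROW")
  types <- c("TAXONOMIC", "COMMONNAME", "MISSPELLING", "SUBSPECIES")
  k <- 0L
  for (id in term_ids(g)) {
    t <- g$terms[[id]]
    nsyn <- rpois(1, 0.7)
    if (nsyn > 0) {
      k <- k + nsyn
      t$synonyms <- dedup_synonyms(rbind(
        t$synonyms,
        synonym_record(paste0("syn", k, "-", seq_len(nsyn)),
                       sample(scopes, nsyn, replace = TRUE),
                       sample(types, nsyn, replace = TRUE), "deco")))
    }
    if (runif(1) < 0.3) {
      t$xrefs <- sort_c(union(t$xrefs, paste0("SRC:", sample.int(1e6, 1))))
    }
    if (runif(1) < 0.1) t$comment <- paste("note", id)
    if (runif(1) < 0.2) t$is_extinct <- TRUE
    g$terms[[id]] <- t
  }
  g
}

# A copy of the example build directory in a writable location.
example_build_dir <- function() {
  src <- system.file("extdata", "example", package = "taxograft")
  dst <- file.path(tempfile("example"), "build")
  dir.create(dst, recursive = TRUE)
  file.copy(list.files(src, full.names = TRUE), dst)
  dst
}
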