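# Fragment a simulated ground-truth taxonomy into realistic source files:
# a coarsened backbone taxdump, a full-coverage specialist OBO ontology, a
# flat specialist checklist, and a fossil status table with planted
# disused / invalid / trace / parentless rows — plus a ready-to-run build
# configuration. The union of the sources covers every retainable planted
# fact; what the merge must reconstruct is stated by the expected tables in
# the ground truth.

# backbone membership: extant terms; within the specialist clades only the
# clade root, its orders and its species (coarse NCBI-like coverage)
backbone_included <- function(terms) {
  specialist <- terms$role %in% c("obo", "tabular")
  clade_root <- terms$rank == "class" & specialist
  !terms$extinct & !(terms$subsp & specialist) &
    (!specialist | clade_root | terms$rank %in% c("order", "species"))
}

#' Fragment a simulated taxonomy into source files
#'
#' Writes \code{names.dmp}/\code{nodes.dmp} (backbone), \code{tto.obo}
#' (ontology-format specialist source for the fish-like clade),
#' \code{amphibia.tsv} (checklist-format source for the amphibian-like
#' clade), \code{fossils.tsv} (PaleoDB-style status table) and
#' \code{config.yaml} into \code{dir}.
#'
#' @param sim a \code{sim_taxonomy} from [generate_taxonomy()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file paths and the expected-merge
#'   ground truth.
#' @export
fragment_into_sources <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_taxonomy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  terms <- sim$truth$terms
  syn <- sim$truth$synonyms
  junk <- sim$truth$junk
  mixed <- sim$truth$mixed

  inc <- backbone_included(terms)
  # nearest included ancestor (for the coarsened hierarchy)
  bb_parent <- function(i) {
    p <- terms$parent[i]
    while (p > 0 && !inc[p]) p <- terms$parent[p]
    p
  }

  nodes <- character(0); nms <- character(0)
  for (i in which(inc)) {
    p <- bb_parent(i)
    nodes <- c(nodes, sprintf("%d\t|\t%d\t|\t%s\t|", i,
                              if (p > 0) p else i, terms$rank[i]))
    nms <- c(nms, sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", i,
                          terms$name[i]))
    if (terms$role[i] == "backbone") {
      for (k in which(syn$idx == i & syn$via == "backbone")) {
        cls <- if (syn$type[k] == "COMMONNAME") "genbank common name"
               else "synonym"
        nms <- c(nms, sprintf("%d\t|\t%s\t|\t\t|\t%s\t|", i, syn$name[k],
                              cls))
      }
    }
  }
  paths <- list(nodes = file.path(dir, "nodes.dmp"),
                names = file.path(dir, "names.dmp"),
                obo = file.path(dir, "tto.obo"),
                tabular = file.path(dir, "amphibia.tsv"),
                fossil = file.path(dir, "fossils.tsv"),
                config = file.path(dir, "config.yaml"))
  write_lines_atomic(nodes, paths$nodes)
  write_lines_atomic(nms, paths$names)

  # specialist OBO source: full extant coverage of the obo-role clade
  vocab <- default_rank_vocabulary()
  obo_rows <- which(terms$role == "obo" & !terms$extinct)
  tto_ids <- make_term_id("TTO", seq_along(obo_rows))
  names(tto_ids) <- as.character(obo_rows)
  og <- taxonomy_graph(ontology = "tto")
  for (i in obo_rows) {
    s <- syn[syn$idx == i & syn$via == "obo", , drop = FALSE]
    srec <- if (nrow(s)) synonym_record(s$name, s$scope, s$type, "tto")
            else empty_synonyms()
    p <- terms$parent[i]
    t <- taxon_term(tto_ids[[as.character(i)]], terms$name[i],
                    parent = if (as.character(p) %in% names(tto_ids))
                               tto_ids[[as.character(p)]]
                             else NA_character_,
                    synonyms = srec,
                    xrefs = tto_ids[[as.character(i)]], source = "tto")
    og <- add_term(og, annotate_rank(t, terms$rank[i], vocab))
  }
  write_obo(og, paths$obo)

  # specialist checklist source: one row per extant species of the
  # tabular-role clade
  tab_rows <- which(terms$role == "tabular" & !terms$extinct &
                      terms$rank == "species")
  lines <- "order\tfamily\tgenus\tspecies\tcommon_name\tsynonyms"
  for (i in tab_rows) {
    genus <- terms$parent[i]; family <- terms$parent[genus]
    ord <- terms$parent[family]
    epithet <- sub("^\\S+ ", "", terms$name[i])
    cn <- syn$name[syn$idx == i & syn$type == "COMMONNAME"]
    tx <- syn$name[syn$idx == i & syn$type == "TAXONOMIC" &
                     syn$via == "tabular"]
    lines <- c(lines, paste(terms$name[ord], terms$name[family],
                            terms$name[genus], epithet,
                            if (length(cn)) cn[1] else "",
                            paste(tx, collapse = "|"), sep = "\t"))
  }
  write_lines_atomic(lines, paths$tabular)

  # fossil status table
  frow <- function(name, rank, parent, validity, senior, material,
                   extinct) {
    paste(name, rank, parent, validity, senior, material,
          if (extinct) "true" else "false", sep = "\t")
  }
  flines <- "taxon_name\trank\tparent_name\tvalidity\tsenior_name\tmaterial_class\tis_extinct"
  invalid_above <- stats::setNames(junk$name[junk$kind == "invalid"],
                                   junk$child_name[junk$kind == "invalid"])
  for (i in which(terms$extinct)) {
    pname <- terms$name[terms$parent[i]]
    if (terms$name[i] %in% names(invalid_above)) {
      pname <- invalid_above[[terms$name[i]]]
    }
    flines <- c(flines, frow(terms$name[i], terms$rank[i], pname,
                             if (terms$disused[i]) "DISUSED" else "VALID",
                             "", "BODY_DIAGNOSTIC", TRUE))
  }
  for (i in mixed) {
    flines <- c(flines, frow(terms$name[i], terms$rank[i],
                             terms$name[terms$parent[i]], "VALID", "",
                             "BODY_DIAGNOSTIC", FALSE))
  }
  for (k in which(syn$via == "fossil")) {
    flines <- c(flines, frow(syn$name[k], "", "", "SYNONYM_OF",
                             terms$name[syn$idx[k]], "BODY_DIAGNOSTIC",
                             TRUE))
  }
  for (k in seq_len(nrow(junk))) {
    flines <- c(flines, switch(junk$kind[k],
      trace = frow(junk$name[k], junk$rank[k], junk$parent_name[k],
                   "VALID", "", "TRACE", TRUE),
      invalid = frow(junk$name[k], junk$rank[k], junk$parent_name[k],
                     "INVALID", "", "BODY_DIAGNOSTIC", TRUE),
      parentless = frow(junk$name[k], junk$rank[k], "", "VALID", "",
                        "BODY_DIAGNOSTIC", TRUE)))
  }
  write_lines_atomic(flines, paths$fossil)

  cfg <- list(
    id_namespace = "TXO",
    ontology = "simulated-taxonomy",
    backbone = list(label = "ncbi", format = "taxdump", prefix = "NCBI",
                    names = "names.dmp", nodes = "nodes.dmp"),
    sources = list(
      list(label = "tto", format = "obo", path = "tto.obo",
           mode = "REPLACE", attachment = "Actinopterygii"),
      list(label = "aweb", format = "tabular", path = "amphibia.tsv",
           mode = "REPLACE", attachment = "Amphibia", prefix = "AWEB",
           columns = list(root_name = "Amphibia", root_rank = "class",
                          higher = list(order = "order",
                                        family = "family"),
                          genus = "genus", epithet = "species",
                          common_name = "common_name",
                          synonyms = "synonyms")),
      list(label = "pbdb", format = "paleodb", path = "fossils.tsv",
           mode = "FOSSIL", prefix = "PBDB")),
    filters = list("EXCLUDE_NONDIAGNOSTIC", "EXCLUDE_INVALID",
                   "EXCLUDE_PARENTLESS"),
    output = list(obo = "out/taxonomy.obo", report = "out/report.json",
                  registry = "out/registry.tsv"))
  yaml::write_yaml(cfg, paths$config)

  invisible(c(paths, list(expected = sim$truth$expected)))
}

#' Write a complete ready-to-build simulation directory
#'
#' Generates a taxonomy, fragments it into sources, and additionally writes
#' \code{ground_truth.json} summarizing the planted facts and the expected
#' merge result.
#'
#' @param params a [sim_params()] list.
#' @param dir output directory.
#' @return invisibly, the [fragment_into_sources()] path list plus
#'   \code{sim}.
#' @export
write_simulation <- function(params, dir) {
  sim <- generate_taxonomy(params)
  paths <- fragment_into_sources(sim, dir)
  gt <- list(params = unclass(sim$params),
             n_terms = nrow(sim$truth$terms),
             n_planted_synonyms = nrow(sim$truth$synonyms),
             n_junk_rows = nrow(sim$truth$junk),
             expected_terms = sim$truth$expected$terms,
             expected_synonyms = sim$truth$expected$synonyms)
  json <- jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  write_lines_atomic(json, file.path(dir, "ground_truth.json"))
  invisible(c(paths, list(sim = sim)))
}

#' Check a merge product against the simulated ground truth
#'
#' Compares the built graph with the declaratively derived expectation:
#' every retained term present exactly once (keyed by name + parent name,
#' so homonyms stay distinct) with the right rank and extinct/obsolete
#' flags, every planted synonym present with its type tag, every term
#' carrying cross-references to exactly the sources that mention it, and
#' nothing extra.
#'
#' @param graph the product [taxonomy_graph()] (e.g. from [run_merge()]).
#' @param sim the \code{sim_taxonomy} the sources were fragmented from.
#' @param id_namespace the release namespace (its prefix is ignored when
#'   comparing xref provenance).
#' @return a list: \code{ok} (all checks perfect), \code{term_recall},
#'   \code{extra_terms}, \code{flag_mismatches}, \code{synonym_recall},
#'   \code{prefix_mismatches}.
#' @export
verify_recovery <- function(graph, sim, id_namespace = "TXO") {
  expected <- sim$truth$expected
  vocab <- default_rank_vocabulary()
  nm <- graph_term_names(graph)

  actual_key <- vapply(graph$terms, function(t) {
    pn <- if (!is.na(t$parent)) nm[[t$parent]] else ""
    paste0(t$name, "|", pn)
  }, character(1))
  if (anyDuplicated(actual_key)) {
    dup <- actual_key[duplicated(actual_key)][1]
    return(list(ok = FALSE, term_recall = NA_real_,
                extra_terms = NA_integer_, flag_mismatches = NA_integer_,
                synonym_recall = NA_real_,
                prefix_mismatches = NA_integer_,
                note = paste("duplicate term key:", dup)))
  }
  by_key <- stats::setNames(names(actual_key), actual_key)

  exp_t <- expected$terms
  found <- exp_t$key %in% actual_key
  extra <- setdiff(actual_key, exp_t$key)

  flag_bad <- 0L
  for (r in which(found)) {
    t <- graph$terms[[by_key[[exp_t$key[r]]]]]
    rk <- if (is.na(t$rank)) "" else rank_name(vocab, t$rank)
    if (rk != exp_t$rank[r] || t$is_extinct != exp_t$extinct[r] ||
        t$is_obsolete != exp_t$obsolete[r]) {
      flag_bad <- flag_bad + 1L
    }
  }

  exp_s <- expected$synonyms
  syn_found <- 0L
  for (r in seq_len(nrow(exp_s))) {
    id <- by_key[exp_s$key[r]]
    if (is.na(id)) next
    s <- graph$terms[[id]]$synonyms
    hit <- s$name == exp_s$name[r] & s$scope == exp_s$scope[r] &
      s$type == exp_s$type[r]
    if (any(hit)) syn_found <- syn_found + 1L
  }

  prefix_bad <- 0L
  for (r in which(found)) {
    t <- graph$terms[[by_key[[exp_t$key[r]]]]]
    got <- sort_c(setdiff(unique(id_prefix(t$xrefs)), id_namespace))
    want <- expected$prefixes[[exp_t$key[r]]]
    if (!identical(got, want)) prefix_bad <- prefix_bad + 1L
  }

  list(ok = all(found) && length(extra) == 0 && flag_bad == 0L &&
         syn_found == nrow(exp_s) && prefix_bad == 0L,
       term_recall = mean(found), extra_terms = length(extra),
       flag_mismatches = flag_bad,
       synonym_recall = if (nrow(exp_s)) syn_found / nrow(exp_s) else 1,
       prefix_mismatches = prefix_bad)
}
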