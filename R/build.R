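# Command entry points: one-command rebuild from a declarative config, and
# standalone validation of an OBO file. A thin Rscript wrapper around these
# functions ships in inst/scripts/taxograft.

#' Build a taxonomy ontology from a configuration file
#'
#' Loads every declared source, runs the merge pipeline
#' ([run_merge()]), and writes the OBO product, the JSON merge report and
#' the id registry. Writes are atomic (write-to-temp, rename), so outputs
#' appear only on success. One log line per stage reports counts; the log is
#' identical across reruns on equal inputs.
#'
#' @param config_path path to the YAML build configuration
#'   ([load_config()]).
#' @param out_dir optional directory overriding the directory part of every
#'   configured output path (useful when the config lives in a read-only
#'   location).
#' @param quiet suppress stage logging.
#' @return invisibly, a list with \code{graph}, \code{registry},
#'   \code{report} and the resolved \code{outputs} paths.
#' @export
cmd_build <- function(config_path, out_dir = NULL, quiet = FALSE) {
  log <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  cfg <- load_config(config_path)
  outputs <- cfg$output
  if (!is.null(out_dir)) {
    outputs <- lapply(outputs, function(p) file.path(out_dir, basename(p)))
  }

  vocab <- default_rank_vocabulary()
  bb <- load_declared_source(cfg$backbone, vocab)$graph
  log("load", "backbone %s: %d terms", cfg$backbone$label,
      length(bb$terms))

  sources <- lapply(cfg$sources, function(s) {
    loaded <- load_declared_source(s, vocab)
    log("load", "source %s (%s): %d terms", s$label, s$mode,
        length(loaded$graph$terms))
    merge_source(label = s$label, graph = loaded$graph,
                 mode = s$mode, attachment = s$attachment,
                 root_name = s$root_name, status = loaded$status)
  })

  prior <- if (!is.null(cfg$prior_registry) &&
               file.exists(cfg$prior_registry)) {
    read_id_registry(cfg$prior_registry)
  } else NULL

  res <- run_merge(bb, sources = sources, filters = cfg$filters,
                   curated = cfg$curated %||% list(),
                   id_namespace = cfg$id_namespace,
                   prior_registry = prior, vocab = vocab)
  res$graph$ontology <- cfg$ontology
  log("merge", "%d terms, %d filtered, %d obsoleted, %d demoted",
      length(res$graph$terms), nrow(res$report$filtered),
      length(res$report$obsoleted), nrow(res$report$demoted_subspecies))

  write_obo(res$graph, outputs$obo)
  if (!is.null(outputs$report)) {
    write_merge_report(res$report, outputs$report)
  }
  if (!is.null(outputs$registry)) {
    write_id_registry(res$registry, outputs$registry)
  }
  log("write", "obo=%s", outputs$obo)
  invisible(list(graph = res$graph, registry = res$registry,
                 report = res$report, outputs = outputs))
}

#' Validate an OBO file
#'
#' Parses the file and prints every [validate_taxonomy()] finding as a
#' tab-separated line (code, term ids, message).
#'
#' @param obo_path path to an OBO file.
#' @param quiet suppress printing.
#' @return invisibly, the \code{validation_report}.
#' @export
cmd_validate <- function(obo_path, quiet = FALSE) {
  g <- read_obo(obo_path)
  rep <- validate_taxonomy(g)
  if (!quiet) print(rep)
  invisible(rep)
}
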