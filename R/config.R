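# Declarative build configuration. The whole build is described by one YAML
# document — sources, attachment directives, filter rules, curated moves,
# id namespace, and output paths — so a release can be rebuilt with a single
# command, and the synthesis is scriptable rather than hard-coded.

known_formats <- c("taxdump", "obo", "tabular", "paleodb")

#' Load and validate a build configuration
#'
#' The configuration is a YAML mapping with keys:
#' \describe{
#'   \item{id_namespace}{release id prefix (required).}
#'   \item{ontology}{ontology tag written to the OBO header (default
#'     \code{"taxonomy"}).}
#'   \item{backbone}{mapping with \code{label}, \code{format} and
#'     format-specific paths (\code{names}/\code{nodes} for
#'     \code{taxdump}, \code{path} otherwise).}
#'   \item{sources}{list of source mappings; each adds \code{mode}
#'     (\code{REPLACE}, \code{GRAFT} or \code{FOSSIL}), an
#'     \code{attachment} name for graft modes, an optional \code{prefix}
#'     for loaded term ids, and a \code{columns} mapping for
#'     \code{tabular} sources.}
#'   \item{filters}{list of rule kinds or mappings with \code{kind} and
#'     \code{parameters} (default: exclude non-diagnostic material,
#'     invalid names, and parentless taxa).}
#'   \item{curated}{list of move/merge/comment directives, each with a
#'     mandatory \code{rationale}.}
#'   \item{prior_registry}{optional path to the previous release's id
#'     registry.}
#'   \item{output}{mapping with paths \code{obo}, \code{report},
#'     \code{registry}.}
#' }
#' All paths are resolved relative to the configuration file.
#'
#' @param path path to the YAML configuration.
#' @return a validated \code{build_config} object.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path, mustWork = TRUE))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  fail <- function(key, msg) {
    stop("config ", path, ": ", key, ": ", msg, call. = FALSE)
  }

  if (is.null(cfg$id_namespace)) fail("id_namespace", "missing")
  if (is.null(cfg$backbone)) fail("backbone", "missing")
  if (is.null(cfg$output) || is.null(cfg$output$obo)) {
    fail("output.obo", "missing")
  }

  check_source <- function(s, key, need_mode) {
    if (is.null(s$label)) fail(key, "missing label")
    if (is.null(s$format) || !(s$format %in% known_formats)) {
      fail(paste0(key, ".format"),
           paste0("unknown format \"", s$format %||% "", "\""))
    }
    if (s$format == "taxdump") {
      if (is.null(s$names) || is.null(s$nodes)) {
        fail(key, "taxdump sources need names and nodes paths")
      }
      s$names <- resolve(s$names); s$nodes <- resolve(s$nodes)
    } else {
      if (is.null(s$path)) fail(key, "missing path")
      s$path <- resolve(s$path)
    }
    if (need_mode) {
      if (is.null(s$mode) ||
          !(s$mode %in% c("REPLACE", "GRAFT", "FOSSIL"))) {
        fail(paste0(key, ".mode"), "must be REPLACE, GRAFT or FOSSIL")
      }
      if (s$mode %in% c("REPLACE", "GRAFT") && is.null(s$attachment)) {
        fail(key, paste0(s$mode, " source needs an attachment name"))
      }
      if (s$format == "tabular" && is.null(s$columns)) {
        fail(key, "tabular source needs a columns mapping")
      }
      if (!is.null(s$columns)) {
        s$columns$higher <- unlist(s$columns$higher)
      }
    }
    s
  }
  cfg$backbone <- check_source(cfg$backbone, "backbone", need_mode = FALSE)
  cfg$sources <- lapply(seq_along(cfg$sources %||% list()), function(i) {
    check_source(cfg$sources[[i]], paste0("sources[", i, "]"),
                 need_mode = TRUE)
  })
  labels <- c(cfg$backbone$label,
              vapply(cfg$sources, `[[`, character(1), "label"))
  if (anyDuplicated(labels)) {
    fail("sources", paste0("duplicate label \"",
                           labels[duplicated(labels)][1], "\""))
  }

  cfg$filters <- lapply(cfg$filters %||%
                          list("EXCLUDE_NONDIAGNOSTIC", "EXCLUDE_INVALID",
                               "EXCLUDE_PARENTLESS"), function(f) {
    if (is.character(f)) filter_rule(f)
    else filter_rule(f$kind, f$parameters %||% list())
  })
  for (d in cfg$curated %||% list()) {
    if (is.null(d$action) || is.null(d$rationale)) {
      fail("curated", "each directive needs an action and a rationale")
    }
  }
  cfg$prior_registry <- resolve(cfg$prior_registry)
  cfg$output <- lapply(cfg$output, resolve)
  cfg$ontology <- cfg$ontology %||% "taxonomy"
  cfg$config_dir <- base
  structure(cfg, class = "build_config")
}

load_declared_source <- function(s, vocab) {
  prefix <- s$prefix %||% toupper(s$label)
  switch(s$format,
    taxdump = list(graph = read_ncbi_taxdump(s$names, s$nodes,
                                             prefix = prefix,
                                             source = s$label,
                                             vocab = vocab)),
    obo = list(graph = read_obo(s$path, source = s$label)),
    tabular = list(graph = read_tabular_taxonomy(
      s$path, column_spec = s$columns, prefix = prefix, source = s$label,
      delim = s$delim %||% "\t", vocab = vocab)),
    paleodb = read_paleodb_table(s$path, prefix = prefix,
                                 source = s$label,
                                 delim = s$delim %||% "\t", vocab = vocab))
}
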