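# Build orchestration: the fixed stage order is backbone -> replacement
# grafts -> curated moves/merges -> fossil filter + lowest-inclusive
# attachment -> obsoletion of disused taxa -> subspecies demotion -> stable
# id assignment. Every decision is recorded in a machine-readable merge
# report.

empty_merge_report <- function() {
  structure(list(
    grafts = list(), merges = list(),
    filtered = data.frame(name = character(0), rule = character(0),
                          stringsAsFactors = FALSE),
    obsoleted = character(0), reattached_to_root = character(0),
    demoted_subspecies = data.frame(subspecies = character(0),
                                    species_id = character(0),
                                    stringsAsFactors = FALSE),
    unresolved = list()), class = "merge_report")
}

add_unresolved <- function(report, stage, message) {
  report$unresolved[[length(report$unresolved) + 1L]] <-
    list(stage = stage, message = message)
  report
}

#' Declare a source for [run_merge()]
#'
#' @param label unique source label.
#' @param graph the loaded [taxonomy_graph()].
#' @param mode \code{"REPLACE"} or \code{"GRAFT"} for specialist sources
#'   attached at a named backbone node, \code{"FOSSIL"} for status-filtered
#'   fossil tables placed at their lowest inclusive nodes.
#' @param attachment backbone name to graft at (REPLACE/GRAFT modes).
#' @param root_name optional source-root name when it differs from
#'   \code{attachment}.
#' @param status status data.frame (FOSSIL mode; see
#'   [read_paleodb_table()]).
#' @return a \code{merge_source} declaration.
#' @export
merge_source <- function(label, graph, mode = c("REPLACE", "GRAFT",
                                                "FOSSIL"),
                         attachment = NULL, root_name = NULL,
                         status = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("REPLACE", "GRAFT") && is.null(attachment)) {
    stop("source \"", label, "\": ", mode, " mode requires an attachment")
  }
  if (mode == "FOSSIL" && is.null(status)) {
    stop("source \"", label, "\": FOSSIL mode requires a status table")
  }
  structure(list(label = label, graph = graph, mode = mode,
                 attachment = attachment, root_name = root_name,
                 status = status), class = "merge_source")
}

apply_curated <- function(graph, directives, report) {
  for (d in directives) {
    act <- d$action %||% stop("curated directive without an action")
    rationale <- d$rationale %||%
      stop("curated \"", act, "\" directive requires a rationale")
    note <- function(t) {
      t$comment <- if (is.na(t$comment)) rationale
                   else paste(t$comment, rationale, sep = " | ")
      t
    }
    resolve1 <- function(nm) {
      ids <- find_by_name(graph, nm)
      if (length(ids) != 1) {
        stop("curated directive: name \"", nm, "\" resolves to ",
             length(ids), " terms")
      }
      ids
    }
    if (act == "move") {
      id <- resolve1(d$name); newp <- resolve1(d$new_parent)
      t <- graph$terms[[id]]
      t$parent <- newp
      graph$terms[[id]] <- note(t)
    } else if (act == "merge") {
      id <- resolve1(d$name); into <- resolve1(d$into)
      ch <- children_map(graph)[[id]] %||% character(0)
      for (c_id in ch) {
        t <- graph$terms[[c_id]]
        t$parent <- into
        graph$terms[[c_id]] <- t
      }
      donor <- graph$terms[[id]]
      graph$terms[[id]] <- NULL
      res <- absorb_term(graph, into, donor)
      graph <- res$graph
      graph$terms[[into]] <- note(graph$terms[[into]])
    } else if (act == "comment") {
      id <- resolve1(d$name)
      graph$terms[[id]] <- note(graph$terms[[id]])
    } else {
      stop("unknown curated action: ", act)
    }
  }
  list(graph = graph, report = report)
}

#' Run the full merge pipeline
#'
#' Executes the stages in fixed order on an already-loaded backbone and
#' source set, and returns the product graph (with release ids assigned),
#' the id registry, and a [merge report][write_merge_report()] auditing
#' every graft, merge, filter, obsoletion, reattachment and demotion.
#' The output graph is guaranteed free of cycles and unresolved parents.
#'
#' @param backbone the backbone [taxonomy_graph()].
#' @param sources list of [merge_source()] declarations, applied in order.
#' @param filters list of [filter_rule()]s applied to FOSSIL sources.
#' @param curated list of curated move/merge/comment directives, each a list
#'   with \code{action}, \code{name}, action-specific fields, and a
#'   mandatory free-text \code{rationale} that is recorded in the affected
#'   term's comment.
#' @param id_namespace release id prefix.
#' @param prior_registry optional registry from the previous release (see
#'   [read_id_registry()]).
#' @param vocab rank vocabulary.
#' @return a list: \code{graph}, \code{registry}, \code{report}.
#' @export
run_merge <- function(backbone, sources = list(),
                      filters = default_filter_rules(), curated = list(),
                      id_namespace = "TXO", prior_registry = NULL,
                      vocab = default_rank_vocabulary()) {
  report <- empty_merge_report()
  g <- backbone

  labels <- vapply(sources, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate source label: ", labels[duplicated(labels)][1])
  }

  for (s in sources) {
    if (s$mode %in% c("REPLACE", "GRAFT")) {
      res <- graft_replace(g, s$graph, s$attachment,
                           root_name = s$root_name, mode = s$mode)
      g <- res$graph
      report$grafts[[length(report$grafts) + 1L]] <-
        c(list(source = s$label), res$report)
      for (d in res$report$dropped) {
        report <- add_unresolved(report, "graft", paste0(
          "backbone term \"", d, "\" under ", s$attachment,
          " dropped: no name match in source ", s$label))
      }
      for (m in res$merges) {
        report$merges[[length(report$merges) + 1L]] <- m
      }
    }
  }

  cur <- apply_curated(g, curated, report)
  g <- cur$graph; report <- cur$report

  for (s in sources) {
    if (s$mode != "FOSSIL") next
    fil <- filter_source(s$graph, s$status, filters)
    report$filtered <- rbind(report$filtered, fil$filtered)
    fg <- fil$graph
    names_by_id <- if (length(fg$terms)) graph_term_names(fg)
                   else character(0)
    disused_rows <- s$status[!is.na(s$status$id) &
                               s$status$validity == "DISUSED", , drop = FALSE]
    mapping_all <- character(0)
    for (root_id in graph_roots(fg)) {
      ancestry <- fossil_root_ancestry(s$status, names_by_id[[root_id]])
      res <- attach_at_lowest_inclusive(g, fg, root_id, ancestry)
      g <- res$graph
      mapping_all[names(res$mapping)] <- res$mapping
      for (m in res$merges) {
        report$merges[[length(report$merges) + 1L]] <- m
      }
      if (res$unplaced) {
        report <- add_unresolved(report, "fossil_attach", paste0(
          "subtree rooted at \"", names_by_id[[root_id]],
          "\" had no resolvable ancestor; attached at the root"))
      }
    }
    # obsolete the disused taxa that were installed as new terms; a disused
    # row that merged onto a pre-existing term is a curation flag, not an
    # obsoletion
    dis_ids <- intersect(disused_rows$id, names(mapping_all))
    installed <- dis_ids[mapping_all[dis_ids] == dis_ids]
    clashed <- setdiff(dis_ids, installed)
    for (cid in clashed) {
      report <- add_unresolved(report, "obsoletion", paste0(
        "disused taxon \"", names_by_id[[cid]],
        "\" merged onto an existing term; not obsoleted"))
    }
    if (length(installed)) {
      res <- obsolete_disused(g, installed)
      g <- res$graph
      report$obsoleted <- c(report$obsoleted, installed)
      report$reattached_to_root <- c(report$reattached_to_root,
                                     res$reattached)
    }
  }

  dem <- demote_subspecies(g, vocab)
  g <- dem$graph
  report$demoted_subspecies <- dem$demoted
  for (sk in dem$skipped) {
    report <- add_unresolved(report, "subspecies", paste0(
      "subspecies term ", sk, " not demoted (non-species parent or has ",
      "children)"))
  }

  ids <- assign_ids(g, id_namespace, prior_registry)
  # translate the pre-assignment ids recorded in the report to release ids
  report$obsoleted <- unname(ids$id_map[report$obsoleted])
  report$reattached_to_root <- unname(ids$id_map[report$reattached_to_root])
  g <- ids$graph

  rep <- validate_taxonomy(g, vocab)
  codes <- vapply(rep, function(f) f$code, character(1))
  if (any(codes %in% c("CYCLE", "UNRESOLVED_PARENT"))) {
    stop("merge produced an invalid graph: ",
         rep[[which(codes %in% c("CYCLE", "UNRESOLVED_PARENT"))[1]]]$message)
  }

  list(graph = g, registry = ids$registry, report = report)
}

#' Serialize a merge report as JSON
#'
#' @param report a \code{merge_report} from [run_merge()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_merge_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "rows")
  write_lines_atomic(json, path)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(paste0("<merge_report> %d grafts, %d merges, %d filtered, ",
                     "%d obsoleted, %d reattached, %d demoted, ",
                     "%d unresolved\n"),
              length(x$grafts), length(x$merges), nrow(x$filtered),
              length(x$obsoleted), length(x$reattached_to_root),
              nrow(x$demoted_subspecies), length(x$unresolved)))
  invisible(x)
}
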