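# Core data model: taxon terms, the taxonomy graph (a forest of is_a edges),
# name indexing, subsumption queries, and structural validation.

#' Create a synonym record table
#'
#' Synonyms are typed: a scope (OBO synonym scopes EXACT, RELATED, BROAD,
#' NARROW) plus an open type tag distinguishing kinds of synonyms, at minimum
#' \code{COMMONNAME}, \code{MISSPELLING}, \code{TAXONOMIC} and
#' \code{SUBSPECIES}.
#'
#' @param name synonym string(s); must be nonempty after whitespace
#'   normalization.
#' @param scope synonym scope, one of \code{"EXACT"}, \code{"RELATED"},
#'   \code{"BROAD"}, \code{"NARROW"}.
#' @param type open type tag, e.g. \code{"COMMONNAME"}.
#' @param source label of the source taxonomy the synonym came from.
#' @return a data.frame with columns \code{name}, \code{scope}, \code{type},
#'   \code{source}, one row per synonym.
#' @export
synonym_record <- function(name, scope = "RELATED", type = "TAXONOMIC",
                           source = "") {
  name <- normalize_name(name)
  if (any(!nzchar(name))) {
    stop("synonym name must be nonempty after whitespace normalization")
  }
  scopes <- c("EXACT", "RELATED", "BROAD", "NARROW")
  if (any(!scope %in% scopes)) {
    stop("synonym scope must be one of ", paste(scopes, collapse = ", "))
  }
  data.frame(name = name, scope = scope, type = type, source = source,
             stringsAsFactors = FALSE)
}

empty_synonyms <- function() {
  data.frame(name = character(0), scope = character(0), type = character(0),
             source = character(0), stringsAsFactors = FALSE)
}

# Deduplicate a synonym table on (normalized name, type tag); first
# occurrence wins, so scope conflicts resolve toward the pre-existing record.
dedup_synonyms <- function(syn) {
  if (nrow(syn) == 0) return(syn)
  key <- paste(normalize_name(syn$name), syn$type, sep = "\r")
  syn <- syn[!duplicated(key), , drop = FALSE]
  rownames(syn) <- NULL
  syn
}

#' Create a taxon term
#'
#' A taxon term models one taxon concept as an ontology class: a primary
#' scientific name, an optional rank, typed synonyms, cross-references to the
#' source records the term was derived from, and extinct/obsolete flags.
#'
#' @param id term identifier of the form \code{"PREFIX:zero-padded-integer"}.
#' @param name primary (scientific) name; nonempty.
#' @param parent identifier of the parent term, or \code{NA} for a root.
#' @param rank rank-vocabulary identifier, or \code{NA} for rank-free terms.
#' @param synonyms a synonym table as built by [synonym_record()].
#' @param xrefs character vector of \code{"prefix:local_id"} cross-references.
#' @param is_extinct \code{TRUE} for taxa known only from fossil evidence.
#' @param is_obsolete \code{TRUE} for terms retained for identifier stability
#'   but removed from the hierarchy; obsolete terms have no parent.
#' @param comment free-text curation comment, or \code{NA}.
#' @param source label of the source taxonomy that introduced the term.
#' @param extra character vector of opaque serialized tag lines preserved for
#'   round-tripping unrecognized OBO tags.
#' @return an object of class \code{taxon_term}.
#' @export
taxon_term <- function(id, name, parent = NA_character_, rank = NA_character_,
                       synonyms = empty_synonyms(), xrefs = character(0),
                       is_extinct = FALSE, is_obsolete = FALSE,
                       comment = NA_character_, source = "",
                       extra = character(0)) {
  name <- normalize_name(name)
  if (!nzchar(name)) stop("taxon term ", id, " has an empty primary name")
  # note: the "obsolete terms have no parent" invariant is checked by
  # validate_taxonomy(), not enforced here, so defective inputs can be
  # loaded and reported rather than rejected at parse time
  structure(list(id = id, name = name, parent = parent, rank = rank,
                 synonyms = dedup_synonyms(synonyms),
                 xrefs = sort_c(unique(as.character(xrefs))),
                 is_extinct = isTRUE(is_extinct),
                 is_obsolete = isTRUE(is_obsolete),
                 comment = comment, source = source, extra = extra),
            class = "taxon_term")
}

#' @export
print.taxon_term <- function(x, ...) {
  cat(sprintf("<taxon_term> %s \"%s\"%s\n", x$id, x$name,
              if (x$is_obsolete) " (obsolete)" else ""))
  if (!is.na(x$rank)) cat("  rank:  ", x$rank, "\n")
  if (!is.na(x$parent)) cat("  parent:", x$parent, "\n")
  if (nrow(x$synonyms)) cat("  synonyms:", nrow(x$synonyms), "\n")
  if (length(x$xrefs)) cat("  xrefs:  ", paste(x$xrefs, collapse = " "), "\n")
  invisible(x)
}

#' Create an empty taxonomy graph
#'
#' A taxonomy graph is a forest of taxon terms under \code{is_a} edges:
#' acyclic, at most one parent per term. Obsolete terms stay in the term map
#' (queryable by id and name) but take no part in the hierarchy.
#'
#' @param ontology short tag naming the ontology (used in the OBO header).
#' @return an object of class \code{taxonomy_graph}.
#' @export
taxonomy_graph <- function(ontology = "taxonomy") {
  structure(list(terms = list(), ontology = ontology),
            class = "taxonomy_graph")
}

#' @export
print.taxonomy_graph <- function(x, ...) {
  n <- length(x$terms)
  nobs <- sum(vapply(x$terms, function(t) t$is_obsolete, logical(1)))
  cat(sprintf("<taxonomy_graph> \"%s\": %d terms (%d obsolete), %d roots\n",
              x$ontology, n, nobs, length(graph_roots(x))))
  invisible(x)
}

#' Add a term to a taxonomy graph
#'
#' @param graph a [taxonomy_graph()].
#' @param term a [taxon_term()]; its id must not already be present.
#' @return the updated graph.
#' @export
add_term <- function(graph, term) {
  stopifnot(inherits(term, "taxon_term"))
  if (!is.null(graph$terms[[term$id]])) {
    stop("duplicate term id: ", term$id)
  }
  graph$terms[[term$id]] <- term
  graph
}

#' Fetch one term by id
#' @param graph a taxonomy graph.
#' @param id a term id.
#' @return the [taxon_term()].
#' @export
get_term <- function(graph, id) {
  t <- graph$terms[[id]]
  if (is.null(t)) stop("unknown term id: ", id)
  t
}

has_term <- function(graph, id) !is.null(graph$terms[[id]])

#' @rdname get_term
#' @export
term_ids <- function(graph) names(graph$terms)

# Named character vector id -> parent id (NA for roots/obsolete).
graph_parents <- function(graph) {
  vapply(graph$terms, function(t) t$parent, character(1))
}

# Named character vector id -> primary name.
graph_term_names <- function(graph) {
  vapply(graph$terms, function(t) t$name, character(1))
}

graph_obsolete <- function(graph) {
  vapply(graph$terms, function(t) t$is_obsolete, logical(1))
}

#' Roots and the designated root of a graph
#'
#' Roots are the non-obsolete terms without a parent.
#'
#' @param graph a taxonomy graph.
#' @return `graph_roots()`: character vector of root ids (sorted).
#'   `graph_root()`: the single root id; errors if the graph does not have
#'   exactly one root.
#' @export
graph_roots <- function(graph) {
  if (length(graph$terms) == 0) return(character(0))
  p <- graph_parents(graph)
  obs <- graph_obsolete(graph)
  sort_c(names(p)[is.na(p) & !obs])
}

#' @rdname graph_roots
#' @export
graph_root <- function(graph) {
  r <- graph_roots(graph)
  if (length(r) != 1) {
    stop("graph has ", length(r), " roots; exactly one required")
  }
  r
}

#' Name index of a graph
#'
#' @param graph a taxonomy graph.
#' @return a named list mapping each normalized primary name to the character
#'   vector of term ids bearing it (homonyms map to several ids).
#' @export
name_index <- function(graph) {
  if (length(graph$terms) == 0) return(list())
  nm <- normalize_name(graph_term_names(graph))
  ids <- names(graph$terms)
  split(ids, nm)
}

# children map: named list parent id -> character vector of child ids,
# obsolete terms excluded (they have no parent anyway, but be safe).
children_map <- function(graph) {
  p <- graph_parents(graph)
  keep <- !is.na(p)
  split(names(p)[keep], p[keep])
}

#' Transitive descendants of a term
#'
#' Subsumption-query support: all terms reachable from \code{id} by following
#' child edges transitively, excluding \code{id} itself and excluding
#' obsolete terms. This is the query contract a knowledgebase relies on:
#' data attached to any descendant of a taxon is returned when querying the
#' taxon itself.
#'
#' @param graph a taxonomy graph.
#' @param id an existing term id.
#' @return character vector of descendant term ids (unordered set).
#' @export
descendants <- function(graph, id) {
  if (!has_term(graph, id)) stop("unknown term id: ", id)
  ch <- children_map(graph)
  out <- character(0)
  frontier <- ch[[id]] %||% character(0)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(ch[frontier], use.names = FALSE)
  }
  if (length(out)) {
    obs <- vapply(graph$terms[out], function(t) t$is_obsolete, logical(1))
    out <- out[!obs]
  }
  unique(out)
}

#' Subsumption test
#'
#' \code{TRUE} iff \code{ancestor} equals \code{child} or lies on the parent
#' chain of \code{child}. Reflexive by contract.
#'
#' @param graph a taxonomy graph.
#' @param child,ancestor existing term ids.
#' @return logical scalar.
#' @export
is_subsumed_by <- function(graph, child, ancestor) {
  if (!has_term(graph, child)) stop("unknown term id: ", child)
  if (!has_term(graph, ancestor)) stop("unknown term id: ", ancestor)
  cur <- child
  seen <- character(0)
  repeat {
    if (identical(cur, ancestor)) return(TRUE)
    seen <- c(seen, cur)
    cur <- graph$terms[[cur]]$parent
    if (is.na(cur) || cur %in% seen || !has_term(graph, cur)) return(FALSE)
  }
}

# Ancestor chain names (nearest first), used for homonym disambiguation.
ancestor_names <- function(graph, id) {
  out <- character(0)
  cur <- graph$terms[[id]]$parent
  seen <- character(0)
  while (!is.na(cur) && has_term(graph, cur) && !(cur %in% seen)) {
    seen <- c(seen, cur)
    out <- c(out, normalize_name(graph$terms[[cur]]$name))
    cur <- graph$terms[[cur]]$parent
  }
  out
}

#' Look up terms by primary name
#'
#' Qualified name lookup: the optional \code{rank} and \code{within}
#' arguments disambiguate homonyms (the same name in two families, say).
#'
#' @param graph a taxonomy graph.
#' @param name query name; compared after whitespace normalization,
#'   case-sensitively.
#' @param rank optional rank id; keep only terms of that rank.
#' @param within optional term id; keep only terms subsumed by it.
#' @return character vector of matching term ids, possibly empty.
#' @export
find_by_name <- function(graph, name, rank = NULL, within = NULL) {
  idx <- name_index(graph)
  ids <- idx[[normalize_name(name)]] %||% character(0)
  if (!is.null(rank) && length(ids)) {
    ranks <- vapply(graph$terms[ids], function(t) t$rank, character(1))
    ids <- ids[!is.na(ranks) & ranks == rank]
  }
  if (!is.null(within) && length(ids)) {
    keep <- vapply(ids, function(i) is_subsumed_by(graph, i, within),
                   logical(1))
    ids <- ids[keep]
  }
  unname(ids)
}

# ---------------------------------------------------------------------------
# Structural validation

validation_finding <- function(code, terms, message) {
  list(code = code, terms = as.character(terms), message = message)
}

#' Validate a taxonomy graph
#'
#' Reports structural defects as findings rather than exceptions: cycles,
#' unresolved parent references, obsolete terms retaining a parent, duplicate
#' primary names (homonym candidates), and rank inversions (a ranked
#' descendant whose rank is strictly more inclusive than a ranked
#' ancestor's). An empty report means the graph is clean. Source taxonomies
#' do contain such defects (e.g. the same name listed as valid in two places
#' in fossil compilations), so validation is a first-class reporting step.
#'
#' @param graph a taxonomy graph.
#' @param vocab a rank vocabulary used for the rank-inversion check; defaults
#'   to the packaged vocabulary.
#' @return an object of class \code{validation_report}: a list of findings,
#'   each with a stable \code{code}, the \code{terms} involved, and a human
#'   \code{message}.
#' @export
validate_taxonomy <- function(graph, vocab = default_rank_vocabulary()) {
  findings <- list()
  p <- graph_parents(graph)
  ids <- names(p)

  # unresolved parents
  bad <- ids[!is.na(p) & !(p %in% ids)]
  for (i in bad) {
    findings[[length(findings) + 1L]] <- validation_finding(
      "UNRESOLVED_PARENT", i,
      sprintf("term %s references missing parent %s", i, p[[i]]))
  }

  # obsolete terms with a parent
  obs <- graph_obsolete(graph)
  bad <- ids[obs & !is.na(p)]
  for (i in bad) {
    findings[[length(findings) + 1L]] <- validation_finding(
      "OBSOLETE_WITH_PARENT", i,
      sprintf("obsolete term %s retains parent %s", i, p[[i]]))
  }

  # cycles: walk parent chains with global coloring
  state <- integer(length(ids))  # 0 unvisited, 1 done
  names(state) <- ids
  reported <- character(0)
  for (start in ids) {
    if (state[[start]] == 1L) next
    path <- character(0)
    cur <- start
    while (!is.na(cur) && cur %in% ids && state[[cur]] == 0L &&
           !(cur %in% path)) {
      path <- c(path, cur)
      cur <- p[[cur]]
    }
    if (!is.na(cur) && cur %in% path) {
      cyc <- sort_c(path[seq(match(cur, path), length(path))])
      key <- paste(cyc, collapse = ",")
      if (!(key %in% reported)) {
        reported <- c(reported, key)
        findings[[length(findings) + 1L]] <- validation_finding(
          "CYCLE", cyc, sprintf("is_a cycle among {%s}", key))
      }
    }
    state[path] <- 1L
  }

  # duplicate primary names among non-obsolete terms
  idx <- name_index(graph)
  for (nm in sort_c(names(idx))) {
    dup <- idx[[nm]]
    dup <- dup[!vapply(graph$terms[dup], function(t) t$is_obsolete,
                       logical(1))]
    if (length(dup) > 1) {
      findings[[length(findings) + 1L]] <- validation_finding(
        "DUPLICATE_NAME", sort_c(dup),
        sprintf("primary name \"%s\" borne by %d terms (homonym candidates)",
                nm, length(dup)))
    }
  }

  # rank inversions: along any root-to-leaf chain the rank levels of the
  # leveled terms must be non-decreasing (less inclusive downwards); it
  # suffices to compare each leveled term with its nearest leveled ancestor.
  if (!is.null(vocab)) {
    lev <- vapply(graph$terms, function(t) {
      if (is.na(t$rank)) NA_integer_ else rank_level(vocab, t$rank)
    }, integer(1))
    for (i in ids[!is.na(lev)]) {
      cur <- p[[i]]
      seen <- character(0)
      while (!is.na(cur) && cur %in% ids && !(cur %in% seen)) {
        seen <- c(seen, cur)
        if (!is.na(lev[[cur]])) {
          if (lev[[cur]] > lev[[i]]) {
            findings[[length(findings) + 1L]] <- validation_finding(
              "RANK_INVERSION", c(i, cur),
              sprintf("term %s (%s) has more inclusive rank than ancestor %s (%s)",
                      i, graph$terms[[i]]$rank, cur, graph$terms[[cur]]$rank))
          }
          break
        }
        cur <- p[[cur]]
      }
    }
  }

  structure(findings, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x) == 0) {
    cat("validation: clean (no findings)\n")
  } else {
    for (f in x) {
      cat(sprintf("%s\t%s\t%s\n", f$code, paste(f$terms, collapse = ","),
                  f$message))
    }
  }
  invisible(x)
}

#' Serialize a validation report as JSON lines
#'
#' One finding per line: \code{{"code":..., "terms":[...], "message":...}}.
#'
#' @param report a \code{validation_report}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_validation_report <- function(report, path) {
  lines <- vapply(report, function(f) {
    jsonlite::toJSON(list(code = f$code, terms = f$terms,
                          message = f$message),
                     auto_unbox = TRUE)
  }, character(1))
  write_lines_atomic(lines, path)
}
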