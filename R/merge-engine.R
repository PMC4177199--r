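# Merge engine: graft specialist taxonomies onto a backbone, merge synonym
# lists across sources by primary-name matching, filter and place fossil
# taxa, obsolete disused taxa, demote subspecies to typed synonyms, and
# assign stable release identifiers.

# --------------------------------------------------------------------------
# Name matching

# Disambiguation ladder for a name borne by several candidate terms:
# unique candidate -> it; else unique candidate of equal rank -> it; else
# unique candidate sharing an ancestor name -> it; else NA (ambiguous).
disambiguate <- function(target, cand_ids, rank, anc_names) {
  if (length(cand_ids) == 1) return(cand_ids)
  if (!is.na(rank)) {
    ranks <- vapply(target$terms[cand_ids], function(t) t$rank, character(1))
    hit <- cand_ids[!is.na(ranks) & ranks == rank]
    if (length(hit) == 1) return(hit)
    if (length(hit) > 1) cand_ids <- hit
  }
  if (length(anc_names)) {
    shared <- vapply(cand_ids, function(b) {
      length(intersect(ancestor_names(target, b), anc_names)) > 0
    }, logical(1))
    hit <- cand_ids[shared]
    if (length(hit) == 1) return(hit)
  }
  NA_character_
}

#' Match source terms to backbone terms by primary name
#'
#' A source term maps to a backbone term iff their normalized primary names
#' are equal and the match is unambiguous: exactly one candidate on each
#' side, or disambiguated by equal rank, or by a shared ancestor name.
#' Ambiguous names are omitted from the map and reported — homonymy is the
#' known hazard of automated node mapping between large taxonomies.
#'
#' @param backbone,source taxonomy graphs.
#' @return a list with \code{map} — named character vector, source term id
#'   to backbone term id — and \code{ambiguous} — a data.frame of
#'   unresolved names with a reason.
#' @export
match_terms <- function(backbone, source) {
  bb_idx <- name_index(backbone)
  src_idx <- name_index(source)
  shared <- intersect(names(src_idx), names(bb_idx))
  map <- character(0)
  amb_name <- character(0); amb_reason <- character(0)
  for (nmv in sort_c(shared)) {
    s_ids <- src_idx[[nmv]]
    b_ids <- bb_idx[[nmv]]
    if (length(s_ids) == 1 && length(b_ids) == 1) {
      map[s_ids] <- b_ids
      next
    }
    resolved <- 0L
    for (s in s_ids) {
      hit <- disambiguate(backbone, b_ids,
                          source$terms[[s]]$rank,
                          ancestor_names(source, s))
      if (!is.na(hit)) {
        map[s] <- hit
        resolved <- resolved + 1L
      }
    }
    if (resolved < length(s_ids)) {
      amb_name <- c(amb_name, nmv)
      amb_reason <- c(amb_reason,
                      sprintf("%d source vs %d backbone bearers, %d resolved",
                              length(s_ids), length(b_ids), resolved))
    }
  }
  list(map = map,
       ambiguous = data.frame(name = amb_name, reason = amb_reason,
                              stringsAsFactors = FALSE))
}

#' Merge one term's names and provenance into another
#'
#' The target's synonym set becomes the union of both (deduplicated on
#' normalized name + type tag; scope conflicts resolve toward the
#' pre-existing record). The donor's primary name is added as an EXACT
#' synonym when it differs from the target's after normalization, the
#' donor's xrefs are unioned in, and \code{is_extinct} becomes the logical
#' OR. Idempotent when a term is merged with itself.
#'
#' @param target,donor [taxon_term()] objects the caller has matched.
#' @return the updated target term.
#' @export
merge_synonyms <- function(target, donor) {
  syn <- rbind(target$synonyms, donor$synonyms)
  if (normalize_name(donor$name) != normalize_name(target$name)) {
    syn <- rbind(syn, synonym_record(donor$name, "EXACT", "TAXONOMIC",
                                     donor$source))
  }
  target$synonyms <- dedup_synonyms(syn)
  target$xrefs <- sort_c(union(target$xrefs, donor$xrefs))
  target$is_extinct <- target$is_extinct || donor$is_extinct
  target
}

# Merge donor into the term with id `tid`, also recording the donor's own id
# as an xref (provenance for terms that disappear as classes). Returns the
# updated graph plus an audit entry with the synonym/xref deltas.
absorb_term <- function(graph, tid, donor) {
  before <- graph$terms[[tid]]
  t <- merge_synonyms(before, donor)
  if (donor$id != tid) t$xrefs <- sort_c(union(t$xrefs, donor$id))
  graph$terms[[tid]] <- t
  list(graph = graph,
       merge = list(target = tid, source_name = donor$name,
                    synonyms_added = nrow(t$synonyms) -
                      nrow(before$synonyms),
                    xrefs_added = length(t$xrefs) - length(before$xrefs)))
}

# --------------------------------------------------------------------------
# Grafting

#' Replace a backbone subtree with a specialist source tree
#'
#' Implements replacement grafting: all backbone descendants of the
#' attachment term are removed and the source tree is installed beneath it.
#' The attachment term keeps its backbone identity and gains the source
#' root's synonyms and xrefs. Every removed backbone term whose name matches
#' an installed source term donates its synonyms and xrefs (and its id, as
#' an xref) to that term; removed terms with no match are reported as
#' dropped. Terms outside the attachment subtree are untouched.
#'
#' @param backbone a taxonomy graph.
#' @param source a taxonomy graph with a single root whose name matches
#'   \code{attachment_name} (or is mapped to it via \code{root_name}).
#' @param attachment_name primary name resolving to exactly one non-obsolete
#'   backbone term.
#' @param root_name optional name borne by the source root when it differs
#'   from \code{attachment_name}.
#' @param mode \code{"REPLACE"} (default) removes the backbone subtree
#'   first; \code{"GRAFT"} keeps existing backbone children and only adds
#'   the source terms.
#' @return a list: \code{graph} (updated backbone), \code{report} (a list
#'   with \code{attachment}, \code{terms_added}, \code{carried},
#'   \code{dropped}).
#' @export
graft_replace <- function(backbone, source, attachment_name,
                          root_name = NULL, mode = "REPLACE") {
  att <- find_by_name(backbone, attachment_name)
  att <- att[!vapply(backbone$terms[att], function(t) t$is_obsolete,
                     logical(1))]
  if (length(att) != 1) {
    stop("attachment name \"", attachment_name, "\" resolves to ",
         length(att), " backbone terms; need exactly one")
  }
  src_roots <- graph_roots(source)
  if (length(src_roots) != 1) {
    stop("source has ", length(src_roots),
         " roots; a single root (or a root mapping) is required")
  }
  root <- source$terms[[src_roots]]
  want <- normalize_name(root_name %||% attachment_name)
  if (normalize_name(root$name) != want) {
    stop("source root \"", root$name, "\" does not match attachment \"",
         want, "\"")
  }

  removed <- character(0)
  if (identical(mode, "REPLACE")) {
    removed <- descendants(backbone, att)
    removed_terms <- backbone$terms[removed]
    backbone$terms[removed] <- NULL
  } else {
    removed_terms <- list()
  }

  # install source terms (all but the root) under the attachment term
  clash <- intersect(term_ids(source), term_ids(backbone))
  if (length(clash)) {
    stop("source and backbone share term ids (e.g. ", clash[1],
         "); load sources under distinct namespaces")
  }
  install <- setdiff(term_ids(source), root$id)
  for (id in install) {
    t <- source$terms[[id]]
    if (identical(t$parent, root$id)) t$parent <- att
    backbone$terms[[id]] <- t
  }
  merges <- list()
  res <- absorb_term(backbone, att, root)
  backbone <- res$graph
  merges[[length(merges) + 1L]] <- res$merge

  # carry synonyms/xrefs of removed backbone terms onto name-matched
  # installed terms
  inst_idx <- if (length(install)) {
    nmv <- normalize_name(vapply(backbone$terms[install],
                                 function(t) t$name, character(1)))
    split(install, nmv)
  } else list()
  dropped <- character(0)
  carried <- 0L
  for (rt in removed_terms) {
    cand <- inst_idx[[normalize_name(rt$name)]] %||% character(0)
    hit <- if (length(cand)) {
      disambiguate(backbone, cand, rt$rank, character(0))
    } else NA_character_
    if (is.na(hit)) {
      dropped <- c(dropped, rt$name)
    } else {
      res <- absorb_term(backbone, hit, rt)
      backbone <- res$graph
      merges[[length(merges) + 1L]] <- res$merge
      carried <- carried + 1L
    }
  }
  list(graph = backbone,
       report = list(attachment = att, terms_added = length(install),
                     carried = carried, dropped = sort_c(dropped)),
       merges = merges)
}

# --------------------------------------------------------------------------
# Fossil filtering and placement

#' Declare a filter rule
#'
#' Rules are pure predicates on a term's status row, so they are
#' order-independent. Kinds: \code{EXCLUDE_NONDIAGNOSTIC} removes taxa whose
#' material class is not diagnostic for species identification (trace
#' fossils, eggshells and the like); \code{EXCLUDE_INVALID} removes invalid
#' names; \code{EXCLUDE_PARENTLESS} removes taxa with no parent
#' classification at all (blank parent name); \code{CUSTOM_STATUS} removes
#' taxa whose validity is in \code{parameters$validity}.
#'
#' @param kind rule kind.
#' @param parameters list of parameters, used by \code{CUSTOM_STATUS}.
#' @return an object of class \code{filter_rule}.
#' @export
filter_rule <- function(kind, parameters = list()) {
  kinds <- c("EXCLUDE_NONDIAGNOSTIC", "EXCLUDE_INVALID",
             "EXCLUDE_PARENTLESS", "CUSTOM_STATUS")
  if (!kind %in% kinds) stop("unknown filter rule kind: ", kind)
  structure(list(kind = kind, parameters = parameters),
            class = "filter_rule")
}

#' @rdname filter_rule
#' @export
default_filter_rules <- function() {
  list(filter_rule("EXCLUDE_NONDIAGNOSTIC"), filter_rule("EXCLUDE_INVALID"),
       filter_rule("EXCLUDE_PARENTLESS"))
}

rule_fails <- function(rule, status_row) {
  switch(rule$kind,
    EXCLUDE_NONDIAGNOSTIC =
      status_row$material_class %in% c("TRACE", "EGG",
                                       "OTHER_NONDIAGNOSTIC"),
    EXCLUDE_INVALID = status_row$validity == "INVALID",
    EXCLUDE_PARENTLESS = !nzchar(status_row$parent_name),
    CUSTOM_STATUS =
      status_row$validity %in% (rule$parameters$validity %||% character(0)))
}

#' Filter a fossil source graph by status rules
#'
#' Terms failing any rule are removed. Children of a removed term are
#' re-parented to its nearest surviving ancestor within the source graph,
#' or become subtree roots when no in-graph ancestor survives. Every removal
#' is reported with the rule that caused it.
#'
#' @param source a taxonomy graph (typically from [read_paleodb_table()]).
#' @param status the status data.frame from [read_paleodb_table()]; must
#'   cover all source terms.
#' @param rules list of [filter_rule()] objects.
#' @return a list: \code{graph} (filtered), \code{filtered} — data.frame
#'   (\code{name}, \code{rule}) of removals.
#' @export
filter_source <- function(source, status, rules = default_filter_rules()) {
  st <- status[!is.na(status$id), , drop = FALSE]
  st <- st[!duplicated(st$id), , drop = FALSE]
  rownames(st) <- st$id
  missing <- setdiff(term_ids(source), st$id)
  if (length(missing)) {
    stop("status table does not cover term ", missing[1])
  }

  drop_ids <- character(0); drop_rule <- character(0)
  for (id in term_ids(source)) {
    row <- st[id, , drop = FALSE]
    for (rule in rules) {
      if (isTRUE(rule_fails(rule, row))) {
        drop_ids <- c(drop_ids, id)
        drop_rule <- c(drop_rule, rule$kind)
        break
      }
    }
  }

  parents <- graph_parents(source)
  nearest_survivor <- function(id) {
    cur <- parents[[id]]
    seen <- character(0)
    while (!is.na(cur) && !(cur %in% seen)) {
      if (!(cur %in% drop_ids)) return(cur)
      seen <- c(seen, cur)
      cur <- parents[[cur]]
    }
    NA_character_
  }
  names_by_id <- graph_term_names(source)
  filtered_names <- unname(names_by_id[drop_ids])
  for (id in setdiff(term_ids(source), drop_ids)) {
    p <- parents[[id]]
    if (!is.na(p) && p %in% drop_ids) {
      t <- source$terms[[id]]
      t$parent <- nearest_survivor(id)
      source$terms[[id]] <- t
    }
  }
  source$terms[drop_ids] <- NULL
  list(graph = source,
       filtered = data.frame(name = filtered_names, rule = drop_rule,
                             stringsAsFactors = FALSE))
}

# Ancestry name list (nearest first) to try when placing a fossil subtree
# root: the original in-table ancestor chain (including removed terms),
# terminated by the first out-of-table parent name.
fossil_root_ancestry <- function(status, root_name) {
  st <- status[!is.na(status$id), , drop = FALSE]
  st <- st[!duplicated(st$name), , drop = FALSE]
  rownames(st) <- st$name
  out <- character(0)
  cur <- root_name
  seen <- character(0)
  repeat {
    if (!(cur %in% rownames(st)) || cur %in% seen) break
    seen <- c(seen, cur)
    p <- st[cur, "parent_name"]
    if (!nzchar(p)) break
    out <- c(out, p)
    cur <- p
  }
  out
}

#' Graft a subtree at the lowest inclusive node of a target graph
#'
#' Places one fossil subtree into the proto-ontology. Walking the subtree
#' top-down: a subtree term whose name matches an existing (non-obsolete)
#' target term — uniquely, or disambiguated by rank — is merged into it
#' (synonyms and xrefs unioned, its id recorded as an xref; no duplicate
#' term is created) and its children are placed beneath that term.
#' Unmatched terms are installed as new terms. The subtree root itself,
#' when unmatched, becomes a child of the first name in \code{ancestry}
#' that resolves in the target; if none resolves it is attached at the
#' target's root and reported as unplaced.
#'
#' @param target a taxonomy graph with a single root.
#' @param subtree a taxonomy graph containing the subtree.
#' @param subtree_root id of the subtree's root within \code{subtree}.
#' @param ancestry character vector of the root's ancestor names in the
#'   source, nearest first.
#' @return a list: \code{graph}, \code{mapping} (subtree id -> target id),
#'   \code{merged} (count of name-merged terms), \code{unplaced} (TRUE if
#'   the root fell back to the target root).
#' @export
attach_at_lowest_inclusive <- function(target, subtree, subtree_root,
                                       ancestry = character(0)) {
  idx <- name_index(target)
  non_obsolete <- function(ids) {
    ids[!vapply(target$terms[ids], function(t) t$is_obsolete, logical(1))]
  }
  resolve_name <- function(nmv, rank) {
    cand <- non_obsolete(idx[[normalize_name(nmv)]] %||% character(0))
    if (!length(cand)) return(NA_character_)
    disambiguate(target, cand, rank, character(0))
  }

  order <- c(subtree_root, descendants(subtree, subtree_root))
  mapping <- character(0)
  merges <- list()
  merged <- 0L
  unplaced <- FALSE
  for (id in order) {
    t <- subtree$terms[[id]]
    hit <- resolve_name(t$name, t$rank)
    if (!is.na(hit)) {
      res <- absorb_term(target, hit, t)
      target <- res$graph
      merges[[length(merges) + 1L]] <- res$merge
      mapping[id] <- hit
      merged <- merged + 1L
      next
    }
    if (identical(id, subtree_root) || is.na(t$parent)) {
      parent <- NA_character_
      for (a in ancestry) {
        parent <- resolve_name(a, NA_character_)
        if (!is.na(parent)) break
      }
      if (is.na(parent)) {
        parent <- graph_root(target)
        unplaced <- TRUE
      }
    } else {
      parent <- mapping[[t$parent]]
    }
    t$parent <- parent
    if (has_term(target, t$id)) {
      stop("subtree term id ", t$id, " already present in target")
    }
    target$terms[[t$id]] <- t
    idx[[normalize_name(t$name)]] <-
      c(idx[[normalize_name(t$name)]], t$id)
    mapping[id] <- t$id
  }
  list(graph = target, mapping = mapping, merged = merged,
       unplaced = unplaced, merges = merges)
}

# --------------------------------------------------------------------------
# Obsoletion, subspecies demotion, id assignment

#' Obsolete disused taxa
#'
#' Each disused term is marked obsolete and loses its parent edge; each
#' non-disused child of a disused term is re-attached at the graph root.
#'
#' @param graph a taxonomy graph with a single root.
#' @param disused character vector of term ids to obsolete.
#' @return a list: \code{graph}, \code{reattached} (ids re-parented to the
#'   root).
#' @export
obsolete_disused <- function(graph, disused) {
  if (length(bad <- setdiff(disused, term_ids(graph)))) {
    stop("unknown term id in disused set: ", bad[1])
  }
  if (!length(disused)) {
    return(list(graph = graph, reattached = character(0)))
  }
  root <- graph_root(graph)
  if (root %in% disused) stop("the graph root cannot be obsoleted")
  p <- graph_parents(graph)
  reattach <- names(p)[!is.na(p) & p %in% disused & !(names(p) %in% disused)]
  for (id in reattach) {
    t <- graph$terms[[id]]
    t$parent <- root
    graph$terms[[id]] <- t
  }
  for (id in disused) {
    t <- graph$terms[[id]]
    t$parent <- NA_character_
    t$is_obsolete <- TRUE
    graph$terms[[id]] <- t
  }
  list(graph = graph, reattached = sort_c(reattach))
}

#' Demote subspecies to typed synonyms of their species
#'
#' Every leaf term ranked subspecies whose parent is ranked species is
#' removed as a term: its primary name becomes a NARROW synonym with type
#' tag \code{SUBSPECIES} on the parent, and its own synonyms and xrefs (and
#' id, as an xref) are merged into the parent. Subspecies with a non-species
#' parent, or with children, are left in place and reported.
#'
#' @param graph a taxonomy graph.
#' @param vocab a rank vocabulary.
#' @return a list: \code{graph}, \code{demoted} — data.frame
#'   (\code{subspecies}, \code{species_id}), \code{skipped} — character
#'   vector of subspecies ids left in place.
#' @export
demote_subspecies <- function(graph, vocab = default_rank_vocabulary()) {
  subsp_rank <- rank_lookup(vocab, "subspecies")
  species_rank <- rank_lookup(vocab, "species")
  ranks <- vapply(graph$terms, function(t) t$rank, character(1))
  cand <- names(ranks)[!is.na(ranks) & ranks == subsp_rank]
  ch <- children_map(graph)
  demoted_name <- character(0); demoted_into <- character(0)
  skipped <- character(0)
  for (id in sort_c(cand)) {
    t <- graph$terms[[id]]
    pid <- t$parent
    parent_ok <- !is.na(pid) && has_term(graph, pid) &&
      identical(graph$terms[[pid]]$rank, species_rank)
    if (!parent_ok || length(ch[[id]] %||% character(0))) {
      skipped <- c(skipped, id)
      next
    }
    sp <- graph$terms[[pid]]
    sp$synonyms <- dedup_synonyms(rbind(
      sp$synonyms,
      synonym_record(t$name, "NARROW", "SUBSPECIES", t$source),
      t$synonyms))
    sp$xrefs <- sort_c(union(sp$xrefs, c(t$xrefs, t$id)))
    graph$terms[[pid]] <- sp
    graph$terms[[id]] <- NULL
    demoted_name <- c(demoted_name, t$name)
    demoted_into <- c(demoted_into, pid)
  }
  list(graph = graph,
       demoted = data.frame(subspecies = demoted_name,
                            species_id = demoted_into,
                            stringsAsFactors = FALSE),
       skipped = skipped)
}

# --------------------------------------------------------------------------
# Stable identifier assignment

stable_keys <- function(graph) {
  keys <- vapply(graph$terms, function(t) {
    paste(normalize_name(t$name), t$source, sep = "\t")
  }, character(1))
  # duplicate keys (deliberate homonyms within one source) get a
  # deterministic ordinal suffix by current term id
  if (anyDuplicated(keys)) {
    ord <- order_c(names(keys))
    keys <- keys[ord]
    dup <- stats::ave(seq_along(keys), keys, FUN = seq_along)
    keys[dup > 1] <- paste0(keys[dup > 1], "\t#", dup[dup > 1])
    keys <- keys[names(graph$terms)]  # restore original order
  }
  keys
}

#' Assign stable release identifiers
#'
#' Remints every term id into the release namespace. Terms whose stable key
#' (normalized primary name + source label of first introduction) appears in
#' \code{prior} keep their prior id; new terms get sequential ids after the
#' prior maximum, assigned in sorted-key order. Retired ids are never
#' reused: the returned registry is the prior registry plus the new
#' assignments. Each term's pre-assignment id is retained as an xref, which
#' is the cross-reference provenance mechanism of the product ontology.
#'
#' @param graph a taxonomy graph.
#' @param namespace_prefix id namespace of the release, e.g. \code{"TXO"}.
#' @param prior optional named character vector (stable key -> term id) from
#'   the previous release.
#' @return a list: \code{graph} (reminted), \code{registry} (named character
#'   vector, stable key -> id, for the new release).
#' @export
assign_ids <- function(graph, namespace_prefix, prior = NULL) {
  prior <- prior %||% character(0)
  if (anyDuplicated(prior)) {
    stop("prior registry maps two keys to the same id: ",
         prior[duplicated(prior)][1])
  }
  keys <- stable_keys(graph)
  known <- keys %in% names(prior)
  start <- if (length(prior)) max(id_local_number(prior), na.rm = TRUE)
           else 0L
  new_keys <- sort_c(keys[!known])
  new_ids <- make_term_id(namespace_prefix, start + seq_along(new_keys))
  names(new_ids) <- new_keys

  id_map <- character(length(keys))
  names(id_map) <- names(keys)
  id_map[known] <- prior[keys[known]]
  id_map[!known] <- new_ids[keys[!known]]

  out <- taxonomy_graph(ontology = graph$ontology)
  for (old in names(graph$terms)) {
    t <- graph$terms[[old]]
    t$id <- unname(id_map[[old]])
    if (!is.na(t$parent)) t$parent <- unname(id_map[[t$parent]])
    if (id_prefix(old) != namespace_prefix) {
      t$xrefs <- sort_c(union(t$xrefs, old))
    }
    out$terms[[t$id]] <- t
  }
  registry <- prior
  registry[keys] <- unname(id_map)
  list(graph = out, registry = registry, id_map = id_map)
}

#' Read and write an id registry
#'
#' The registry is a two-column TSV mapping stable keys (primary name +
#' source label, tab-joined) to term ids; it is the cross-release memory
#' that keeps identifiers stable as sources are updated.
#'
#' @param path file path.
#' @return \code{read_id_registry}: named character vector.
#' @export
read_id_registry <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(character(0))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("malformed registry line ", bad[1], " in ", path)
  ids <- vapply(parts, function(p) p[[length(p)]], character(1))
  keys <- vapply(parts, function(p) {
    paste(p[-length(p)], collapse = "\t")
  }, character(1))
  stats::setNames(ids, keys)
}

#' @rdname read_id_registry
#' @param registry named character vector (key -> id).
#' @export
write_id_registry <- function(registry, path) {
  keys <- sort_c(names(registry))
  write_lines_atomic(paste(keys, registry[keys], sep = "\t"), path)
}
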