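# Readers for the source dialects: NCBI-taxdump-style dumps, flat tabular
# checklists (AmphibiaWeb amphib_names.txt style), and PaleoDB-style tabular
# exports with taxon status fields.

parse_dmp <- function(path) {
  lines <- read_text_lines(path)
  # a sentinel keeps trailing empty fields (strsplit drops them otherwise)
  lines <- paste0(sub("\t\\|$", "", lines), "\x01")
  parts <- strsplit(lines, "\t\\|\t")
  lapply(parts, function(p) {
    p[length(p)] <- sub("\x01$", "", p[length(p)])
    p
  })
}

#' Read an NCBI-taxdump-style dump into a taxonomy graph
#'
#' The taxdump dialect separates fields with tab-pipe-tab and terminates
#' records with tab-pipe. \code{nodes} records carry (tax_id, parent_tax_id,
#' rank); \code{names} records carry (tax_id, name_txt, unique name, name
#' class). The record whose parent equals itself is the root. The name class
#' \code{"scientific name"} becomes the primary name; \code{"synonym"}
#' becomes a RELATED/TAXONOMIC synonym and the common-name classes become
#' COMMONNAME synonyms. Every term carries an \code{xref} of the form
#' \code{prefix:tax_id} recording its source record.
#'
#' @param names_path path to the names dump.
#' @param nodes_path path to the nodes dump.
#' @param prefix id namespace for the loaded terms (default
#'   \code{"NCBI"}-style).
#' @param source source label recorded on the terms.
#' @param vocab rank vocabulary used to map the rank strings.
#' @return a [taxonomy_graph()].
#' @export
read_ncbi_taxdump <- function(names_path, nodes_path, prefix = "NCBI",
                              source = "ncbi",
                              vocab = default_rank_vocabulary()) {
  nodes <- parse_dmp(nodes_path)
  bad <- which(lengths(nodes) < 3)
  if (length(bad)) {
    stop("malformed nodes record at line ", bad[1], " (", nodes_path, ")")
  }
  nms <- parse_dmp(names_path)
  bad <- which(lengths(nms) < 4)
  if (length(bad)) {
    stop("malformed names record at line ", bad[1], " (", names_path, ")")
  }

  tax_id <- vapply(nodes, `[[`, character(1), 1)
  parent_id <- vapply(nodes, `[[`, character(1), 2)
  rank_str <- vapply(nodes, `[[`, character(1), 3)
  if (anyDuplicated(tax_id)) {
    stop("duplicate tax_id in nodes dump: ", tax_id[duplicated(tax_id)][1])
  }
  missing_parent <- setdiff(parent_id, tax_id)
  if (length(missing_parent)) {
    stop("dangling parent_tax_id in nodes dump: ", missing_parent[1])
  }

  n_tax <- vapply(nms, `[[`, character(1), 1)
  n_txt <- vapply(nms, `[[`, character(1), 2)
  n_class <- vapply(nms, `[[`, character(1), 4)
  if (length(unknown <- setdiff(n_tax, tax_id))) {
    stop("names record for unknown tax_id ", unknown[1])
  }

  sci <- split(n_txt[n_class == "scientific name"],
               n_tax[n_class == "scientific name"])
  syn_class <- n_class %in% c("synonym", "common name",
                              "genbank common name")
  syn_by_tax <- split(seq_along(n_tax)[syn_class], n_tax[syn_class])

  g <- taxonomy_graph(ontology = source)
  for (i in seq_along(tax_id)) {
    tid <- tax_id[i]
    primary <- sci[[tid]]
    if (is.null(primary) || length(primary) != 1) {
      stop("tax_id ", tid, " must have exactly one scientific name (has ",
           length(primary), ")")
    }
    syns <- empty_synonyms()
    for (j in syn_by_tax[[tid]]) {
      if (n_class[j] == "synonym") {
        syns <- rbind(syns, synonym_record(n_txt[j], "RELATED", "TAXONOMIC",
                                           source))
      } else {
        syns <- rbind(syns, synonym_record(n_txt[j], "EXACT", "COMMONNAME",
                                           source))
      }
    }
    # taxdump ids stay unpadded (NCBI-style "prefix:tax_id"); the id doubles
    # as the provenance xref
    term <- taxon_term(
      id = paste0(prefix, ":", tid), name = primary,
      parent = if (parent_id[i] == tid) NA_character_
               else paste0(prefix, ":", parent_id[i]),
      synonyms = dedup_synonyms(syns),
      xrefs = paste0(prefix, ":", tid),
      source = source)
    g <- add_term(g, annotate_rank(term, rank_str[i], vocab))
  }
  g
}

#' Read a flat tabular checklist into a taxonomy graph
#'
#' Builds a tree from a delimited checklist with one species per row
#' (AmphibiaWeb \code{amphib_names.txt} style): ordered higher-taxon columns
#' (e.g. order, family), a genus column and a species-epithet column. One
#' term is materialized per distinct value-path of the higher-taxon columns,
#' so the same family name under two different orders yields two terms.
#' Species primary names are \code{"genus epithet"}. Duplicate rows are
#' idempotent.
#'
#' @param path path to the delimited file.
#' @param column_spec a list describing column roles: \code{higher} — a named
#'   character vector, names are rank names and values are column names, in
#'   hierarchical order; \code{genus}, \code{epithet} — column names;
#'   optional \code{common_name} (attached as a COMMONNAME synonym) and
#'   \code{synonyms} (separator-joined scientific synonyms, attached as
#'   TAXONOMIC synonyms); optional \code{synonym_sep} (default \code{"|"});
#'   optional \code{root_name}/\code{root_rank} — when given, a single root
#'   term with that name is created above the highest taxon column, so the
#'   checklist loads as one tree and can be grafted at a named backbone node
#'   (flat checklists usually omit the clade they cover).
#' @param prefix id namespace for the loaded terms.
#' @param source source label.
#' @param delim field delimiter (default tab).
#' @param vocab rank vocabulary.
#' @return a [taxonomy_graph()].
#' @export
read_tabular_taxonomy <- function(path, column_spec, prefix = "TAB",
                                  source = "tabular", delim = "\t",
                                  vocab = default_rank_vocabulary()) {
  tab <- utils::read.delim(path, sep = delim, colClasses = "character",
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  need <- c(unname(column_spec$higher), column_spec$genus,
            column_spec$epithet)
  if (length(absent <- setdiff(need, names(tab)))) {
    stop("required column missing from ", path, ": ", absent[1])
  }
  sep <- column_spec$synonym_sep %||% "|"

  g <- taxonomy_graph(ontology = source)
  counter <- 0L
  path_ids <- character(0)  # joined value path -> term id
  new_id <- function() {
    counter <<- counter + 1L
    make_term_id(prefix, counter)
  }
  ensure_path_term <- function(key, name, parent, rank_nm) {
    if (!is.na(path_ids[key])) return(path_ids[[key]])
    id <- new_id()
    term <- taxon_term(id, name, parent = parent,
                       xrefs = id, source = source)
    g <<- add_term(g, annotate_rank(term, rank_nm, vocab))
    path_ids[key] <<- id
    id
  }

  root_id <- NA_character_
  if (!is.null(column_spec$root_name)) {
    root_id <- new_id()
    root <- taxon_term(root_id, column_spec$root_name, xrefs = root_id,
                       source = source)
    g <- add_term(g, annotate_rank(root, column_spec$root_rank %||% "",
                                   vocab))
  }

  higher_cols <- column_spec$higher
  for (r in seq_len(nrow(tab))) {
    genus <- normalize_name(tab[r, column_spec$genus])
    epithet <- normalize_name(tab[r, column_spec$epithet])
    if (!nzchar(genus) || !nzchar(epithet)) {
      stop("blank genus or epithet on data row ", r, " of ", path)
    }
    parent <- root_id
    key <- ""
    for (k in seq_along(higher_cols)) {
      val <- normalize_name(tab[r, higher_cols[[k]]])
      if (!nzchar(val)) next
      key <- paste(key, val, sep = "/")
      parent <- ensure_path_term(key, val, parent, names(higher_cols)[k])
    }
    key <- paste(key, genus, sep = "/")
    parent <- ensure_path_term(key, genus, parent, "genus")
    skey <- paste(key, epithet, sep = "/")
    sp_name <- paste(genus, epithet)
    if (is.na(path_ids[skey])) {
      id <- new_id()
      term <- taxon_term(id, sp_name, parent = parent, xrefs = id,
                         source = source)
      g <- add_term(g, annotate_rank(term, "species", vocab))
      path_ids[skey] <- id
    }
    id <- path_ids[[skey]]
    t <- g$terms[[id]]
    if (!is.null(column_spec$common_name)) {
      cn <- normalize_name(tab[r, column_spec$common_name])
      if (nzchar(cn)) {
        t$synonyms <- dedup_synonyms(rbind(
          t$synonyms, synonym_record(cn, "EXACT", "COMMONNAME", source)))
      }
    }
    if (!is.null(column_spec$synonyms)) {
      sy <- strsplit(tab[r, column_spec$synonyms], sep, fixed = TRUE)[[1]]
      sy <- normalize_name(sy)
      sy <- sy[nzchar(sy)]
      if (length(sy)) {
        t$synonyms <- dedup_synonyms(rbind(
          t$synonyms, synonym_record(sy, "RELATED", "TAXONOMIC", source)))
      }
    }
    g$terms[[id]] <- t
  }
  g
}

#' Read a PaleoDB-style tabular export
#'
#' Consumes a normalized 7-column table: \code{taxon_name}, \code{rank},
#' \code{parent_name}, \code{validity} (VALID / INVALID / SYNONYM_OF /
#' DISUSED), \code{senior_name} (when SYNONYM_OF), \code{material_class}
#' (BODY_DIAGNOSTIC / TRACE / EGG / OTHER_NONDIAGNOSTIC) and
#' \code{is_extinct} (true/false). VALID, DISUSED and INVALID rows become
#' terms; all exclusion (non-diagnostic material, invalid names, taxa
#' lacking a parent classification) is the merge engine's job, see
#' [filter_source()]. SYNONYM_OF rows whose senior is in the table become
#' TAXONOMIC synonyms on the senior term; otherwise they are only recorded
#' in the status table. Rows whose parent name is not found in the table are
#' loaded parentless and flagged (\code{parent_in_table = FALSE}) — such
#' subtree roots are later placed by [attach_at_lowest_inclusive()].
#'
#' @param path path to the delimited file.
#' @param prefix id namespace for the loaded terms.
#' @param source source label.
#' @param delim field delimiter.
#' @param vocab rank vocabulary.
#' @return a list with components \code{graph} (a [taxonomy_graph()]) and
#'   \code{status} — a data.frame with one row per input row: \code{id}
#'   (NA for synonym-only rows), \code{name}, \code{rank},
#'   \code{parent_name}, \code{validity}, \code{senior_name},
#'   \code{material_class}, \code{is_extinct}, \code{parent_in_table},
#'   \code{line}.
#' @export
read_paleodb_table <- function(path, prefix = "PBDB", source = "paleodb",
                               delim = "\t",
                               vocab = default_rank_vocabulary()) {
  tab <- utils::read.delim(path, sep = delim, colClasses = "character",
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  need <- c("taxon_name", "rank", "parent_name", "validity", "senior_name",
            "material_class", "is_extinct")
  if (length(absent <- setdiff(need, names(tab)))) {
    stop("required column missing from ", path, ": ", absent[1])
  }
  validity <- toupper(normalize_name(tab$validity))
  ok_validity <- c("VALID", "INVALID", "SYNONYM_OF", "DISUSED")
  if (length(bad <- which(!validity %in% ok_validity))) {
    stop("unknown validity \"", tab$validity[bad[1]], "\" at data row ",
         bad[1], " of ", path)
  }
  nm <- normalize_name(tab$taxon_name)
  parent_nm <- normalize_name(tab$parent_name)
  senior <- normalize_name(tab$senior_name)
  senior[senior == "-"] <- ""
  if (any(validity == "SYNONYM_OF" & !nzchar(senior))) {
    stop("SYNONYM_OF row without a senior_name in ", path)
  }
  extinct <- tolower(normalize_name(tab$is_extinct)) %in%
    c("true", "t", "1", "yes", "extinct")

  is_term_row <- validity != "SYNONYM_OF"
  ids <- rep(NA_character_, nrow(tab))
  ids[is_term_row] <- make_term_id(prefix, cumsum(is_term_row)[is_term_row])
  # first term row bearing each name wins parent resolution
  name_to_id <- ids[is_term_row][!duplicated(nm[is_term_row])]
  names(name_to_id) <- nm[is_term_row][!duplicated(nm[is_term_row])]

  parent_in_table <- nzchar(parent_nm) & parent_nm %in% names(name_to_id)

  g <- taxonomy_graph(ontology = source)
  for (i in which(is_term_row)) {
    term <- taxon_term(
      id = ids[i], name = nm[i],
      parent = if (parent_in_table[i]) unname(name_to_id[parent_nm[i]])
               else NA_character_,
      xrefs = ids[i], is_extinct = extinct[i], source = source)
    g <- add_term(g, annotate_rank(term, tab$rank[i], vocab))
  }
  # self-parent guard (a name equal to its own parent would self-loop)
  for (i in which(is_term_row & parent_in_table)) {
    if (identical(g$terms[[ids[i]]]$parent, ids[i])) {
      t <- g$terms[[ids[i]]]
      t$parent <- NA_character_
      g$terms[[ids[i]]] <- t
      parent_in_table[i] <- FALSE
    }
  }
  for (i in which(validity == "SYNONYM_OF")) {
    sid <- name_to_id[senior[i]]
    if (!is.na(sid)) {
      t <- g$terms[[sid]]
      t$synonyms <- dedup_synonyms(rbind(
        t$synonyms, synonym_record(nm[i], "RELATED", "TAXONOMIC", source)))
      g$terms[[sid]] <- t
    }
  }

  status <- data.frame(
    id = ids, name = nm, rank = normalize_name(tab$rank),
    parent_name = parent_nm, validity = validity, senior_name = senior,
    material_class = toupper(normalize_name(tab$material_class)),
    is_extinct = extinct, parent_in_table = parent_in_table,
    line = seq_len(nrow(tab)) + 1L, stringsAsFactors = FALSE)
  list(graph = g, status = status)
}
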