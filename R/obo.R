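# Deterministic OBO 1.2 reader and writer for the product ontology.
#
# Dialect: [Term] stanzas with id, name, is_a, synonym (scope keyword plus an
# optional bare author-defined type token), xref, comment, is_obsolete, and
# property_value lines for has_rank (rank-vocabulary id) and is_extinct
# (xsd:boolean), following the pattern used to render the NCBI taxonomy in
# OBO. Unrecognized tags are preserved opaquely per term for round-tripping.

obo_tag_split <- function(lines) {
  m <- regexpr(": ", lines, fixed = TRUE)
  tag <- substr(lines, 1L, m - 1L)
  value <- substr(lines, m + 2L, nchar(lines))
  list(tag = tag, value = value, ok = m > 0L)
}

strip_obo_comment <- function(x) sub("[ \t]+!.*$", "", x)

parse_obo_synonym <- function(value, source) {
  # synonym: "NAME" SCOPE [TYPETOKEN] [dbxrefs]
  m <- regmatches(value, regexec(
    '^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z]+)?\\s*([A-Za-z0-9_]+)?\\s*(\\[.*\\])?\\s*$',
    value))[[1]]
  if (length(m) == 0) stop("malformed synonym line: ", value)
  nm <- gsub('\\\\(.)', "\\1", m[2])
  scope <- if (nzchar(m[3])) m[3] else "RELATED"
  type <- if (nzchar(m[4])) m[4] else "TAXONOMIC"
  synonym_record(nm, scope = scope, type = type, source = source)
}

#' Read an OBO 1.2 ontology into a taxonomy graph
#'
#' @param path path to an OBO file (optionally gzip-compressed) or a
#'   connection.
#' @param source source label recorded on every term read.
#' @return a [taxonomy_graph()].
#' @export
read_obo <- function(path, source = "obo") {
  lines <- read_text_lines(path)
  lines <- sub("\r$", "", lines)
  stanza_start <- grepl("^\\[", lines)
  stanza_id <- cumsum(stanza_start)
  stanza_type <- character(max(stanza_id, 0) + 1L)
  stanza_type[1L] <- "header"
  if (any(stanza_start)) {
    stanza_type[unique(stanza_id[stanza_start]) + 1L] <- lines[stanza_start]
  }

  header <- lines[stanza_id == 0L & nzchar(lines)]
  ontology <- "taxonomy"
  h <- obo_tag_split(header)
  if (any(h$ok & h$tag == "ontology")) {
    ontology <- h$value[h$ok & h$tag == "ontology"][1]
  }

  g <- taxonomy_graph(ontology = ontology)
  known <- c("id", "name", "is_a", "synonym", "xref", "comment",
             "is_obsolete", "property_value")
  for (s in seq_len(max(stanza_id, 0))) {
    if (stanza_type[s + 1L] != "[Term]") next  # [Typedef] etc. skipped
    body <- lines[stanza_id == s & !stanza_start[seq_along(lines)]]
    body <- body[nzchar(body) & !grepl("^!", body)]
    tv <- obo_tag_split(body)
    if (any(!tv$ok)) stop("malformed OBO line: ", body[!tv$ok][1])
    tag <- tv$tag; value <- tv$value

    id <- strip_obo_comment(value[tag == "id"])
    if (length(id) != 1) stop("[Term] stanza without exactly one id (line ~",
                              which(stanza_id == s)[1], ")")
    if (has_term(g, id)) stop("duplicate term id in OBO input: ", id)
    nm <- value[tag == "name"]
    if (length(nm) != 1) stop("term ", id, " must have exactly one name")
    isa <- strip_obo_comment(value[tag == "is_a"])
    if (length(isa) > 1) {
      stop("term ", id, " has multiple is_a parents; the taxonomy is a tree")
    }
    syns <- empty_synonyms()
    for (v in value[tag == "synonym"]) {
      syns <- rbind(syns, parse_obo_synonym(v, source))
    }
    xrefs <- strip_obo_comment(value[tag == "xref"])
    obsolete <- any(tag == "is_obsolete" &
                      strip_obo_comment(value) == "true")
    comment <- if (any(tag == "comment")) value[tag == "comment"][1]
               else NA_character_

    rank <- NA_character_
    extinct <- FALSE
    extra <- character(0)
    for (v in value[tag == "property_value"]) {
      v2 <- strip_obo_comment(v)
      if (grepl("^has_rank ", v2)) {
        rank <- sub("^has_rank +", "", v2)
      } else if (grepl("^is_extinct ", v2)) {
        extinct <- grepl("\"true\"", v2, fixed = TRUE)
      } else {
        extra <- c(extra, paste0("property_value: ", v))
      }
    }
    unknown <- !(tag %in% known)
    if (any(unknown)) {
      extra <- c(extra, paste0(tag[unknown], ": ", value[unknown]))
    }

    g <- add_term(g, taxon_term(
      id = id, name = nm,
      parent = if (length(isa) == 1) isa else NA_character_,
      rank = rank, synonyms = syns, xrefs = xrefs,
      is_extinct = extinct, is_obsolete = obsolete,
      comment = comment, source = source, extra = extra))
  }

  p <- graph_parents(g)
  dangling <- p[!is.na(p) & !(p %in% names(p))]
  if (length(dangling)) {
    stop("is_a target not defined in file: ", dangling[[1]],
         " (referenced by ", names(dangling)[1], ")")
  }
  g
}

format_obo_synonyms <- function(syn) {
  if (nrow(syn) == 0) return(character(0))
  esc <- gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", syn$name))
  sort_c(sprintf("synonym: \"%s\" %s %s []", esc, syn$scope, syn$type))
}

#' Write a taxonomy graph as canonical OBO 1.2
#'
#' Serialization is canonical: stanzas sorted by term id, tags in fixed
#' order, synonym/xref lines sorted in C collation — so two writes of equal
#' graphs are byte-identical regardless of in-memory insertion order.
#' Refuses graphs whose [validate_taxonomy()] report contains cycles or
#' unresolved parents.
#'
#' @param graph a taxonomy graph.
#' @param path output file path.
#' @param date optional date string for the header; omitted by default so
#'   rebuilds from identical inputs are byte-identical.
#' @return the path, invisibly.
#' @export
write_obo <- function(graph, path, date = NULL) {
  rep <- validate_taxonomy(graph, vocab = NULL)
  codes <- vapply(rep, function(f) f$code, character(1))
  hard <- codes %in% c("CYCLE", "UNRESOLVED_PARENT")
  if (any(hard)) {
    stop("graph fails validation; first finding: ",
         rep[[which(hard)[1]]]$message)
  }
  out <- c("format-version: 1.2",
           if (!is.null(date)) paste0("date: ", date),
           paste0("ontology: ", graph$ontology),
           "")
  nm <- graph_term_names(graph)
  chunks <- lapply(sort_c(term_ids(graph)), function(id) {
    t <- graph$terms[[id]]
    c("[Term]",
      paste0("id: ", t$id),
      paste0("name: ", t$name),
      if (!is.na(t$parent))
        paste0("is_a: ", t$parent, " ! ", nm[[t$parent]]),
      format_obo_synonyms(t$synonyms),
      if (length(t$xrefs)) paste0("xref: ", sort_c(t$xrefs)),
      if (!is.na(t$rank)) paste0("property_value: has_rank ", t$rank),
      if (t$is_extinct) "property_value: is_extinct \"true\" xsd:boolean",
      if (!is.na(t$comment)) paste0("comment: ", t$comment),
      if (t$is_obsolete) "is_obsolete: true",
      if (length(t$extra)) sort_c(t$extra),
      "")
  })
  write_lines_atomic(c(out, unlist(chunks)), path)
}
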