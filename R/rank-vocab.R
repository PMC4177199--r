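# TAXRANK-style controlled vocabulary of taxonomic ranks: canonical names,
# aliases used by source taxonomies, and an integer level on the standard
# Linnaean ladder giving the partial order used for rank-inversion checks
# and lowest-inclusive-node logic.

rank_free_aliases <- c("", "no rank", "unranked", "clade")

#' Build a rank vocabulary from a definition table
#'
#' The vocabulary is data, not code: a table of canonical rank names, an
#' optional integer level (smaller = more inclusive, so kingdom < species),
#' and pipe-separated aliases from source vocabularies. Ranks without a
#' level (e.g. botanical-only ranks) are incomparable to all others.
#'
#' @param definitions a data.frame with columns \code{canonical_name},
#'   \code{level} (integer or NA), \code{aliases} (pipe-separated string),
#'   or a path to a TSV file with those columns.
#' @param prefix namespace prefix for rank term ids.
#' @return an object of class \code{rank_vocabulary}.
#' @export
build_rank_vocab <- function(definitions, prefix = "RANK") {
  if (is.character(definitions)) {
    definitions <- utils::read.delim(definitions, stringsAsFactors = FALSE,
                                     colClasses = c("character", "integer",
                                                    "character"))
  }
  stopifnot(all(c("canonical_name", "level", "aliases") %in%
                  names(definitions)))
  cn <- normalize_name(definitions$canonical_name)
  if (anyDuplicated(cn)) {
    stop("duplicate canonical rank name: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  }
  ids <- make_term_id(prefix, seq_along(cn))
  terms <- vector("list", length(cn))
  names(terms) <- ids
  alias_map <- character(0)
  for (i in seq_along(cn)) {
    raw <- definitions$aliases[i]
    if (length(raw) == 0 || is.na(raw)) raw <- ""
    aliases <- strsplit(raw, "|", fixed = TRUE)[[1]]
    aliases <- normalize_name(aliases)
    aliases <- unique(c(cn[i], aliases[nzchar(aliases)]))
    terms[[i]] <- list(id = ids[i], name = cn[i],
                       level = definitions$level[i],
                       aliases = aliases)
    for (a in aliases) {
      if (a %in% names(alias_map) && alias_map[[a]] != ids[i]) {
        stop(sprintf("rank alias \"%s\" maps to both %s (%s) and %s (%s)",
                     a, alias_map[[a]],
                     terms_name_of(terms, alias_map[[a]]), ids[i], cn[i]))
      }
      alias_map[[a]] <- ids[i]
    }
  }
  structure(list(terms = terms, alias_map = alias_map, prefix = prefix),
            class = "rank_vocabulary")
}

terms_name_of <- function(terms, id) terms[[id]]$name

#' @export
print.rank_vocabulary <- function(x, ...) {
  cat(sprintf("<rank_vocabulary> %d ranks (%d leveled), prefix %s\n",
              length(x$terms),
              sum(!vapply(x$terms, function(t) is.na(t$level), logical(1))),
              x$prefix))
  invisible(x)
}

#' The packaged default rank vocabulary
#'
#' Covers the standard Linnaean ladder plus the intercalated ranks used by
#' major taxonomic databases (superfamily, subfamily, tribe, infraorder,
#' species group, ...), with the NCBI-taxonomy rank strings as aliases.
#' Botanical-only ranks ship without a level and are therefore incomparable.
#'
#' @return a \code{rank_vocabulary}.
#' @export
default_rank_vocabulary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "rank_vocabulary.tsv",
                          package = "taxograft", mustWork = TRUE)
      cache <<- build_rank_vocab(path)
    }
    cache
  }
})

#' Resolve a rank name or alias to its rank id
#'
#' @param vocab a rank vocabulary.
#' @param name canonical rank name or source alias.
#' @return the rank id, or \code{NA_character_} if the name does not resolve
#'   (including the rank-free markers \code{""}, \code{"no rank"},
#'   \code{"unranked"}, \code{"clade"}).
#' @export
rank_lookup <- function(vocab, name) {
  name <- normalize_name(name)
  if (name %in% rank_free_aliases) return(NA_character_)
  unname(vocab$alias_map[name])  # NA when absent
}

#' Canonical name of a rank id
#' @param vocab a rank vocabulary.
#' @param id a rank id.
#' @return canonical rank name string.
#' @export
rank_name <- function(vocab, id) {
  t <- vocab$terms[[id]]
  if (is.null(t)) stop("unknown rank id: ", id)
  t$name
}

rank_level <- function(vocab, id) {
  t <- vocab$terms[[id]]
  if (is.null(t)) return(NA_integer_)
  t$level
}

#' Compare two ranks
#'
#' \code{"LOWER"} means \code{a} is less inclusive than \code{b} (species is
#' LOWER than genus); \code{"INCOMPARABLE"} when either rank lacks a level.
#'
#' @param vocab a rank vocabulary.
#' @param a,b rank ids present in the vocabulary.
#' @return one of \code{"LOWER"}, \code{"HIGHER"}, \code{"EQUAL"},
#'   \code{"INCOMPARABLE"}.
#' @export
rank_order <- function(vocab, a, b) {
  ta <- vocab$terms[[a]]; tb <- vocab$terms[[b]]
  if (is.null(ta)) stop("unknown rank id: ", a)
  if (is.null(tb)) stop("unknown rank id: ", b)
  if (identical(a, b)) return("EQUAL")
  if (is.na(ta$level) || is.na(tb$level)) return("INCOMPARABLE")
  if (ta$level == tb$level) return("EQUAL")
  if (ta$level > tb$level) "LOWER" else "HIGHER"
}

#' Annotate a term with a rank
#'
#' If \code{rank_name} resolves (canonically or via an alias) the term's
#' rank is set. Empty or rank-free markers leave the rank unset with no
#' finding; an unknown rank name leaves the rank unset and attaches an
#' \code{"unknown_rank"} attribute to the returned term so callers can
#' collect findings. Rank-free terms are legal throughout.
#'
#' @param term a [taxon_term()].
#' @param rank_name rank string from a source.
#' @param vocab a rank vocabulary.
#' @return the term, possibly with \code{rank} set.
#' @export
annotate_rank <- function(term, rank_name, vocab) {
  rank_name <- normalize_name(rank_name %||% "")
  if (rank_name %in% rank_free_aliases) return(term)
  id <- rank_lookup(vocab, rank_name)
  if (is.na(id)) {
    attr(term, "unknown_rank") <- rank_name
  } else {
    term$rank <- id
  }
  term
}
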