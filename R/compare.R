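# Graph comparison used by round-trip and graft-locality checks.

term_fingerprint <- function(t) {
  syn <- t$synonyms
  syn_key <- sort_c(paste(syn$name, syn$scope, syn$type, sep = "\r"))
  paste(t$name, t$parent, t$rank, t$is_extinct, t$is_obsolete, t$comment,
        paste(syn_key, collapse = "\n"),
        paste(sort_c(t$xrefs), collapse = "\n"), sep = "\r\r")
}

#' Test two taxonomy graphs for id-preserving isomorphism
#'
#' \code{TRUE} iff both graphs hold the same term ids and, per id, identical
#' primary name, parent, rank, synonym records (as a set of name/scope/type
#' triples), xref set, extinct/obsolete flags and comment. Insertion order
#' never matters. On mismatch the reason is attached as the
#' \code{"reason"} attribute.
#'
#' @param a,b taxonomy graphs.
#' @return logical scalar with a \code{"reason"} attribute when FALSE.
#' @export
graph_identical <- function(a, b) {
  ids_a <- sort_c(term_ids(a)); ids_b <- sort_c(term_ids(b))
  if (!identical(ids_a, ids_b)) {
    d <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    return(structure(FALSE, reason = paste("term id sets differ:", d[1])))
  }
  for (id in ids_a) {
    fa <- term_fingerprint(a$terms[[id]])
    fb <- term_fingerprint(b$terms[[id]])
    if (!identical(fa, fb)) {
      return(structure(FALSE, reason = paste("term", id, "differs")))
    }
  }
  TRUE
}
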