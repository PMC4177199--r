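# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a taxon name for indexing and matching
#'
#' Trims leading/trailing whitespace and collapses internal whitespace runs
#' to single spaces. Comparison stays case-sensitive because scientific
#' names are case-meaningful (genus capitalized, epithet lower-case), which
#' avoids false homonym merges between, e.g., a genus and a vernacular word.
#'
#' @param x character vector of names.
#' @return character vector of normalized names.
#' @export
normalize_name <- function(x) {
  gsub("[ \t\r\n]+", " ", trimws(x))
}

# Locale-independent (C collation) sort so serializations are byte-identical
# across machines.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(x) order(x, method = "radix")

# Open a text connection; transparently handles gzip by file extension.
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, encoding = "UTF-8")
  else file(path, encoding = "UTF-8")
}

read_text_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (!file.exists(x)) stop("cannot read input file: ", x, call. = FALSE)
  con <- open_text(x)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Write lines atomically: write to a temp file in the same directory, then
# rename over the destination so partial outputs never appear.
write_lines_atomic <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok) unlink(tmp)
  })
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Zero-padded term identifier in a namespace, e.g. "TXO:0000042".
make_term_id <- function(prefix, n, width = 7L) {
  sprintf("%s:%s", prefix, formatC(as.integer(n), width = width, flag = "0"))
}

id_local_number <- function(id) {
  suppressWarnings(as.integer(sub("^[^:]+:", "", id)))
}

id_prefix <- function(id) sub(":.*$", "", id)
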