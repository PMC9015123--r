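#' Multiple sequence alignment container
#'
#' An `msa` object holds `n` equal-length rows of single-byte characters
#' (typically `a`, `c`, `g`, `t` and the gap `-`, but any non-whitespace byte
#' is allowed, including ambiguity codes and protein letters), together with
#' their FASTA description lines in original record order. Rows are stored
#' verbatim: no case folding, no gap canonicalisation — upper- and lower-case
#' copies of a letter are distinct alphabet symbols, because the compressor is
#' lossless at the byte level.
#'
#' @param rows character vector of aligned rows, all the same number of
#'   characters.
#' @param headers character vector of description lines (without the leading
#'   `">"`); defaults to `seq_1 ... seq_n`.
#' @return An object of class `msa` with fields `headers`, `rows`, `n`, `l`
#'   and `alphabet` (the exact set of characters observed across all rows,
#'   sorted by byte value).
#' @examples
#' m <- msa(c("acgt", "ac-t"), c("first", "second"))
#' m$alphabet
#' @export
msa <- function(rows, headers = NULL) {
  if (length(rows) < 1L) stop_format("no records")
  rows <- as.character(rows)
  if (is.null(headers)) headers <- paste0("seq_", seq_along(rows))
  headers <- as.character(headers)
  if (length(headers) != length(rows)) {
    stop("headers and rows must have the same length")
  }
  widths <- nchar(rows, type = "bytes")
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop_format(sprintf(
      "not an alignment: record %d has length %d but record 1 has length %d",
      bad, widths[bad], widths[1L]))
  }
  if (widths[1L] < 1L) stop_format("not an alignment: empty rows")
  structure(
    list(
      headers = headers,
      rows = rows,
      n = length(rows),
      l = widths[[1L]],
      alphabet = msa_alphabet(rows)
    ),
    class = "msa"
  )
}

msa_alphabet <- function(rows) {
  bytes <- sort(unique(as.integer(unlist(
    lapply(rows, function(s) as.integer(charToRaw(s)))
  ))))
  vapply(bytes, function(b) rawToChar(as.raw(b)), character(1))
}

# n x l integer matrix of byte values; the workhorse representation for all
# column-wise arithmetic.
msa_bytes <- function(msa) {
  matrix(
    as.integer(unlist(lapply(msa$rows, charToRaw), use.names = FALSE)),
    nrow = msa$n, ncol = msa$l, byrow = TRUE
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns, alphabet {%s}\n",
              x$n, x$l, paste(x$alphabet, collapse = "")))
  show <- min(x$n, 6L)
  for (i in seq_len(show)) {
    row <- x$rows[i]
    if (nchar(row) > 60) row <- paste0(substr(row, 1, 57), "...")
    cat(sprintf("  >%s\n  %s\n", x$headers[i], row))
  }
  if (x$n > show) cat(sprintf("  ... and %d more\n", x$n - show))
  invisible(x)
}

#' Test two alignments for exact equality
#'
#' Byte-exact comparison of rows, headers and record order; this is the
#' lossless round-trip contract of the codec.
#'
#' @param a,b `msa` objects.
#' @return `TRUE` or `FALSE`.
#' @export
msa_identical <- function(a, b) {
  inherits(a, "msa") && inherits(b, "msa") &&
    identical(a$headers, b$headers) && identical(a$rows, b$rows)
}
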