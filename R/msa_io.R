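#' Read an aligned FASTA file
#'
#' Parses a FASTA file into an [msa()]. Records may be line-wrapped; Windows
#' and Unix line endings are both accepted; header lines are kept verbatim
#' (everything after `">"`, including spaces); character case is preserved.
#' Blanks and tabs inside sequence lines are discarded — any other byte is a
#' sequence character.
#'
#' @param path path to a FASTA file.
#' @return An [msa()] object.
#' @seealso [write_msa()]
#' @export
read_msa <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_format(paste0("format error: ", conditionMessage(e)))
  )
  if (length(set) == 0L) stop_format("no records")
  rows <- as.character(set)
  # whitespace is layout, not sequence data
  rows <- gsub("[ \t\r]", "", rows, useBytes = TRUE)
  msa(rows, headers = names(set))
}

#' Write an alignment as FASTA
#'
#' The written file re-parses to an alignment identical to the input
#' (round-trip identity on headers, rows and order). Lines are wrapped at
#' `line_width` characters and terminated with `"\n"`.
#'
#' @param msa an [msa()] object.
#' @param path output path.
#' @param line_width positive integer; sequence line wrap width.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, line_width = 60L) {
  stopifnot(inherits(msa, "msa"), line_width >= 1L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(fasta_bytes(msa, line_width), con)
  invisible(path)
}

# FASTA serialisation as a raw vector (also the "raw size" that compression
# ratios are measured against).
fasta_bytes <- function(msa, line_width = 60L) {
  starts <- seq(1L, msa$l, by = line_width)
  pieces <- vapply(seq_len(msa$n), function(i) {
    body <- substring(msa$rows[i], starts, pmin(starts + line_width - 1L, msa$l))
    paste0(">", msa$headers[i], "\n", paste(body, collapse = "\n"), "\n")
  }, character(1))
  charToRaw(paste(pieces, collapse = ""))
}
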