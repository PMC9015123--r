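#' Column-wise character profiles of an alignment
#'
#' For every column `j` of the alignment, counts how many rows carry each
#' character. The empirical column probability of character `x` at column `j`
#' is `count / n`; a character present in a row always has probability at
#' least `1/n`, so per-row log-likelihoods are finite.
#'
#' @param msa an [msa()] object.
#' @return An object of class `column_profiles` with fields:
#'   * `counts`: list of length `l`; element `j` is a named integer vector of
#'     occurrence counts for the characters observed in column `j` (absent
#'     characters have no entry; counts in each column sum to `n`);
#'   * `n`, `l`: alignment dimensions;
#'   * `alphabet`: observed characters, in byte order.
#' @examples
#' p <- column_profiles(msa(c("at", "tt")))
#' p$counts[[1]]            # a: 1, t: 1
#' profile_prob(p, "t", 2)  # 1
#' @export
column_profiles <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  B <- msa_bytes(msa)
  ab <- sort(unique(as.vector(B)))
  K <- length(ab)
  codes <- match(B, ab)
  dim(codes) <- dim(B)
  flat <- as.vector(codes) + K * rep(seq_len(msa$l) - 1L, each = msa$n)
  cnt <- matrix(tabulate(flat, K * msa$l), nrow = K, ncol = msa$l)
  chars <- vapply(ab, function(b) rawToChar(as.raw(b)), character(1))
  counts <- lapply(seq_len(msa$l), function(j) {
    nz <- cnt[, j] > 0L
    setNames(cnt[nz, j], chars[nz])
  })
  structure(
    list(counts = counts, n = msa$n, l = msa$l, alphabet = chars,
         count_mat = cnt, codes = codes),
    class = "column_profiles"
  )
}

#' @rdname column_profiles
#' @param profiles a `column_profiles` object.
#' @param char single character.
#' @param column column index (1-based).
#' @return `profile_prob()`: the empirical probability `count(char, column)/n`
#'   (0 for a character never observed in that column).
#' @export
profile_prob <- function(profiles, char, column) {
  stopifnot(inherits(profiles, "column_profiles"))
  cnt <- profiles$counts[[column]][char]
  if (is.na(cnt)) 0 else unname(cnt) / profiles$n
}

# n x l matrix of per-cell column counts F, shared by the likelihood
# functions below.
cell_counts <- function(profiles) {
  K <- length(profiles$alphabet)
  flat <- as.vector(profiles$codes) +
    K * rep(seq_len(profiles$l) - 1L, each = nrow(profiles$codes))
  matrix(profiles$count_mat[flat], nrow = nrow(profiles$codes))
}

#' Log-likelihood of one row under the column profiles
#'
#' The likelihood of row `i` treats columns as independent and multiplies the
#' empirical column probabilities of its own characters; on the log scale this
#' is `sum_j log(F[i,j] / n)` where `F[i,j]` is the count, in column `j`, of
#' the character row `i` carries there. The score is always finite (each
#' character counts itself, so every factor is at least `1/n`) and never
#' positive; rows close to the column-wise consensus score highest.
#'
#' @param msa an [msa()] object.
#' @param index row index (1-based).
#' @param profiles column profiles computed from the same alignment.
#' @return A single number in natural-log units, `<= 0` and
#'   `>= l * log(1/n)`.
#' @export
sequence_log_likelihood <- function(msa, index, profiles = column_profiles(msa)) {
  stopifnot(index >= 1L, index <= msa$n)
  F_row <- profiles$count_mat[cbind(profiles$codes[index, ], seq_len(msa$l))]
  sum(log(F_row)) - msa$l * log(profiles$n)
}

all_log_likelihoods <- function(msa, profiles = column_profiles(msa)) {
  rowSums(log(cell_counts(profiles))) - msa$l * log(profiles$n)
}

#' Rank rows by descending log-likelihood
#'
#' Sorting by likelihood places mutually similar rows next to each other, so
#' adjacent entries of the returned order are cheap references for one
#' another. Ties (e.g. identical rows) are broken by ascending original row
#' index, making the order — and therefore the archive — deterministic.
#'
#' @inheritParams sequence_log_likelihood
#' @return An integer permutation of `1:n`, most likely row first.
#' @export
rank_by_likelihood <- function(msa, profiles = column_profiles(msa)) {
  ll <- all_log_likelihoods(msa, profiles)
  order(-ll, seq_len(msa$n))
}

#' Sliding-window configuration
#'
#' The ranked row order is cut into overlapping windows; rows sharing a
#' window form a clique in the encodability graph. The window length and
#' overlap are the compressor's two tunables: larger windows give each row
#' more candidate references (denser graph, better compression, more time).
#' The defaults, window 30 with overlap 20, are the strongest of the standard
#' settings (5/3, 10/7, 20/15, 30/20) on ribosomal-RNA style data.
#'
#' @param window_length window length `l_w >= 2`.
#' @param overlap overlap between consecutive windows; `0 <= overlap <
#'   window_length`. The step is `window_length - overlap`.
#' @return A `window_config` object with fields `window_length`, `overlap`,
#'   `step`.
#' @export
window_config <- function(window_length = 30L, overlap = 20L) {
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (is.na(window_length) || window_length < 2L) {
    stop_usage("window_length must be an integer >= 2")
  }
  if (is.na(overlap) || overlap < 0L || overlap >= window_length) {
    stop_usage("overlap must satisfy 0 <= overlap < window_length")
  }
  structure(
    list(window_length = window_length, overlap = overlap,
         step = window_length - overlap),
    class = "window_config"
  )
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("<window_config> length %d, overlap %d (step %d)\n",
              x$window_length, x$overlap, x$step))
  invisible(x)
}

#' Cut a ranked order into overlapping windows
#'
#' Windows are contiguous slices of `order`, each of length
#' `min(window_length, n)`, starting at positions `1, 1 + step, 1 + 2*step,
#' ...`; the final window is anchored to end exactly at position `n` (its
#' start is clipped), so the tail rows still sit in a full-size clique. Every
#' index appears in at least one window, and for `n > window_length` the
#' number of windows is `ceiling((n - l_w)/l_s) + 1`.
#'
#' @param order integer permutation, e.g. from [rank_by_likelihood()].
#' @param config a [window_config()].
#' @return A list of integer vectors (slices of `order`).
#' @examples
#' length(sliding_windows(1:100, window_config(30, 20)))  # 8
#' @export
sliding_windows <- function(order, config = window_config()) {
  stopifnot(inherits(config, "window_config"))
  n <- length(order)
  lw <- config$window_length
  ls <- config$step
  if (n <= lw) return(list(order))
  k <- as.integer(ceiling((n - lw) / ls)) + 1L
  starts <- c((seq_len(k - 1L) - 1L) * ls, n - lw) + 1L
  lapply(starts, function(s) order[s:(s + lw - 1L)])
}
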