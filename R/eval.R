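#' Average Hamming distance of an alignment
#'
#' The sum of Hamming distances over all unordered row pairs, divided by
#' `L * N` where `L` is the alignment length and `N` the number of rows (the
#' normalisation as defined — note it divides by `L*N`, not by the number of
#' pairs, so values can exceed 1 for large alignments). Gaps count as
#' ordinary characters. Low values indicate high redundancy and predict high
#' compression ratios.
#'
#' @param msa an [msa()] object with at least 2 rows.
#' @return A non-negative number.
#' @examples
#' average_hamming_distance(msa(c("aaaaaaaaaa", "tttttttttt")))  # 0.5
#' @export
average_hamming_distance <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  if (msa$n < 2L) stop("average_hamming_distance is undefined for n < 2")
  p <- column_profiles(msa)
  n <- msa$n
  # per column: mismatching pairs = C(n,2) - sum_x C(count_x,2)
  same <- colSums(p$count_mat * (p$count_mat - 1) / 2)
  total_mismatch <- sum(n * (n - 1) / 2 - same)
  total_mismatch / (msa$l * n)
}

#' Average p-distance of an alignment
#'
#' Mean over unordered row pairs of the fraction of mismatching columns
#' among pairwise-comparable columns; a column where either row carries a
#' gap is excluded from both numerator and denominator. A pair with no
#' comparable column is skipped with a warning.
#'
#' @param msa an [msa()] object with at least 2 rows.
#' @param gap_char gap character (default `"-"`).
#' @return A number in `[0, 1]`.
#' @export
average_p_distance <- function(msa, gap_char = "-") {
  stopifnot(inherits(msa, "msa"))
  if (msa$n < 2L) stop("average_p_distance is undefined for n < 2")
  B <- msa_bytes(msa)
  gap <- as.integer(charToRaw(gap_char))
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(msa$n - 1L)) {
    for (j in (i + 1L):msa$n) {
      comp <- B[i, ] != gap & B[j, ] != gap
      nc <- sum(comp)
      if (nc == 0L) { skipped <- skipped + 1L; next }
      vals <- c(vals, sum(B[i, comp] != B[j, comp]) / nc)
    }
  }
  if (skipped) warning(sprintf("%d pair(s) with no comparable columns skipped", skipped))
  if (!length(vals)) stop("no comparable pairs")
  mean(vals)
}

#' Benchmark a grid of window configurations on one alignment
#'
#' Runs the full pipeline once per configuration and tabulates sizes.
#' Because denser graphs can only reveal cheaper parent choices, the
#' arborescence total weight is non-increasing as windows grow, with the
#' single full window (complete graph) as the lower bound.
#'
#' @param msa an [msa()] object.
#' @param configs list of [window_config()] objects, or `NULL` for the
#'   standard grid 5/3, 10/7, 20/15, 30/20 plus the single full window.
#' @param backend entropy backend name.
#' @return A tibble of class `window_sweep`, one row per configuration:
#'   `window_length`, `overlap` (`NA` for the full window), `n`, `l`,
#'   `raw_bytes` (FASTA size), `pre_backend_bytes`, `compressed_bytes`,
#'   `ratio` (raw/compressed), `total_weight`, `n_references`,
#'   `avg_hamming`, `elapsed` (seconds).
#' @export
sweep_windows <- function(msa, configs = NULL, backend = "bzip2") {
  stopifnot(inherits(msa, "msa"))
  full <- list(window_length = NA_integer_, overlap = NA_integer_)
  if (is.null(configs)) {
    configs <- list(window_config(5, 3), window_config(10, 7),
                    window_config(20, 15), window_config(30, 20), full)
  }
  raw_bytes <- length(fasta_bytes(msa))
  avg_h <- if (msa$n >= 2L) average_hamming_distance(msa) else 0
  cm <- cost_model(msa)
  ord <- rank_by_likelihood(msa)
  rows <- lapply(configs, function(cfg) {
    t0 <- proc.time()[["elapsed"]]
    windows <- if (is.list(cfg) && inherits(cfg, "window_config")) {
      sliding_windows(ord, cfg)
    } else {
      list(seq_len(msa$n))
    }
    g <- build_graph(msa, windows, cm)
    arb <- min_arborescence(g)
    body <- serialize_archive(encode_archive(msa, arb, cm))
    z <- backend_compress(body, backend)
    tibble(
      window_length = if (inherits(cfg, "window_config")) cfg$window_length else msa$n,
      overlap = if (inherits(cfg, "window_config")) cfg$overlap else NA_integer_,
      n = msa$n, l = msa$l,
      raw_bytes = raw_bytes,
      pre_backend_bytes = length(body),
      compressed_bytes = length(z),
      ratio = raw_bytes / length(z),
      total_weight = arb$total_weight,
      n_references = length(arb$references),
      avg_hamming = avg_h,
      elapsed = proc.time()[["elapsed"]] - t0
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_sweep", class(out))
  out
}

#' Compression ratio versus divergence
#'
#' Generates synthetic alignments over a grid of divergence levels (several
#' seeds per level), compresses each, and tabulates average Hamming distance
#' against compression ratio. The expected relationship is monotone in
#' trend: the more redundant the alignment, the higher the ratio, i.e. a
#' strongly negative Spearman correlation (see
#' [divergence_correlation()]).
#'
#' @param divergences numeric vector of per-site substitution probabilities.
#' @param seeds integer vector of seeds used at every divergence level.
#' @param n,l alignment dimensions.
#' @param config a [window_config()].
#' @param backend entropy backend name.
#' @param gap_prob gap-run rate passed to [generate_msa()].
#' @param tree tree shape passed to [generate_msa()].
#' @return A tibble of class `divergence_sweep`: `divergence`, `seed`,
#'   `avg_hamming`, `raw_bytes`, `compressed_bytes`, `ratio`.
#' @export
divergence_sweep <- function(divergences, seeds = 1:20, n = 60L, l = 400L,
                             config = window_config(), backend = "bzip2",
                             gap_prob = 0.01, tree = "star") {
  grid <- expand.grid(divergence = divergences, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    d <- grid$divergence[k]
    s <- grid$seed[k]
    m <- generate_msa(n, l, divergence = d, gap_prob = gap_prob,
                      tree = tree, seed = s)
    z <- compress_msa(m, config = config, backend = backend)
    raw_bytes <- length(fasta_bytes(m))
    tibble(
      divergence = d, seed = s,
      avg_hamming = average_hamming_distance(m),
      raw_bytes = raw_bytes,
      compressed_bytes = length(z),
      ratio = raw_bytes / length(z)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("divergence_sweep", class(out))
  out
}

#' @rdname divergence_sweep
#' @param sweep a `divergence_sweep` tibble.
#' @return `divergence_correlation()`: the Spearman correlation between
#'   average Hamming distance and compression ratio (expected strongly
#'   negative).
#' @export
divergence_correlation <- function(sweep) {
  cor(sweep$avg_hamming, sweep$ratio, method = "spearman")
}

#' @export
autoplot.window_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$window_length, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window length", y = "compression ratio",
                  title = "Compression ratio vs sliding-window length")
}

#' @export
autoplot.divergence_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$avg_hamming, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "average Hamming distance", y = "compression ratio",
                  title = "Compression ratio vs alignment divergence")
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
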