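#' Generate a synthetic alignment with controlled redundancy
#'
#' Draws a root row uniformly over the non-gap alphabet and evolves copies
#' down a tree by per-site substitution; each branch independently redraws
#' each site with probability `divergence`, uniformly over the non-gap
#' alphabet (so `divergence = 1` is exact saturation: rows become i.i.d.
#' uniform and the expected pairwise mismatch fraction is
#' `(|alphabet|-1)/|alphabet|`). Shared gap runs are then overlaid: column
#' runs are chosen at random and replaced by the gap character in a random
#' subset of rows, keeping all rows equal length (gaps substitute, they do
#' not shift). The output is fully determined by `seed`.
#'
#' Tree shapes:
#' * `"star"` — every row is one branch away from the root; pairwise
#'   divergence is homogeneous.
#' * `"binary"` — a random binary tree with a substitution dose per edge;
#'   produces nested similarity structure.
#' * `"clustered"` — `clusters` centres far from each other (branch
#'   probability `cluster_divergence`), members tight around their centre;
#'   produces block structure with cheap within-cluster references.
#'
#' @param n number of rows.
#' @param l alignment length (columns).
#' @param divergence per-site, per-branch substitution probability in
#'   `[0, 1]`.
#' @param gap_prob expected fraction of columns at which a shared gap run
#'   starts, in `[0, 1]`.
#' @param tree `"star"`, `"binary"` or `"clustered"`.
#' @param clusters number of clusters for `tree = "clustered"`.
#' @param cluster_divergence per-site substitution probability on the
#'   root-to-centre branches.
#' @param alphabet non-gap alphabet characters.
#' @param gap_char gap character.
#' @param seed integer seed; if `NULL` the current RNG stream is used.
#' @param prefix header prefix; headers are `<prefix>_1 ... <prefix>_n`.
#' @return An [msa()] object.
#' @examples
#' m <- generate_msa(10, 100, divergence = 0.05, seed = 42)
#' average_hamming_distance(m)
#' @export
generate_msa <- function(n, l, divergence = 0.02, gap_prob = 0.01,
                         tree = c("star", "binary", "clustered"),
                         clusters = 3L,
                         cluster_divergence = min(1, divergence * 10),
                         alphabet = c("a", "c", "g", "t"),
                         gap_char = "-", seed = NULL, prefix = "seq") {
  tree <- match.arg(tree)
  stopifnot(n >= 1L, l >= 1L, divergence >= 0, divergence <= 1,
            gap_prob >= 0, gap_prob <= 1, length(alphabet) >= 2L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  K <- length(alphabet)
  mutate <- function(row, p) {
    if (p <= 0) return(row)
    hit <- runif(l) < p
    nh <- sum(hit)
    if (nh) row[hit] <- sample.int(K, nh, replace = TRUE)
    row
  }
  root <- sample.int(K, l, replace = TRUE)
  rows_codes <- switch(
    tree,
    star = lapply(seq_len(n), function(i) mutate(root, divergence)),
    binary = {
      leaves <- vector("list", n)
      count <- 0L
      grow <- function(node, size) {
        if (size == 1L) {
          count <<- count + 1L
          leaves[[count]] <<- node
          return(invisible(NULL))
        }
        split_at <- sample.int(size - 1L, 1L)
        grow(mutate(node, divergence), split_at)
        grow(mutate(node, divergence), size - split_at)
      }
      grow(root, n)
      leaves
    },
    clustered = {
      k <- max(1L, min(as.integer(clusters), n))
      centres <- lapply(seq_len(k), function(i) mutate(root, cluster_divergence))
      member <- rep_len(seq_len(k), n)
      lapply(member, function(ci) mutate(centres[[ci]], divergence))
    }
  )
  mat <- do.call(rbind, rows_codes)
  chars <- matrix(alphabet[mat], n, l)

  if (gap_prob > 0) {
    n_events <- rbinom(1L, l, gap_prob)
    for (e in seq_len(n_events)) {
      start <- sample.int(l, 1L)
      len <- sample.int(5L, 1L)
      cols <- start:min(l, start + len - 1L)
      members <- runif(n) < 0.5
      if (any(members)) chars[members, cols] <- gap_char
    }
  }
  rows <- apply(chars, 1L, paste, collapse = "")
  msa(rows, headers = paste0(prefix, "_", seq_len(n)))
}
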