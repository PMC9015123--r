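# Shared fixtures and independent oracles for the test suite.

# Random alignment built directly from i.i.d. characters (independent of
# generate_msa, so generator tests are not circular).
random_msa <- function(n, l, alphabet = c("a", "c", "g", "t", "-"),
                       headers = NULL) {
  rows <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
  msa(rows, headers = headers)
}

# Brute-force average Hamming distance: explicit double loop over pairs.
ahd_brute <- function(m) {
  B <- msazip:::msa_bytes(m)
  tot <- 0
  for (i in seq_len(m$n - 1L)) {
    for (j in (i + 1L):m$n) tot <- tot + sum(B[i, ] != B[j, ])
  }
  tot / (m$l * m$n)
}

# Random root-connected weighted digraph on n row vertices: all root edges
# present (as in graphs built by build_graph), each ordered row pair present
# with probability p_edge; positive integer weights.
random_graph <- function(n, p_edge = 0.5, wmax = 100L) {
  from <- 0L + integer(n)
  to <- seq_len(n)
  w <- sample.int(wmax, n, replace = TRUE) + wmax  # root edges on the pricier side
  if (n >= 2L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && runif(1) < p_edge) {
          from <- c(from, i); to <- c(to, j)
          w <- c(w, sample.int(wmax, 1L))
        }
      }
    }
  }
  structure(
    list(n = n, edges = data.frame(from = from, to = to, weight = w),
         cost_model = NULL),
    class = "encodability_graph"
  )
}

# The worked cost-matrix pair: two length-14 rows that differ exactly at
# 0-based columns {2,3,10,11}, in two runs of two characters.
fig_pair <- function() {
  list(
    s1 = "gtaagtcttgccgt",   # carries "aa" at cols 3:4 and "cc" at 11:12 (1-based)
    s2 = "gtttgtcttgttgt"    # carries "tt" at both sites
  )
}

expect_msa_equal <- function(a, b) {
  expect_true(msa_identical(a, b))
}
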