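test_that("cost model constants are derived from the alignment", {
  cm <- cost_model(msa(c("acgt", "ac-t")))
  expect_equal(cm$N, 3L)   # 5 symbols
  expect_equal(cm$I, 2L)   # max(n, l) = 4
  cm <- cost_model(random_msa(100, 2000))
  expect_equal(cm$I, 11L)
  # degenerate single-symbol alignment still gets positive widths
  cm <- cost_model(msa(c("aaa", "aaa")))
  expect_equal(cm$N, 1L)
  expect_true(cm$I >= 1L)
})

test_that("mismatch runs are maximal, sorted and exactly cover the diffs", {
  expect_equal(nrow(mismatch_runs("acgt", "acgt")), 0L)

  p <- fig_pair()
  r <- mismatch_runs(p$s2, p$s1)   # represent s1 using s2
  expect_equal(r$start, c(3L, 11L))
  expect_equal(r$chars, c("aa", "cc"))

  expect_error(mismatch_runs("acg", "acgt"), "not comparable")

  withr::local_seed(21)
  for (rep in 1:30) {
    l <- sample(1:80, 1)
    a <- paste(sample(c("a", "t", "-"), l, TRUE), collapse = "")
    b <- paste(sample(c("a", "t", "-"), l, TRUE), collapse = "")
    r <- mismatch_runs(a, b)
    covered <- unlist(mapply(function(s, ch) s + seq_len(nchar(ch)) - 1L,
                             r$start, r$chars, SIMPLIFY = FALSE))
    truth <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(sort(as.integer(covered)), truth)
    # maximality: no two runs adjacent or overlapping
    if (nrow(r) >= 2) {
      ends <- r$start + nchar(r$chars) - 1L
      expect_true(all(r$start[-1] > ends[-nrow(r)] + 1L))
    }
  }
})

test_that("pair_cost equals the measured serialized record size (master oracle)", {
  withr::local_seed(31)
  for (rep in 1:10) {
    m <- random_msa(sample(3:12, 1), sample(5:120, 1))
    cm <- cost_model(m)
    g <- build_graph(m, NULL, cm)
    arb <- min_arborescence(g)
    body <- serialize_archive(a <- encode_archive(m, arb, cm))
    rb <- attr(body, "record_bits")
    for (k in seq_along(a$records)) {
      rec <- a$records[[k]]
      w <- if (rec$type == "reference") reference_cost(m, cm)
           else pair_cost(m, rec$parent, rec$index, cm)
      expect_equal(rb[k], w)
    }
  }
})

test_that("the worked cost-matrix pair prices at 2I + 4N run payload", {
  p <- fig_pair()
  m <- msa(c(p$s1, p$s2))
  cm <- cost_model(m)
  r <- mismatch_runs(p$s2, p$s1)
  lens <- nchar(r$chars)
  expect_equal(msazip:::run_payload_bits(lens, cm), 2 * cm$I + 4 * cm$N)
  # full record = run payload + tag + indices + varint count/length fields
  expect_equal(pair_cost(m, 2, 1, cm),
               2 * cm$I + 4 * cm$N + 1 + 2 * cm$I + 8 + 2 * 8)
})

test_that("reference cost is I + l*N plus the record tag, row-independent", {
  m <- random_msa(6, 14, alphabet = c("a", "c", "g", "t", "-", "n"))
  cm <- cost_model(m)
  expect_equal(reference_cost(m, cm), 1 + cm$I + 14 * cm$N)
  # identical for every row: the formula has no sequence content
  expect_length(unique(vapply(1:6, function(i) reference_cost(m, cm),
                              numeric(1))), 1L)
})

test_that("identical rows cost only the fixed delta overhead", {
  m <- msa(rep("acgtacgt", 3))
  cm <- cost_model(m)
  expect_equal(pair_cost(m, 1, 2, cm), 1 + 2 * cm$I + 8)  # zero runs
})

test_that("graph construction follows the windows exactly", {
  m <- random_msa(3, 20)
  g <- build_graph(m, NULL)
  seq_edges <- g$edges[g$edges$from != 0L, ]
  root_edges <- g$edges[g$edges$from == 0L, ]
  expect_equal(nrow(seq_edges), 6L)   # complete directed graph on 3
  expect_equal(nrow(root_edges), 3L)
  expect_equal(sort(root_edges$to), 1:3)

  m <- random_msa(3, 20)
  g <- build_graph(m, list(c(1L, 2L), c(2L, 3L)))
  keys <- paste(g$edges$from, g$edges$to)
  expect_setequal(keys[g$edges$from != 0],
                  c("1 2", "2 1", "2 3", "3 2"))
  expect_false(any(keys %in% c("1 3", "3 1")))

  # duplicated pairs across overlapping windows yield a single edge
  g2 <- build_graph(m, list(c(1L, 2L, 3L), c(2L, 3L)))
  expect_equal(sum(g2$edges$from == 2 & g2$edges$to == 3), 1L)
})

test_that("edge count grows linearly in n for a fixed window setting", {
  cfg <- window_config(10, 5)
  counts <- vapply(c(50L, 100L, 150L), function(n) {
    m <- random_msa(n, 10)
    g <- build_graph(m, sliding_windows(seq_len(n), cfg))
    sum(g$edges$from != 0L)
  }, numeric(1))
  expect_lt(counts[3], sum(vapply(sliding_windows(1:150, cfg), function(w) {
    length(w) * (length(w) - 1)
  }, numeric(1))) + 1)
  # equal increments: pure O(n) growth
  expect_equal(counts[2] - counts[1], counts[3] - counts[2])
})

test_that("apply_runs inverts mismatch_runs on random pairs", {
  expect_equal(apply_runs("acgt", mismatch_runs("acgt", "acgt")), "acgt")
  p <- fig_pair()
  expect_equal(apply_runs(p$s2, mismatch_runs(p$s2, p$s1)), p$s1)
  expect_equal(apply_runs(p$s1, mismatch_runs(p$s1, p$s2)), p$s2)

  withr::local_seed(41)
  for (rep in 1:200) {
    l <- sample(1:60, 1)
    ab <- c("a", "c", "g", "t", "-", "N", "y")
    a <- paste(sample(ab, l, TRUE), collapse = "")
    b <- paste(sample(ab, l, TRUE), collapse = "")
    expect_identical(apply_runs(a, mismatch_runs(a, b)), b)
  }

  expect_error(
    apply_runs("acgt", tibble::tibble(start = 4L, chars = "cc")),
    "corrupt delta")
})
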