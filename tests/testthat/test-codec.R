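test_that("archives hold one record per row with references = root children", {
  m <- generate_msa(20, 100, divergence = 0.05, seed = 9)
  cm <- cost_model(m)
  arb <- min_arborescence(build_graph(m, NULL, cm))
  a <- encode_archive(m, arb, cm)
  expect_length(a$records, 20L)
  expect_setequal(vapply(a$records, `[[`, integer(1), "index"), 1:20)
  nref <- sum(vapply(a$records, function(r) r$type == "reference", logical(1)))
  expect_equal(nref, length(arb$references))
})

test_that("identical rows archive as one reference plus empty deltas", {
  m <- msa(rep(strrep("acgt", 25), 8))
  arb <- min_arborescence(build_graph(m))
  a <- encode_archive(m, arb)
  types <- vapply(a$records, `[[`, character(1), "type")
  expect_equal(sum(types == "reference"), 1L)
  expect_equal(sum(types == "delta"), 7L)
  expect_true(all(vapply(a$records[types == "delta"],
                         function(r) nrow(r$runs) == 0L, logical(1))))
})

test_that("records are topologically ordered: parents precede children", {
  withr::local_seed(13)
  for (rep in 1:5) {
    m <- generate_msa(30, 150, divergence = 0.1, seed = rep, tree = "binary")
    arb <- min_arborescence(build_graph(m))
    a <- encode_archive(m, arb)
    seen <- logical(m$n)
    for (rec in a$records) {
      if (rec$type == "delta") expect_true(seen[rec$parent])
      seen[rec$index] <- TRUE
    }
    expect_true(all(seen))
    # every delta chain terminates at a reference
    for (i in seq_len(m$n)) {
      v <- i
      for (s in seq_len(m$n)) if (v != 0L) v <- arb$parent[v]
      expect_equal(v, 0L)
    }
  }
})

test_that("serialize/deserialize is the identity on archives", {
  withr::local_seed(17)
  cases <- list(
    msa(rep("aaaa", 3)),                       # empty-delta archive
    msa("acgtn-ACGT", "single"),               # single reference
    random_msa(15, 40, alphabet = c("a", "c", "g", "t", "-", "X", "y"))
  )
  for (m in cases) {
    cm <- cost_model(m)
    arb <- min_arborescence(build_graph(m, NULL, cm))
    a <- encode_archive(m, arb, cm)
    b <- deserialize_archive(serialize_archive(a))
    expect_equal(b$n, a$n)
    expect_equal(b$l, a$l)
    expect_equal(b$alphabet, a$alphabet)
    expect_equal(b$headers, a$headers)
    expect_equal(length(b$records), length(a$records))
    expect_msa_equal(decode_archive(b), m)
  }
  # determinism: equal archives serialize to equal bytes
  m <- cases[[3]]
  z1 <- compress_msa(m)
  z2 <- compress_msa(m)
  expect_identical(as.vector(z1), as.vector(z2))
})

test_that("cost fidelity: record sizes equal edge weights, sum equals arborescence", {
  withr::local_seed(19)
  for (rep in 1:4) {
    m <- generate_msa(25, 200, divergence = runif(1, 0, 0.3), seed = rep,
                      gap_prob = 0.05)
    cm <- cost_model(m)
    ord <- rank_by_likelihood(m)
    g <- build_graph(m, sliding_windows(ord, window_config(10, 7)), cm)
    arb <- min_arborescence(g)
    body <- serialize_archive(a <- encode_archive(m, arb, cm))
    rb <- attr(body, "record_bits")
    expect_equal(sum(rb), arb$total_weight)
    for (k in seq_along(a$records)) {
      rec <- a$records[[k]]
      expected <- if (rec$type == "reference") reference_cost(m, cm)
                  else pair_cost(m, rec$parent, rec$index, cm)
      expect_equal(rb[k], expected)
    }
  }
})

test_that("corruption and foreign input are distinguishable errors", {
  m <- random_msa(4, 30)
  z <- as.vector(compress_msa(m))
  expect_error(backend_decompress(charToRaw("not an archive at all")),
               "unrecognized archive")
  bad_version <- z
  bad_version[5] <- as.raw(99)
  expect_error(backend_decompress(bad_version), "unrecognized archive")
  truncated <- z[1:(length(z) - 5)]
  expect_error(decompress_msa(truncated), "corrupt archive")
  flipped <- z
  flipped[20] <- xor(flipped[20], as.raw(255))
  expect_error(decompress_msa(flipped), "corrupt archive")
})

test_that("entropy backends round-trip and are self-describing", {
  withr::local_seed(23)
  b <- as.raw(sample(0:255, 5000, replace = TRUE))
  for (backend in c("bzip2", "gzip", "xz", "none")) {
    z <- backend_compress(b, backend)
    expect_identical(backend_decompress(z), b)
  }
  # "none" is the identity plus envelope
  z <- backend_compress(b, "none")
  expect_identical(z[-(1:14)], b)
  expect_error(backend_compress(b, "zstd"), "unsupported backend")
  # redundant input shrinks under bzip2
  m <- generate_msa(60, 400, divergence = 0.005, seed = 1)
  body <- serialize_archive(encode_archive(m, min_arborescence(build_graph(m))))
  expect_lt(length(backend_compress(body, "bzip2")), length(body))
})

test_that("compress/decompress is lossless across shapes and backends", {
  withr::local_seed(29)
  fixtures <- list(
    msa("a"),                                          # 1x1
    msa(strrep("t", 500), "one long row"),
    msa(c("----", "ac--", "--gt")),                    # gap-heavy
    random_msa(40, 120),
    generate_msa(50, 300, divergence = 0.02, seed = 2),
    generate_msa(30, 80, divergence = 0.9, seed = 3),  # near saturation
    random_msa(10, 50, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY-", "")[[1]])
  )
  for (m in fixtures) {
    for (backend in c("bzip2", "none")) {
      z <- compress_msa(m, backend = backend)
      expect_msa_equal(decompress_msa(z), m)
    }
  }
  # order restoration: decompressed order is the original even though the
  # archive stores records parents-first
  m <- generate_msa(25, 100, divergence = 0.03, seed = 11)
  m <- msa(rev(m$rows), headers = paste0("h", 25:1))
  expect_equal(decompress_msa(compress_msa(m))$headers, paste0("h", 25:1))
})

test_that("file-level compress/decompress round-trips through FASTA", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  arch <- withr::local_tempfile(fileext = ".msaz")
  back <- withr::local_tempfile(fileext = ".fasta")
  m <- generate_msa(20, 150, divergence = 0.02, seed = 5)
  write_msa(m, fa)
  info <- compress_file(fa, arch)
  expect_true(info$compressed_bytes > 0)
  expect_equal(info$n, 20L)
  decompress_file(arch, back)
  expect_msa_equal(read_msa(back), m)
})
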