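#' Bit-cost model of an alignment
#'
#' Two constants govern every stored size: `N`, the number of bits needed to
#' store one character, and `I`, the number of bits needed to store an index
#' (a row number or a column number). Both are derived from the alignment:
#' `N = max(1, ceiling(log2(|alphabet|)))` and
#' `I = max(1, ceiling(log2(max(n, l))))`. Storing a full reference row costs
#' `I + l*N` bits (its original position plus its characters); storing a row
#' as a delta costs the mismatch-run metadata priced by [pair_cost()]. Edge
#' weights in the encodability graph are these exact serialized sizes, so the
#' minimum spanning arborescence minimises the true pre-backend archive size.
#'
#' @param msa an [msa()] object.
#' @return A `cost_model` object with integer fields `N` and `I`.
#' @examples
#' cost_model(msa(c("acgt", "ac-t")))
#' @export
cost_model <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  K <- length(msa$alphabet)
  structure(
    list(N = max(1L, as.integer(ceiling(log2(K)))),
         I = max(1L, as.integer(ceiling(log2(max(msa$n, msa$l)))))),
    class = "cost_model"
  )
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("<cost_model> N = %d bits/char, I = %d bits/index\n", x$N, x$I))
  invisible(x)
}

#' Mismatch runs between two aligned rows
#'
#' A mismatch run is a maximal block of consecutive columns where the target
#' differs from the reference, stored as its start column plus the target's
#' replacement characters. Applying the runs to the reference
#' ([apply_runs()]) reproduces the target exactly. Gaps are ordinary
#' characters — rows are aligned, so substitution runs are a complete delta
#' grammar (no indel handling is needed).
#'
#' @param ref,target equal-length strings.
#' @return A tibble with columns `start` (1-based column index) and `chars`
#'   (non-empty replacement string), sorted by `start`, runs maximal and
#'   non-adjacent.
#' @examples
#' mismatch_runs("gtaacctgaacgt", "gtcccctgatcgt")
#' @export
mismatch_runs <- function(ref, target) {
  if (nchar(ref, type = "bytes") != nchar(target, type = "bytes")) {
    stop("not comparable: rows have different lengths")
  }
  rb <- charToRaw(ref)
  tb <- charToRaw(target)
  runs_from_neq(rb != tb, tb)
}

# shared core: logical mismatch mask + target bytes -> run tibble
runs_from_neq <- function(neq, target_bytes) {
  if (!any(neq)) {
    return(tibble(start = integer(0), chars = character(0)))
  }
  r <- rle(neq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values
  tibble(
    start = starts[hit],
    chars = mapply(function(s, e) rawToChar(target_bytes[s:e]),
                   starts[hit], ends[hit], USE.NAMES = FALSE)
  )
}

#' Apply mismatch runs to a reference row
#'
#' Inverse of [mismatch_runs()]: `apply_runs(r, mismatch_runs(r, t))` equals
#' `t` for any aligned pair.
#'
#' @param ref reference row string.
#' @param runs tibble of runs as returned by [mismatch_runs()].
#' @return The reconstructed target row string.
#' @export
apply_runs <- function(ref, runs) {
  out <- charToRaw(ref)
  if (nrow(runs)) {
    lens <- nchar(runs$chars, type = "bytes")
    if (any(runs$start < 1L) || any(runs$start + lens - 1L > length(out))) {
      stop_format("corrupt delta: run exceeds row bounds")
    }
    for (k in seq_len(nrow(runs))) {
      out[runs$start[k] + seq_len(lens[k]) - 1L] <- charToRaw(runs$chars[k])
    }
  }
  rawToChar(out)
}

# Exact bit size of a delta record given its run lengths (integer vector,
# possibly empty). Layout: 1-bit record tag + I-bit target index + I-bit
# parent index + varint run count + per run (I-bit start + varint length +
# N bits per character).
delta_record_bits <- function(run_lengths, cm) {
  1 + 2 * cm$I + varint_nbits(length(run_lengths)) +
    sum(cm$I + varint_nbits(run_lengths) + cm$N * run_lengths)
}

# Run payload only (start indices + characters), the quantity the cost matrix
# examples are quoted in: one I-bit index plus N bits per character per run.
run_payload_bits <- function(run_lengths, cm) {
  sum(cm$I + cm$N * run_lengths)
}

#' Exact delta cost of representing one row by another
#'
#' Returns the serialized size, in bits, of the delta record that encodes row
#' `target` against row `ref` — the weight of the directed edge
#' `(ref, target)` in the encodability graph. By construction this equals the
#' number of bits [serialize_archive()] emits for that record (cost
#' fidelity), so the arborescence optimises real storage, not a proxy. The
#' dominant term is the run payload, `I + N * length` bits per mismatch run.
#'
#' @param msa an [msa()] object.
#' @param ref,target distinct row indices (1-based).
#' @param cm a [cost_model()]; defaults to the alignment's own.
#' @return Number of bits (positive integer).
#' @export
pair_cost <- function(msa, ref, target, cm = cost_model(msa)) {
  stopifnot(ref != target, ref >= 1L, target >= 1L, ref <= msa$n, target <= msa$n)
  rb <- charToRaw(msa$rows[ref])
  tb <- charToRaw(msa$rows[target])
  r <- rle(rb != tb)
  delta_record_bits(r$lengths[r$values], cm)
}

#' Cost of storing a row verbatim as a reference
#'
#' `I + l*N` bits (original index plus characters) plus the 1-bit record tag;
#' identical for every row of an alignment. This is the weight of every edge
#' leaving the dummy root.
#'
#' @inheritParams pair_cost
#' @return Number of bits (positive integer).
#' @export
reference_cost <- function(msa, cm = cost_model(msa)) {
  1 + cm$I + msa$l * cm$N
}

#' Build the dummy-rooted encodability graph
#'
#' Vertices are the `n` rows plus a dummy root (vertex `0`). The root has an
#' edge to every row weighted by [reference_cost()], so the graph is always
#' root-connected and a spanning arborescence exists. Rows sharing a sliding
#' window form a directed clique whose edge weights are [pair_cost()]; no
#' other row-to-row edges exist, which keeps the edge count `O(n)` for a
#' fixed window configuration. A pair occurring in several windows
#' contributes a single edge (the cost is deterministic, duplicates are
#' redundant).
#'
#' @param msa an [msa()] object.
#' @param windows list of integer row-index vectors (from
#'   [sliding_windows()]); `NULL` means one full window, i.e. the complete
#'   directed graph.
#' @param cm a [cost_model()].
#' @return An `encodability_graph`: list with `n`, `edges` (data frame
#'   `from`, `to`, `weight`; `from = 0` is the dummy root) and `cost_model`.
#' @export
build_graph <- function(msa, windows = NULL, cm = cost_model(msa)) {
  stopifnot(inherits(msa, "msa"))
  n <- msa$n
  if (is.null(windows)) windows <- list(seq_len(n))
  covered <- sort(unique(unlist(windows)))
  if (!identical(covered, seq_len(n))) {
    stop("windows must cover every row index exactly once or more")
  }

  # unordered pairs within windows, deduplicated across windows
  pr <- lapply(windows, function(w) {
    w <- as.integer(w)
    if (length(w) < 2L) return(NULL)
    cbind(rep(w, each = length(w)), rep.int(w, length(w)))
  })
  pm <- do.call(rbind, pr)
  edges_seq <- NULL
  if (!is.null(pm)) {
    pm <- pm[pm[, 1L] < pm[, 2L], , drop = FALSE]
    pm <- pm[!duplicated(pm[, 1L] + (n + 1) * pm[, 2L]), , drop = FALSE]
    B <- msa_bytes(msa)
    w <- vapply(seq_len(nrow(pm)), function(k) {
      r <- rle(B[pm[k, 1L], ] != B[pm[k, 2L], ])
      delta_record_bits(r$lengths[r$values], cm)
    }, numeric(1))
    # mismatch positions are symmetric between aligned rows, so the delta
    # cost is direction-independent; emit both directed edges
    edges_seq <- data.frame(
      from = c(pm[, 1L], pm[, 2L]),
      to = c(pm[, 2L], pm[, 1L]),
      weight = c(w, w)
    )
  }
  rc <- reference_cost(msa, cm)
  edges <- rbind(
    data.frame(from = 0L, to = seq_len(n), weight = rc),
    edges_seq
  )
  structure(list(n = n, edges = edges, cost_model = cm),
            class = "encodability_graph")
}

#' @export
print.encodability_graph <- function(x, ...) {
  cat(sprintf("<encodability_graph> %d rows + dummy root, %d edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}
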