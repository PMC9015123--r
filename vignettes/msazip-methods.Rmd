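---
title: "How msazip compresses alignments: model, costs, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How msazip compresses alignments: model, costs, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msazip)
```

## The problem

A multiple sequence alignment (MSA) is an `n x l` character matrix over a
small alphabet (typically `{a, c, g, t, -}`), where rows are homologous
sequences and columns homologous sites. Alignments are often highly
redundant — most rows are small perturbations of other rows — yet
general-purpose byte compressors see only a linear stream of text.
`msazip` exploits the redundancy explicitly: it stores a few rows verbatim
("references") and everything else as a small set of *mismatch runs*
against another row, choosing the references and the referencing order so
that the total encoded size is minimal, exactly.

## Representational cost

Two alignment-wide constants price everything:

* `N = max(1, ceiling(log2 |alphabet|))` — bits per character,
* `I = max(1, ceiling(log2 max(n, l)))` — bits per index (row or column).

Storing a row verbatim costs `I + l*N` bits (its original position, so the
decompressed MSA keeps the input order, plus its characters) plus a 1-bit
record tag. Storing a row as a delta against a parent row costs the runs:
each maximal block of differing columns is stored as an `I`-bit start
column, a varint length, and `N` bits per replacement character, plus fixed
per-record overhead (tag, own index, parent index, varint run count). The
gap character is an ordinary alphabet symbol: within an alignment all rows
have equal length, so substitution runs are a *complete* delta grammar and
no indel logic is needed.

A deliberate invariant, enforced by tests, is **cost fidelity**: the edge
weights used during optimisation are the exact serialized record sizes in
bits, so the optimiser minimises the real pre-backend archive, not a proxy.
A consequence of this concrete scheme is that the delta cost is symmetric
(`C[i,j] = C[j,i]`): mismatch *positions* between two aligned rows do not
depend on direction, and our per-run price depends only on run count and
lengths. The graph machinery is nonetheless fully directed, because the
arborescence below needs directed edges.

## The encodability graph and the arborescence

Build a directed graph on the `n` rows plus a dummy root: the root has an
edge to every row weighted by the full reference cost, and row `i` has an
edge to row `j` weighted by the delta cost of encoding `j` given `i`. Any
spanning arborescence rooted at the dummy vertex is a valid storage plan —
root children are stored verbatim, every other row as a delta against its
parent, decodable top-down — and its total weight *is* the stored size.
Therefore the **minimum spanning arborescence** yields an optimal reference
set and hierarchical referencing order. We solve it with the
Chu-Liu/Edmonds algorithm (`O(VE)`), with deterministic tie-breaking
(lower source id wins; the root has the lowest id) so archives are
bit-reproducible. An exhaustive oracle (`brute_force_arborescence()`,
feasible up to 8 rows) independently verifies optimality on hundreds of
random graphs in the test suite.

## Likelihood ranking and sparse windows

The complete graph costs `O(n^2 l)` to weigh. To stay near-linear we only
connect rows that are likely to be similar. Each row is scored by its
log-likelihood under the alignment's own column profiles:

```
log p(row i) = sum_j log( F[i,j] / n )
```

where `F[i,j]` counts how often row `i`'s character at column `j` occurs in
column `j`. Columns are treated as independent; the score is finite (each
character counts itself) and rows near the column-wise consensus score
highest. Sorting rows by this score places similar rows adjacently; a
sliding window of length `l_w` with step `l_s = l_w - overlap` then cuts the
order into overlapping cliques, and only intra-clique edges are priced. For
`n > l_w` there are exactly `ceiling((n - l_w)/l_s) + 1` windows; the final
window is clipped to end at position `n` rather than run short, so tail rows
also sit in a full-size clique. Edge count is `O(n)` at fixed `l_w, l_s`.

Sorting direction and tie rule are not dictated by the ranking idea itself;
we use descending likelihood with ties broken by original row index, purely
for determinism. Natural logs are used since only the ordering matters.

**Defaults:** `window_length = 30`, `overlap = 20` — the strongest of the
standard grid (5/3, 10/7, 20/15, 30/20) on ribosomal-RNA-scale data, and a
reasonable speed/ratio compromise. A single full window (`windows = NULL`
in `build_graph()`) recovers the exact complete-graph optimum and is the
upper bound on what any window setting can achieve: adding edges can never
increase the optimal arborescence weight. This monotonicity is asserted at
the total-weight level in the tests.

## Archive layout and the entropy backend

Records are written parents-first (siblings by original index), so decoding
is a single pass. The field *encodings* follow the cost model exactly, but
the fields are grouped **column-wise** into per-series byte-aligned
streams — all run starts together, all run characters together, and so on —
the way CRAM groups its data series into blocks. The grouping costs nothing
(per-record bit totals are unchanged, stream padding is a few bits of
container overhead) and matters a great deal at the final stage: the
entropy backend (bzip2 by default; gzip, xz and none are also available)
sees homogeneous, mutually redundant streams instead of interleaved
bit-packed records, and compresses them far better. An outer envelope
(magic, version, backend id, pre-backend size, Adler-32 checksum) makes
archives self-describing and corruption detectable.

Headers are kept verbatim in their own length-prefixed block: the tool is
lossless for the whole FASTA record, not just the sequence bytes, and
upper/lower case are distinct symbols throughout. References and metadata
travel through one backend stream, not two.

## The synthetic generator

`generate_msa()` emulates the one property the compressor depends on —
graded redundancy between rows — without attempting realistic molecular
evolution. A uniform random root row is evolved down a star, random-binary
or clustered-k tree; on each branch every site is redrawn uniformly from
the non-gap alphabet with probability `divergence` (so `divergence = 1` is
exact saturation, giving the analytic `(K-1)/K` expected mismatch between
rows, which the tests verify by Monte Carlo). Shared gap runs (1–5 columns,
a random ~half of the rows) are overlaid at rate `gap_prob = 0.01` per
column by default, replacing characters so rows stay aligned. What it does
*not* model: substitution-rate heterogeneity, true indels, conserved
blocks, base composition bias. Passing tests therefore demonstrate the
pipeline's behaviour under controlled redundancy, not performance claims on
any particular biological corpus.

## Numerical and degenerate-input choices

* Weights are integer bit counts end to end; the solver needs no floating
  point tolerance anywhere.
* `n = 1` alignments force the single root edge; `l = 1` and single-symbol
  alphabets get floor widths `N, I >= 1`.
* A duplicate ordered pair appearing in several windows is priced once.
* Zero-mismatch deltas are legal and cheap (fixed overhead only), which is
  why an alignment of identical rows archives as one reference plus empty
  deltas.
* Varints use 8-bit groups with 7 payload bits; run starts are absolute
  `I`-bit columns (0-based on the wire), not deltas — keeping the printed
  cost formula exact.
* The decompressor validates magic, version, backend id, payload size and
  checksum before touching the body, and distinguishes "unrecognized
  archive" from "corrupt archive".

## Problem sizes used in the checks

The package's own verification runs at desk scale, chosen once: the
lossless fuzz corpus draws 200 alignments with `n` and `l` log-uniform over
`[1, 200] x [1, 5000]` (four extreme corners forced), divergence from zero
to saturation, DNA and protein alphabets; solver-vs-oracle agreement uses
500 random root-connected graphs on 3–7 vertices; the densification and
backend-gain checks use 20 seeds at `n = 100` (`l = 500`, divergence 5% and
`l = 2000`, divergence 1% respectively); the divergence-ratio correlation
uses a 7-point divergence grid with 20 seeds at `n = 60, l = 400`. The
`scripts/acceptance.R` report recomputes the same quantities (with a
40-case fuzz corpus) from a command-line seed.

## Known limitations

* The likelihood ranking is a heuristic: with small windows, rows that are
  similar but score differently may never share a clique. The full-window
  mode is exact but `O(n^2 l)`.
* Row indices are stored in fixed `I`-bit fields; alignments beyond
  `2^31` rows or columns are out of scope.
* The delta grammar is substitution-only by design; the tool compresses
  *alignments*, not unaligned sequence sets.
* Compression gain degrades gracefully toward saturation divergence; on
  essentially random alignments the arborescence simply stores most rows as
  references and the result approaches backend-only compression of the raw
  characters.
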