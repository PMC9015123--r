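#' Minimum spanning arborescence of an encodability graph
#'
#' Chu-Liu/Edmonds algorithm, rooted at the dummy vertex: repeatedly pick the
#' cheapest incoming edge of every row vertex; if the picks are acyclic they
#' are the answer, otherwise a cycle is contracted into a supernode with
#' incoming weights reduced by the cycle edge they displace, and the problem
#' recurses. Runs in `O(VE)`. Children of the root in the result are the
#' reference sequences; every other row is delta-encoded against its parent.
#'
#' Among equal-weight incoming edges the lower source vertex id wins (the
#' dummy root, id 0, is lowest), so the output — and therefore the archive —
#' is bit-reproducible for a fixed input. Weights are integers (bits); no
#' floating-point tolerance is involved.
#'
#' @param g an `encodability_graph` from [build_graph()].
#' @return An `arborescence`: list with `parent` (integer vector of length
#'   `n`; `parent[i] = 0` means row `i` is a reference), `total_weight` (sum
#'   of chosen edge weights, in bits) and `references` (sorted root
#'   children).
#' @examples
#' m <- msa(c("acgtacgt", "acgaacgt", "tcgaacgg"))
#' min_arborescence(build_graph(m))
#' @export
min_arborescence <- function(g) {
  stopifnot(inherits(g, "encodability_graph"))
  ed <- g$edges
  # internal labels: 1 = dummy root, row i = i + 1
  sel <- edmonds_solve(g$n + 1L, ed$from + 1L, ed$to + 1L, ed$weight,
                       seq_len(nrow(ed)))
  parent <- integer(g$n)
  parent[ed$to[sel]] <- ed$from[sel]
  new_arborescence(parent, sum(ed$weight[sel]))
}

new_arborescence <- function(parent, total_weight) {
  structure(
    list(parent = as.integer(parent),
         total_weight = as.numeric(total_weight),
         references = which(parent == 0L)),
    class = "arborescence"
  )
}

# Recursive Chu-Liu/Edmonds on vertex labels 1..nv with root 1.
# from/to/w/eid are parallel edge vectors; eid values are stable original
# edge identifiers. Returns the eids of the chosen arborescence edges.
edmonds_solve <- function(nv, from, to, w, eid) {
  if (nv == 1L) return(integer(0))
  # cheapest in-edge per vertex; ties by source id then eid for determinism
  ord <- order(to, w, from, eid)
  first <- ord[!duplicated(to[ord])]
  bto <- to[first]
  if (length(setdiff(2:nv, bto))) stop("graph not root-connected")
  bestedge <- integer(nv)
  bestedge[bto] <- first
  parent <- integer(nv)
  parent[bto] <- from[first]

  # cycle detection in the functional parent graph
  state <- integer(nv)   # 0 new, 1 on current path, 2 settled
  state[1L] <- 2L
  cyc <- NULL
  for (v in 2:nv) {
    if (state[v] != 0L) next
    u <- v
    path <- integer(0)
    while (state[u] == 0L) {
      state[u] <- 1L
      path <- c(path, u)
      u <- parent[u]
    }
    if (state[u] == 1L) {
      cyc <- path[which(path == u):length(path)]
      state[path] <- 2L
      break
    }
    state[path] <- 2L
  }
  if (is.null(cyc)) return(eid[bestedge[2:nv]])

  # contract the cycle into one supernode
  incyc <- logical(nv)
  incyc[cyc] <- TRUE
  newlab <- integer(nv)
  newlab[!incyc] <- seq_len(sum(!incyc))   # root stays label 1
  cl <- sum(!incyc) + 1L
  newlab[incyc] <- cl

  nf <- newlab[from]
  nt <- newlab[to]
  wadj <- w
  entering <- nt == cl & nf != cl
  wadj[entering] <- w[entering] - w[bestedge[to[entering]]]
  keep <- nf != nt
  sub <- edmonds_solve(cl, nf[keep], nt[keep], wadj[keep], eid[keep])

  # expand: the chosen edge entering the supernode displaces one cycle edge
  ke <- which(keep)
  into_cl <- ke[nt[keep] == cl & eid[keep] %in% sub]
  vstar <- to[into_cl[1L]]
  c(sub, eid[bestedge[setdiff(cyc, vstar)]])
}

#' Exhaustive minimum-arborescence oracle
#'
#' Enumerates every parent assignment (each row vertex picks one of its
#' incoming edges), keeps the root-connected acyclic ones and returns a
#' minimum-total-weight arborescence. Exponential in the worst case, so it
#' refuses graphs with more than 8 row vertices; it exists purely as an
#' independent check that the Chu-Liu/Edmonds solver is optimal.
#'
#' @param g an `encodability_graph` with `n <= 8`.
#' @return An `arborescence` (ties resolved to the lexicographically smallest
#'   parent vector).
#' @export
brute_force_arborescence <- function(g) {
  stopifnot(inherits(g, "encodability_graph"))
  n <- g$n
  if (n > 8L) stop("brute_force_arborescence refuses n > 8")
  ed <- g$edges
  cand <- split(seq_len(nrow(ed)), factor(ed$to, levels = seq_len(n)))
  sizes <- vapply(cand, length, integer(1))
  if (any(sizes == 0L)) stop("graph not root-connected")
  if (prod(sizes) > 4e6) stop("graph too dense for exhaustive enumeration")
  combos <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
  nc <- nrow(combos)
  par <- matrix(ed$from[combos], nc, n)
  # root-connectivity: iterate the parent map n times; survivors of any
  # cycle never reach 0
  cur <- par
  for (step in seq_len(n)) {
    idx <- which(cur != 0L)
    if (!length(idx)) break
    rows <- (idx - 1L) %% nc + 1L
    cur[idx] <- par[cbind(rows, cur[idx])]
  }
  ok <- rowSums(cur != 0L) == 0L
  if (!any(ok)) stop("graph not root-connected")
  wsum <- rowSums(matrix(ed$weight[combos], nc, n))
  wsum[!ok] <- Inf
  best <- which(wsum == min(wsum))
  if (length(best) > 1L) {
    pv <- par[best, , drop = FALSE]
    o <- do.call(order, as.data.frame(pv))
    best <- best[o[1L]]
  }
  new_arborescence(par[best, ], wsum[best])
}

#' @export
print.arborescence <- function(x, ...) {
  cat(sprintf("<arborescence> %d rows, %d reference(s), total weight %s bits\n",
              length(x$parent), length(x$references),
              format(x$total_weight, big.mark = ",")))
  invisible(x)
}

#' @describeIn min_arborescence `tidy()` returns the parent edges as a tibble
#'   (`child`, `parent`, `is_reference`).
#' @param x an `arborescence`.
#' @param ... unused.
#' @export
tidy.arborescence <- function(x, ...) {
  tibble(
    child = seq_along(x$parent),
    parent = x$parent,
    is_reference = x$parent == 0L
  )
}

#' @describeIn min_arborescence `glance()` returns a one-row summary
#'   (`n`, `n_references`, `total_weight`).
#' @export
glance.arborescence <- function(x, ...) {
  tibble(
    n = length(x$parent),
    n_references = length(x$references),
    total_weight = x$total_weight
  )
}
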