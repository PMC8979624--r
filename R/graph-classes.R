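#' Weighted graph container
#'
#' A minimal container for an undirected, non-negatively weighted graph on
#' `n` nodes: a symmetric `n x n` weight matrix with an exactly-zero
#' diagonal. All graph-metric functions in the package accept either a
#' `weighted_graph` or a bare matrix satisfying the same invariants.
#'
#' @param weights symmetric numeric matrix, zero diagonal, finite
#'   non-negative entries.
#' @param labels optional character vector of node labels.
#' @return An object of class `weighted_graph` with fields `n`, `weights`,
#'   `labels`.
#' @export
weighted_graph <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights)) stop("`weights` must be square", call. = FALSE)
  if (!all(is.finite(weights))) stop("weights must be finite", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("weights must be symmetric", call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  if (length(labels) != n) stop("labels length must equal n", call. = FALSE)
  structure(list(n = n, weights = weights, labels = labels),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  e <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<weighted_graph> %d nodes, %d edges, density %.1f%%\n",
              x$n, e, 100 * e / (x$n * (x$n - 1) / 2)))
  invisible(x)
}

as_weight_matrix <- function(A) {
  if (inherits(A, "weighted_graph")) A$weights else as.matrix(A)
}

#' Backbone topology specification
#'
#' Describes the ground-truth graph on which the synthetic generator plants
#' envelope coupling: a Watts-Strogatz small world, a ring lattice, or an
#' Erdos-Renyi graph with matched edge count, plus a uniform edge-weight
#' distribution.
#'
#' @param kind one of `"watts_strogatz"`, `"ring_lattice"`, `"erdos_renyi"`.
#' @param n node count (>= 3).
#' @param k mean degree; must be even and `< n` for the ring constructions.
#' @param p_rewire rewiring probability in `[0, 1]` (Watts-Strogatz only).
#' @param weight_dist length-2 numeric `c(lo, hi)`: edge weights are drawn
#'   i.i.d. uniform on `[lo, hi]`.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(kind = c("watts_strogatz", "ring_lattice",
                                   "erdos_renyi"),
                          n, k, p_rewire = 0.1, weight_dist = c(1, 1)) {
  kind <- match.arg(kind)
  n <- as.integer(n); k <- as.integer(k)
  if (n < 3L) stop("n must be >= 3", call. = FALSE)
  if (k >= n) stop("k must be < n", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (kind != "erdos_renyi" && k %% 2L != 0L) {
    stop("ring constructions require even k", call. = FALSE)
  }
  if (p_rewire < 0 || p_rewire > 1) stop("p_rewire must be in [0,1]",
                                         call. = FALSE)
  if (length(weight_dist) != 2L || weight_dist[1] > weight_dist[2] ||
      weight_dist[1] < 0) {
    stop("weight_dist must be c(lo, hi) with 0 <= lo <= hi", call. = FALSE)
  }
  structure(list(kind = kind, n = n, k = k, p_rewire = p_rewire,
                 weight_dist = as.numeric(weight_dist)),
            class = "backbone_spec")
}
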