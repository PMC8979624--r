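#' Node strength
#'
#' Mean weight of each node's connections. With the structurally zero
#' diagonal, the default `mean_offdiag` mode averages each column over its
#' `N - 1` off-diagonal entries; `mean_incl_diag` divides by `N` (a plain
#' column mean), `sum` returns the column sum.
#'
#' @param A a [weighted_graph()] or symmetric non-negative matrix.
#' @param mode `"mean_offdiag"` (default), `"mean_incl_diag"` or `"sum"`.
#' @return numeric vector of length N.
#' @export
node_strength <- function(A, mode = c("mean_offdiag", "mean_incl_diag",
                                      "sum")) {
  mode <- match.arg(mode)
  W <- as_weight_matrix(A)
  n <- nrow(W)
  if (n < 2L) stop("need >= 2 nodes", call. = FALSE)
  s <- colSums(W)
  switch(mode,
         mean_offdiag = s / (n - 1),
         mean_incl_diag = s / n,
         sum = s)
}

#' Average connectivity
#'
#' Node strength averaged across nodes; equals the mean of all off-diagonal
#' entries under the default strength mode.
#'
#' @inheritParams node_strength
#' @return scalar.
#' @export
average_connectivity <- function(A, mode = "mean_offdiag") {
  mean(node_strength(A, mode = mode))
}

#' Onnela weighted clustering coefficient
#'
#' Weights are normalized by the graph maximum, `w_hat = w / max(w)`, and
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w_hat_ij w_hat_ih w_hat_jh)^{1/3}`
#' with `k_i` the binary degree; `C_i = 0` for nodes of degree < 2, and an
#' all-zero graph yields all-zero clustering (documented, not an error).
#' Invariant under global rescaling of the weights.
#'
#' @param A a [weighted_graph()] or symmetric non-negative matrix.
#' @return list with `per_node` (length-N vector) and `mean`.
#' @export
weighted_clustering_onnela <- function(A) {
  W <- as_weight_matrix(A)
  mx <- max(W)
  n <- nrow(W)
  if (mx == 0) return(list(per_node = numeric(n), mean = 0))
  S <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  num <- diag(S %*% S %*% S)
  per <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  list(per_node = per, mean = mean(per))
}

#' Characteristic weighted path length
#'
#' Edge lengths are inverse weights (`1/w`; absent edges are unreachable);
#' all-pairs shortest paths are computed with Dijkstra's algorithm (via
#' igraph), and `L` is the mean of the finite off-diagonal distances. The
#' fraction of unreachable ordered pairs is reported alongside.
#'
#' @param A a [weighted_graph()] or symmetric non-negative matrix with at
#'   least one edge.
#' @return list with `l` (characteristic path length), `unreachable_frac`,
#'   and `distances` (the N x N matrix, `Inf` for unreachable pairs).
#' @export
weighted_path_length <- function(A) {
  W <- as_weight_matrix(A)
  n <- nrow(W)
  if (all(W == 0)) stop("graph has no edges: path length undefined",
                        call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  list(l = mean(off[finite]),
       unreachable_frac = mean(!finite),
       distances = D)
}

# upper-triangle pairs ordered by (ring distance, lexicographic index)
ring_ordered_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- pmin(idx[, 2] - idx[, 1], n - (idx[, 2] - idx[, 1]))
  o <- order(d, idx[, 1], idx[, 2])
  idx[o, , drop = FALSE]
}

#' Lattice equivalent of a weighted graph
#'
#' The lattice null model: same node count, edge count and weight multiset
#' as the input, arranged as a ring lattice. Edges fill the shortest ring
#' distances first (distance-1 shell, then distance-2, ...); observed
#' weights sorted descending are assigned to edges sorted ascending by ring
#' distance, so the strongest weights are the most local. Deterministic.
#'
#' @param A a [weighted_graph()] or symmetric non-negative matrix.
#' @return A [weighted_graph()] with identical weight multiset.
#' @export
lattice_equivalent <- function(A) {
  W <- as_weight_matrix(A)
  n <- nrow(W)
  w <- W[upper.tri(W)]
  w <- w[w > 0]
  e <- length(w)
  if (e == 0) return(weighted_graph(matrix(0, n, n)))
  pairs <- ring_ordered_pairs(n)[seq_len(e), , drop = FALSE]
  L <- matrix(0, n, n)
  L[pairs] <- sort(w, decreasing = TRUE)
  weighted_graph(L + t(L))
}

#' Random equivalent of a weighted graph
#'
#' Each realization places the observed edges on a uniformly random simple
#' topology with the same node and edge count, and randomly permutes the
#' observed weight multiset onto them. Onnela clustering (mean) and
#' characteristic path length are averaged over `n_reps` realizations.
#'
#' @param A a [weighted_graph()] or symmetric non-negative matrix.
#' @param seed integer seed (realizations are deterministic given it).
#' @param n_reps number of realizations (>= 1).
#' @param return_graphs also return the realized weight matrices (for
#'   inspection; off by default).
#' @return list with `c_rand`, `l_rand`, `unreachable_frac` (mean over
#'   reps), `n_reps`, and `graphs` when requested.
#' @export
random_equivalent <- function(A, seed = 1L, n_reps = 10L,
                              return_graphs = FALSE) {
  W <- as_weight_matrix(A)
  n <- nrow(W)
  w <- W[upper.tri(W)]
  w <- w[w > 0]
  e <- length(w)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (e == 0) stop("graph has no edges", call. = FALSE)
  all_pairs <- which(upper.tri(matrix(0, n, n)))
  cs <- numeric(n_reps); ls <- numeric(n_reps); uf <- numeric(n_reps)
  graphs <- if (return_graphs) vector("list", n_reps) else NULL
  with_local_seed(seed, {
    for (r in seq_len(n_reps)) {
      sel <- sample(all_pairs, e)
      R <- matrix(0, n, n)
      R[sel] <- sample(w)
      R <- R + t(R)
      cs[r] <- weighted_clustering_onnela(R)$mean
      pl <- weighted_path_length(R)
      ls[r] <- pl$l
      uf[r] <- pl$unreachable_frac
      if (return_graphs) graphs[[r]] <- R
    }
  })
  out <- list(c_rand = mean(cs), l_rand = mean(ls),
              unreachable_frac = mean(uf), n_reps = n_reps)
  if (return_graphs) out$graphs <- graphs
  out
}

#' Small-world deviations from the lattice and random equivalents
#'
#' `delta_c = (C_latt - C_obs) / (C_latt - C_rand)` and
#' `delta_l = (L_obs - L_rand) / (L_latt - L_rand)`, each clipped to
#' `[0, 1]`. A degenerate denominator (lattice and random nulls coincide)
#' yields a deviation of 0 with a warning.
#'
#' @param c_obs,c_latt,c_rand,l_obs,l_latt,l_rand clustering and path-length
#'   values for the observed graph and its two nulls.
#' @return list with `delta_c`, `delta_l`.
#' @export
swp_deltas <- function(c_obs, c_latt, c_rand, l_obs, l_latt, l_rand) {
  if (is.null(.swpnet_state$dl_notice)) {
    .swpnet_state$dl_notice <- TRUE
    message("swpnet: delta-L is computed as (L_obs - L_rand)/(L_latt - L_rand)")
  }
  safe_ratio <- function(num, den, what) {
    if (abs(den) < 1e-12) {
      warning(sprintf("%s: lattice and random nulls coincide; deviation set to 0",
                      what), call. = FALSE)
      0
    } else num / den
  }
  dc <- safe_ratio(c_latt - c_obs, c_latt - c_rand, "delta_c")
  dl <- safe_ratio(l_obs - l_rand, l_latt - l_rand, "delta_l")
  list(delta_c = min(max(dc, 0), 1), delta_l = min(max(dl, 0), 1))
}

#' Small-World Propensity from clipped deviations
#'
#' `SWP = 1 - sqrt(0.5 * (delta_c^2 + delta_l^2))`; with deviations in
#' `[0, 1]` the result lies in `[0, 1]`. Vectorized.
#'
#' @param delta_c,delta_l deviations in `[0, 1]` (clipped if not).
#' @return SWP value(s) in `[0, 1]`.
#' @export
swp_from_deltas <- function(delta_c, delta_l) {
  dc <- pmin(pmax(delta_c, 0), 1)
  dl <- pmin(pmax(delta_l, 0), 1)
  1 - sqrt(0.5 * (dc^2 + dl^2))
}

# everything SWP and sigma need, computed once
small_world_indices <- function(A, seed = 1L, n_reps = 10L) {
  W <- as_weight_matrix(A)
  c_obs <- weighted_clustering_onnela(W)$mean
  pl <- weighted_path_length(W)
  latt <- lattice_equivalent(W)
  c_latt <- weighted_clustering_onnela(latt)$mean
  l_latt <- weighted_path_length(latt)$l
  rnd <- random_equivalent(W, seed = seed, n_reps = n_reps)
  d <- swp_deltas(c_obs, c_latt, rnd$c_rand, pl$l, l_latt, rnd$l_rand)
  sigma <- if (rnd$c_rand > 0 && pl$l > 0) {
    (c_obs / rnd$c_rand) / (pl$l / rnd$l_rand)
  } else NA_real_
  list(swp = swp_from_deltas(d$delta_c, d$delta_l),
       sigma = sigma,
       delta_c = d$delta_c, delta_l = d$delta_l,
       c_obs = c_obs, c_latt = c_latt, c_rand = rnd$c_rand,
       l_obs = pl$l, l_latt = l_latt, l_rand = rnd$l_rand,
       unreachable_frac = pl$unreachable_frac,
       unreliable = pl$unreachable_frac > 0.05,
       n_null = n_reps, seed = seed)
}

#' Small-World Propensity of a weighted graph
#'
#' Quantifies how far the observed weighted clustering and path length sit
#' between their lattice and random equivalents:
#' `SWP = 1 - sqrt(0.5 (delta_c^2 + delta_l^2))`, in `[0, 1]`. Values above
#' 0.6 are conventionally read as the small-world regimen. The result is
#' flagged unreliable when more than 5 percent of node pairs are
#' unreachable in the observed graph.
#'
#' @param A a [weighted_graph()] or symmetric non-negative matrix with at
#'   least one edge.
#' @param seed RNG seed for the random null.
#' @param n_reps random-null realizations (default 10; the lattice null is
#'   deterministic).
#' @return list of class `swp_result`: `swp`, `delta_c`, `delta_l`,
#'   `c_obs`, `c_latt`, `c_rand`, `l_obs`, `l_latt`, `l_rand`,
#'   `small_world` (`swp > 0.6`), `unreachable_frac`, `unreliable`,
#'   `n_null`, `seed`.
#' @export
small_world_propensity <- function(A, seed = 1L, n_reps = 10L) {
  res <- small_world_indices(A, seed = seed, n_reps = n_reps)
  res$small_world <- res$swp > 0.6
  res$sigma <- NULL
  class(res) <- "swp_result"
  res
}

#' @export
print.swp_result <- function(x, ...) {
  cat(sprintf("<swp_result> SWP = %.4f (dC = %.3f, dL = %.3f)%s\n",
              x$swp, x$delta_c, x$delta_l,
              if (x$small_world) " [small-world]" else ""))
  invisible(x)
}

#' Classic small-worldness index sigma
#'
#' `sigma = (C_obs / C_rand) / (L_obs / L_rand)` against the same
#' random-equivalent null as [small_world_propensity()]. Values above 1
#' indicate small-world topology, but unlike SWP the index depends strongly
#' on graph density. Undefined (NA, with warning) when `C_rand = 0`.
#'
#' @inheritParams small_world_propensity
#' @return list with `sigma`, `small_world` (`sigma > 1`), the underlying
#'   metric values, `n_null`, `seed`.
#' @export
sigma_small_worldness <- function(A, seed = 1L, n_reps = 10L) {
  res <- small_world_indices(A, seed = seed, n_reps = n_reps)
  if (is.na(res$sigma)) {
    warning("sigma undefined: random-equivalent clustering is zero",
            call. = FALSE)
  }
  list(sigma = res$sigma,
       small_world = isTRUE(res$sigma > 1),
       c_obs = res$c_obs, c_rand = res$c_rand,
       l_obs = res$l_obs, l_rand = res$l_rand,
       n_null = n_reps, seed = seed)
}

#' SWP and sigma curves over the density sweep
#'
#' Applies each (carrier, density) consistency mask to every subject's
#' adjacency matrix and computes SWP and sigma. Cells whose thresholded
#' graph has no surviving edge are NA and flagged; cells with more than 5
#' percent unreachable pairs are flagged unreliable but kept.
#'
#' @param sweep a [consistency_threshold()] result.
#' @param stack the [adjacency_stack()] it was derived from.
#' @param seed master seed; each cell uses a deterministic offset derived
#'   from the carrier, density and cell data, so neither execution order
#'   nor subject ordering can change results.
#' @param n_reps random-null realizations per cell.
#' @return Object of class `swp_curve_set`: arrays `swp`, `sigma`,
#'   `unreliable`, `edgeless` indexed `subject x carrier x density`, plus
#'   `density_grid` and `carriers_hz`.
#' @export
metric_density_curves <- function(sweep, stack, seed = 1L, n_reps = 10L) {
  stopifnot(inherits(sweep, "density_sweep"),
            inherits(stack, "adjacency_stack"))
  if (!isTRUE(all.equal(sweep$carriers_hz, stack$carriers_hz))) {
    stop("sweep and stack carrier grids differ", call. = FALSE)
  }
  ns <- stack$n_subjects
  nc <- length(stack$carriers_hz)
  nd <- length(sweep$density_grid)
  dm <- c(ns, nc, nd)
  swp <- array(NA_real_, dm); sig <- array(NA_real_, dm)
  unrel <- array(FALSE, dm); edgeless <- array(FALSE, dm)
  for (s in seq_len(ns)) {
    for (ci in seq_len(nc)) {
      As <- stack$weights[s, ci, , ]
      for (di in seq_len(nd)) {
        W <- As * sweep$masks[ci, di, , ]
        if (all(W == 0)) {
          edgeless[s, ci, di] <- TRUE
          next
        }
        # seed keyed to (carrier, density, cell data), not the subject's
        # row position: permuting subjects permutes curve rows exactly,
        # and execution order cannot change results
        h <- as.integer(round(sum(W) * 1e4) %% 65536)
        cell_seed <- seed + ci * 1000000L + di * 70000L + h
        res <- tryCatch(
          small_world_indices(W, seed = cell_seed, n_reps = n_reps),
          error = function(e) {
            stop(sprintf("subject %d, carrier %.4g Hz, density %g%%: %s",
                         s, stack$carriers_hz[ci], sweep$density_grid[di],
                         conditionMessage(e)), call. = FALSE)
          })
        swp[s, ci, di] <- res$swp
        sig[s, ci, di] <- res$sigma
        unrel[s, ci, di] <- res$unreliable
      }
    }
  }
  structure(list(swp = swp, sigma = sig, unreliable = unrel,
                 edgeless = edgeless,
                 density_grid = sweep$density_grid,
                 carriers_hz = stack$carriers_hz),
            class = "swp_curve_set")
}
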