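#' Generate a toy weighted graph from a backbone specification
#'
#' Deterministic given `seed`. Ring-lattice and Watts-Strogatz constructions
#' have exactly `n * k / 2` edges; Erdos-Renyi draws the same edge count
#' uniformly at random so densities are matched across kinds. Edge weights
#' are i.i.d. uniform on `weight_dist` and symmetrized.
#'
#' @param spec a [backbone_spec()].
#' @param seed integer RNG seed.
#' @return A [weighted_graph()].
#' @export
generate_toy_graph <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "backbone_spec"))
  with_local_seed(seed, {
    g <- switch(spec$kind,
      ring_lattice = igraph::sample_smallworld(
        dim = 1, size = spec$n, nei = spec$k / 2L, p = 0,
        loops = FALSE, multiple = FALSE),
      watts_strogatz = igraph::sample_smallworld(
        dim = 1, size = spec$n, nei = spec$k / 2L, p = spec$p_rewire,
        loops = FALSE, multiple = FALSE),
      erdos_renyi = igraph::sample_gnm(
        spec$n, m = round(spec$n * spec$k / 2), directed = FALSE)
    )
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- runif(nrow(el), spec$weight_dist[1], spec$weight_dist[2])
    W <- matrix(0, spec$n, spec$n)
    W[el] <- w
    W <- W + t(W)
    weighted_graph(W)
  })
}

#' Multi-subject noisy copies of a ground-truth adjacency
#'
#' Fixture generator for consistency thresholding: each subject's matrix is
#' the truth plus i.i.d. Gaussian noise on the existing edges, symmetrized,
#' with negative values rectified to zero. Non-edges stay exactly zero so the
#' edge support is shared across subjects.
#'
#' @param truth a [weighted_graph()] (or plain symmetric matrix).
#' @param n_subjects number of subjects.
#' @param noise_sd standard deviation of the additive edge noise (>= 0).
#' @param seed integer RNG seed.
#' @return An `adjacency_stack` (see [adjacency_stack()]) with one carrier.
#' @export
generate_multisubject_adjacency <- function(truth, n_subjects, noise_sd,
                                            seed = 1L) {
  W <- as_weight_matrix(truth)
  n <- nrow(W)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  ut <- upper.tri(W)
  edge_idx <- which(ut & W > 0)
  arr <- array(0, dim = c(n_subjects, 1L, n, n))
  with_local_seed(seed, {
    for (s in seq_len(n_subjects)) {
      Ws <- W
      Ws[edge_idx] <- pmax(0, W[edge_idx] + rnorm(length(edge_idx),
                                                  sd = noise_sd))
      Ws[lower.tri(Ws)] <- 0
      Ws <- Ws + t(Ws)
      arr[s, 1L, , ] <- Ws
    }
  })
  adjacency_stack(arr, carriers_hz = NA_real_)
}
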