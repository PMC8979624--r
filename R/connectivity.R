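#' Orthogonalize one analytic signal with respect to another
#'
#' Removes the instantaneously coherent (zero-lag, same-phase) component of
#' `y` along `x`: `y_orth(t) = Im( y(t) * Conj(x(t)) / |x(t)| )`. The result
#' is the quadrature component of `y` relative to `x`; any signal that is a
#' real multiple of `x` maps to exactly zero, which is what suppresses
#' spurious envelope correlation from instantaneous field spread.
#'
#' Magnitudes of `x` below `.Machine$double.eps * max(|x|)` are floored to
#' that value to keep the division stable.
#'
#' @param x,y complex vectors of equal length.
#' @return Real vector `y` orthogonalized with respect to `x`.
#' @export
orthogonalize <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  m <- Mod(x)
  mx <- max(m)
  if (mx == 0) stop("cannot orthogonalize against an all-zero signal",
                    call. = FALSE)
  m <- pmax(m, .Machine$double.eps * mx)
  Im(y * Conj(x) / m)
}

# log power with a magnitude floor (natural log of squared envelope)
log_power <- function(env) {
  mx <- max(env)
  if (mx == 0) stop("constant zero envelope: log-power undefined",
                    call. = FALSE)
  2 * log(pmax(env, .Machine$double.eps * mx))
}

#' Orthogonalized power-envelope correlation (Fisher z)
#'
#' The symmetric envelope-correlation edge weight: both directions
#' `r(log|x|^2, log|y_orth_x|^2)` and `r(log|y|^2, log|x_orth_y|^2)` are
#' computed, each Pearson `r` is clipped to `1 - 1e-12` in magnitude and
#' Fisher-transformed (`atanh`), and the two z values are averaged.
#'
#' @param x,y complex analytic coefficient series (same carrier), equal
#'   length, at least 30 samples.
#' @return A single Fisher-z weight (may be negative; rectification is the
#'   adjacency builder's decision, not this function's).
#' @export
envelope_correlation <- function(x, y) {
  if (length(x) < 30L) stop("need >= 30 valid samples", call. = FALSE)
  r_dir <- function(a, b_orth) {
    la <- log_power(Mod(a))
    lb <- log_power(abs(b_orth))
    if (sd(la) == 0 || sd(lb) == 0) {
      stop("constant envelope: correlation undefined", call. = FALSE)
    }
    cor(la, lb)
  }
  r1 <- r_dir(x, orthogonalize(x, y))
  r2 <- r_dir(y, orthogonalize(y, x))
  cap <- 1 - 1e-12
  mean(atanh(pmin(pmax(c(r1, r2), -cap), cap)))
}

#' Per-subject, per-carrier adjacency container
#'
#' @param weights numeric array `subject x carrier x N x N`; symmetric in
#'   the last two axes, zero diagonal, non-negative.
#' @param carriers_hz carrier frequencies (length = dim 2).
#' @param labels node labels.
#' @return Object of class `adjacency_stack`.
#' @export
adjacency_stack <- function(weights, carriers_hz, labels = NULL) {
  d <- dim(weights)
  stopifnot(length(d) == 4L, d[3] == d[4])
  if (is.null(labels)) labels <- paste0("node", seq_len(d[3]))
  structure(list(weights = weights, carriers_hz = carriers_hz,
                 labels = labels, n_subjects = d[1], n_nodes = d[3]),
            class = "adjacency_stack")
}

#' @export
print.adjacency_stack <- function(x, ...) {
  cat(sprintf("<adjacency_stack> %d subjects x %d carriers x %d nodes\n",
              x$n_subjects, length(x$carriers_hz), x$n_nodes))
  invisible(x)
}

#' Build one subject's functional-connectivity matrices
#'
#' Fills all `N(N-1)/2` node pairs at every carrier with the orthogonalized
#' envelope-correlation Fisher-z weight computed over the carrier's valid
#' (edge-effect-free) samples. Negative z values are rectified to 0 by
#' default so the downstream weighted-graph machinery (Onnela clustering,
#' inverse-weight path lengths) sees non-negative weights.
#'
#' @param spectra an [analytic_spectra()] for one subject.
#' @param rectify_negative clip negative Fisher-z weights to zero
#'   (default TRUE).
#' @param min_samples minimum valid-sample overlap per carrier.
#' @return numeric array `carrier x N x N` (one subject's slice).
#' @export
build_adjacency <- function(spectra, rectify_negative = TRUE,
                            min_samples = 30L) {
  stopifnot(inherits(spectra, "analytic_spectra"))
  d <- dim(spectra$coefficients)
  n_nodes <- d[1]; n_car <- d[2]
  if (n_nodes < 2L) stop("need >= 2 nodes", call. = FALSE)
  A <- array(0, dim = c(n_car, n_nodes, n_nodes))
  for (ci in seq_len(n_car)) {
    keep <- spectra$valid_mask[ci, ]
    if (sum(keep) < min_samples) {
      stop(sprintf("carrier %d: only %d valid samples (< %d)",
                   ci, sum(keep), min_samples), call. = FALSE)
    }
    co <- spectra$coefficients[, ci, keep, drop = FALSE]
    for (i in seq_len(n_nodes - 1L)) {
      xi <- co[i, 1, ]
      for (j in (i + 1L):n_nodes) {
        z <- tryCatch(envelope_correlation(xi, co[j, 1, ]),
                      error = function(e) {
                        stop(sprintf("pair (%d, %d), carrier %d: %s",
                                     i, j, ci, conditionMessage(e)),
                             call. = FALSE)
                      })
        if (rectify_negative) z <- max(z, 0)
        A[ci, i, j] <- A[ci, j, i] <- z
      }
    }
  }
  A
}

#' Build the full multi-subject adjacency stack
#'
#' Runs [wavelet_transform()] and [build_adjacency()] per subject.
#'
#' @param ts a [roi_timeseries_set()].
#' @param grid [carrier_frequencies()] grid.
#' @param params [morse_params()].
#' @param rectify_negative see [build_adjacency()].
#' @return An [adjacency_stack()].
#' @export
build_adjacency_stack <- function(ts, grid, params = morse_params(),
                                  rectify_negative = TRUE) {
  stopifnot(inherits(ts, "roi_timeseries_set"))
  n_sub <- length(ts$data)
  n_nodes <- nrow(ts$data[[1]])
  n_car <- length(grid$frequencies_hz)
  arr <- array(0, dim = c(n_sub, n_car, n_nodes, n_nodes))
  for (s in seq_len(n_sub)) {
    sp <- wavelet_transform(ts, grid, params, subject = s)
    arr[s, , , ] <- build_adjacency(sp, rectify_negative = rectify_negative)
  }
  adjacency_stack(arr, carriers_hz = grid$frequencies_hz,
                  labels = ts$labels)
}

#' Cross-subject consistency thresholding over a density sweep
#'
#' Per carrier, each edge's coefficient of variation (sample sd / mean of
#' its Fisher-z weight across subjects) is computed; edges are ranked by
#' ascending CV (most consistent first), ties broken by descending mean
#' weight then by lexicographic edge index, and edges whose mean weight is
#' zero (CV undefined) rank last. At density `d` percent the
#' `round(d/100 * N(N-1)/2)` best-ranked edges are kept (round half away
#' from zero). One mask per (carrier, density) applies to every subject, so
#' all subjects' thresholded graphs are equally sparse, and masks are nested
#' across densities by construction.
#'
#' @param stack an [adjacency_stack()] with at least 2 subjects.
#' @param density_grid densities in percent (default 1:100).
#' @return Object of class `density_sweep` with `masks` (logical array
#'   `carrier x density x N x N`), `density_grid`, `cv` (array
#'   `carrier x N x N`), `carriers_hz`.
#' @export
consistency_threshold <- function(stack, density_grid = 1:100) {
  stopifnot(inherits(stack, "adjacency_stack"))
  if (stack$n_subjects < 2L) {
    stop("consistency thresholding needs >= 2 subjects (CV undefined for 1)",
         call. = FALSE)
  }
  if (any(density_grid <= 0 | density_grid > 100)) {
    stop("densities must be in (0, 100]", call. = FALSE)
  }
  n <- stack$n_nodes
  n_car <- length(stack$carriers_hz)
  ut <- which(upper.tri(matrix(0, n, n)))
  n_edges_tot <- length(ut)
  masks <- array(FALSE, dim = c(n_car, length(density_grid), n, n))
  cv_arr <- array(NA_real_, dim = c(n_car, n, n))
  keep_counts <- round_half_up(density_grid / 100 * n_edges_tot)
  for (ci in seq_len(n_car)) {
    Wc <- stack$weights[, ci, , , drop = FALSE]
    flat <- matrix(Wc, nrow = stack$n_subjects)   # subjects x (n*n)
    mu <- colMeans(flat)[ut]
    sdev <- apply(flat[, ut, drop = FALSE], 2, sd)
    cv <- ifelse(mu > 0, sdev / mu, Inf)          # zero-mean edges rank last
    M <- matrix(NA_real_, n, n)
    M[ut] <- cv
    cv_arr[ci, , ] <- pmin(M, t(M), na.rm = TRUE)
    ord <- order(cv, -mu, seq_along(ut))
    for (di in seq_along(density_grid)) {
      kept <- ut[ord[seq_len(keep_counts[di])]]
      m <- matrix(FALSE, n, n)
      m[kept] <- TRUE
      masks[ci, di, , ] <- m | t(m)
    }
  }
  structure(list(masks = masks, density_grid = density_grid, cv = cv_arr,
                 carriers_hz = stack$carriers_hz),
            class = "density_sweep")
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) trunc(x + 0.5 * sign(x))
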