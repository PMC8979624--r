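#' Synthetic recording configuration
#'
#' Describes a stated world for the generator: `n_subjects` recordings of
#' `n_nodes` source-space signals, each the sum of 1/f^`noise_exponent`
#' background noise and a band-limited oscillation centred at
#' `coupling_band_hz` whose slow amplitude envelope is partially shared
#' between nodes joined by a backbone edge. Because each node's oscillation
#' carries an independent random phase, the planted coupling lives in the
#' envelopes, not in zero-lag coherence, and therefore survives pairwise
#' orthogonalization downstream.
#'
#' @param n_subjects subjects (independent seed streams, subject `s` uses
#'   `seed + s`).
#' @param n_nodes nodes (>= 3).
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds (>= 2).
#' @param backbone a [backbone_spec()]; defaults to a Watts-Strogatz small
#'   world with mean degree 4 and rewiring 0.1 on `n_nodes`.
#' @param coupling_band_hz centre frequency of the planted oscillation, Hz.
#' @param band_halfwidth_hz half-bandwidth of the oscillation, Hz.
#' @param envelope_coupling shared-envelope mixing fraction rho in `[0, 1]`:
#'   node envelope = (1 - rho) * private + rho * mean of its edges' latent
#'   envelopes.
#' @param noise_exponent spectral slope of the background (power ~ 1/f^a).
#' @param snr oscillation-to-noise amplitude (RMS) ratio.
#' @param seed integer master seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 12L, n_nodes = 20L, fs = 256,
                         duration = 60,
                         backbone = NULL,
                         coupling_band_hz = 8, band_halfwidth_hz = 2,
                         envelope_coupling = 0.8, noise_exponent = 1,
                         snr = 2, seed = 1L) {
  if (is.null(backbone)) {
    backbone <- backbone_spec("watts_strogatz", n = n_nodes, k = 4L,
                              p_rewire = 0.1, weight_dist = c(1, 1))
  }
  stopifnot(inherits(backbone, "backbone_spec"))
  if (n_nodes < 3L) stop("n_nodes must be >= 3", call. = FALSE)
  if (backbone$n != n_nodes) stop("backbone n must equal n_nodes",
                                  call. = FALSE)
  if (duration * fs < 2 * fs) stop("duration must be >= 2 s", call. = FALSE)
  if (envelope_coupling < 0 || envelope_coupling > 1) {
    stop("envelope_coupling must be in [0,1]", call. = FALSE)
  }
  if (coupling_band_hz - band_halfwidth_hz <= 0 ||
      coupling_band_hz + band_halfwidth_hz >= fs / 2) {
    stop("coupling band [", coupling_band_hz - band_halfwidth_hz, ", ",
         coupling_band_hz + band_halfwidth_hz,
         "] Hz must lie inside (0, fs/2)", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes), fs = fs,
                 duration = duration, backbone = backbone,
                 coupling_band_hz = coupling_band_hz,
                 band_halfwidth_hz = band_halfwidth_hz,
                 envelope_coupling = envelope_coupling,
                 noise_exponent = noise_exponent, snr = snr,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Multi-subject ROI time-series container
#'
#' @param data list of `n_nodes x n_samples` numeric matrices, one per
#'   subject, all with identical dimensions and node labels.
#' @param fs sampling rate, Hz.
#' @param labels node labels (rownames of each matrix).
#' @return Object of class `roi_timeseries_set`.
#' @export
roi_timeseries_set <- function(data, fs, labels = NULL) {
  stopifnot(is.list(data), length(data) >= 1L)
  dims <- vapply(data, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all subjects must share node and sample counts", call. = FALSE)
  }
  if (is.null(labels)) labels <- rownames(data[[1]]) %||%
      paste0("node", seq_len(dims[1, 1]))
  data <- lapply(data, function(m) { rownames(m) <- labels; m })
  if (is.null(names(data))) names(data) <- sprintf("sub%02d",
                                                   seq_along(data))
  structure(list(data = data, fs = fs, labels = labels),
            class = "roi_timeseries_set")
}

#' @export
print.roi_timeseries_set <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("<roi_timeseries_set> %d subjects, %d nodes, %d samples @ %g Hz\n",
              length(x$data), d[1], d[2], x$fs))
  invisible(x)
}

# 1/f^a noise by spectral shaping of white noise; unit variance.
colored_noise <- function(n, fs, exponent) {
  w <- rnorm(n)
  if (exponent == 0) return(w / sd(w))
  fr <- seq(0, n - 1) / n * fs
  f2 <- pmin(fr, fs - fr)           # two-sided |f|, keeps Hermitian symmetry
  shape <- numeric(n)
  nz <- f2 > 0
  shape[nz] <- f2[nz]^(-exponent / 2)
  x <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
  x / sd(x)
}

# Gaussian-kernel low-pass filtered white noise; unit variance. The slow
# process behind every amplitude envelope (cutoff ~1 Hz: slow power
# co-fluctuations as assumed by envelope-correlation connectivity).
lowpass_gp <- function(n, fs, cutoff) {
  w <- rnorm(n)
  fr <- seq(0, n - 1) / n * fs
  f2 <- pmin(fr, fs - fr)
  H <- exp(-0.5 * (f2 / cutoff)^2)
  x <- Re(fft(fft(w) * H, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate multi-subject ROI time series with planted envelope coupling
#'
#' For each subject, every node signal is
#' `snr`-scaled `env_i(t) * cos(2 pi f0 t + phi_i)` plus unit-RMS
#' 1/f^`noise_exponent` noise. Envelopes are rectified low-pass (~1 Hz)
#' Gaussian processes; node `i` mixes a private envelope with the mean of
#' one latent envelope per incident backbone edge, weighted
#' `(1 - rho) : rho`, so adjacent nodes share envelope variance while
#' non-adjacent nodes do not. Oscillation phases `phi_i` are i.i.d. uniform,
#' so zero-lag coherence carries none of the planted structure.
#'
#' @param config a [synth_config()].
#' @return A list with `ts` (a [roi_timeseries_set()]) and `truth` (the
#'   backbone as a [weighted_graph()]).
#' @export
generate_roi_timeseries <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  truth <- generate_toy_graph(config$backbone, seed = config$seed)
  W <- truth$weights
  n <- config$n_nodes
  ns <- round(config$duration * config$fs)
  rho <- config$envelope_coupling
  cutoff <- min(1, config$band_halfwidth_hz)
  el <- which(upper.tri(W) & W > 0, arr.ind = TRUE)   # edge list (i < j)
  n_edges <- nrow(el)
  inc <- lapply(seq_len(n), function(i) {
    which(el[, 1] == i | el[, 2] == i)
  })
  tt <- seq_len(ns) / config$fs
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    subjects[[s]] <- with_local_seed(config$seed + s, {
      g_lat <- if (n_edges > 0) {
        vapply(seq_len(n_edges),
               function(e) abs(lowpass_gp(ns, config$fs, cutoff)),
               numeric(ns))
      } else NULL
      X <- matrix(0, n, ns)
      for (i in seq_len(n)) {
        u <- abs(lowpass_gp(ns, config$fs, cutoff))
        env <- if (length(inc[[i]]) > 0 && rho > 0) {
          shared <- rowMeans(g_lat[, inc[[i]], drop = FALSE])
          (1 - rho) * u + rho * shared
        } else u
        phi <- runif(1, 0, 2 * pi)
        osc <- env * cos(2 * pi * config$coupling_band_hz * tt + phi)
        osc <- osc / sd(osc) * config$snr
        X[i, ] <- osc + colored_noise(ns, config$fs, config$noise_exponent)
      }
      X
    })
  }
  list(ts = roi_timeseries_set(subjects, fs = config$fs), truth = truth)
}
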