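#' Log-spaced carrier-frequency grid
#'
#' Carriers are `2^e` Hz for exponents `e` running from `min_exp` to
#' `max_exp` in steps of `step`. The default grid, quarter-octave steps from
#' 2^0.5 to 2^6 Hz, has exactly 23 carriers spanning ~1.414-64 Hz and covers
#' the conventional EEG bands (delta through gamma) with fine detail.
#'
#' @param min_exp,max_exp,step grid exponents (base-2); `step > 0` and
#'   `(max_exp - min_exp)` must be a whole multiple of `step`.
#' @return An object of class `carrier_grid` with `exponents` and
#'   `frequencies_hz` (strictly increasing).
#' @export
carrier_frequencies <- function(min_exp = 0.5, max_exp = 6, step = 0.25) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (max_exp < min_exp) stop("max_exp must be >= min_exp", call. = FALSE)
  n_steps <- (max_exp - min_exp) / step
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("step must divide the exponent range", call. = FALSE)
  }
  ex <- min_exp + step * 0:round(n_steps)
  structure(list(exponents = ex, frequencies_hz = 2^ex),
            class = "carrier_grid")
}

#' Generalized Morse wavelet parameters
#'
#' The analytic Morse family with frequency-domain window
#' `a * omega^beta * exp(-omega^gamma)` on positive frequencies only.
#' `gamma = 3` gives the symmetric ("Airy") members usually recommended for
#' time-frequency analysis; `beta` sets the decay, and the time-bandwidth
#' product is `P = sqrt(beta * gamma)` (roughly the number of oscillation
#' cycles under the envelope). Defaults: `gamma = 3`, `beta = 25/3`, so
#' `P = 5`.
#'
#' @param gamma shape parameter, > 0.
#' @param beta decay parameter, > 0.
#' @return Object of class `morse_params`.
#' @export
morse_params <- function(gamma = 3, beta = 25 / 3) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0",
                                            call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  structure(list(gamma = gamma, beta = beta,
                 p = sqrt(beta * gamma)), class = "morse_params")
}

# Peak angular frequency of the unscaled Morse window: (beta/gamma)^(1/gamma).
morse_peak_omega <- function(params) (params$beta / params$gamma)^(1 / params$gamma)

# Half-support of the scaled wavelet in samples: P cycles at the carrier.
morse_half_support <- function(params, carrier_hz, fs) {
  ceiling(params$p / carrier_hz * fs)
}

#' Frequency-domain Morse filter
#'
#' Returns the complex (here real-valued, zero-phase) frequency response of
#' a Morse wavelet scaled so its peak sits at `carrier_hz`, sampled on the
#' DFT bins of an `n_samples`-point transform at rate `fs`. The response is
#' exactly zero at DC, at all negative-frequency bins and at/above Nyquist,
#' so convolution yields a strictly analytic output for real input. The
#' peak magnitude is normalized to 1 (bandpass normalization: a unit-
#' amplitude complex exponential at the carrier maps to unit envelope).
#'
#' @param params a [morse_params()].
#' @param carrier_hz carrier frequency, must satisfy `0 < carrier < fs/2`.
#' @param n_samples DFT length.
#' @param fs sampling rate, Hz.
#' @return Numeric vector of length `n_samples` (per-bin response).
#' @export
morse_filter <- function(params, carrier_hz, n_samples, fs) {
  stopifnot(inherits(params, "morse_params"))
  if (carrier_hz <= 0) stop("carrier must be positive", call. = FALSE)
  if (carrier_hz >= fs / 2) {
    stop(sprintf("carrier %.3f Hz is at/above Nyquist (%.3f Hz)",
                 carrier_hz, fs / 2), call. = FALSE)
  }
  fr <- seq(0, n_samples - 1) / n_samples * fs
  H <- numeric(n_samples)
  pos <- fr > 0 & fr < fs / 2
  x <- fr[pos] / carrier_hz    # peak of b*log(x) - (b/g)(x^g - 1) is x = 1
  b <- params$beta; g <- params$gamma
  H[pos] <- exp(b * log(x) - (b / g) * (x^g - 1))
  H
}

#' Analytic spectra container
#'
#' Complex wavelet coefficients for one subject: `node x carrier x time`,
#' with a per-carrier logical mask flagging samples at least one wavelet
#' half-support away from both signal edges.
#'
#' @param coefficients complex array `n_nodes x n_carriers x n_samples`.
#' @param fs sampling rate, Hz.
#' @param grid the [carrier_frequencies()] grid used.
#' @param valid_mask logical `n_carriers x n_samples` matrix.
#' @return Object of class `analytic_spectra`.
#' @export
analytic_spectra <- function(coefficients, fs, grid, valid_mask) {
  stopifnot(length(dim(coefficients)) == 3L,
            dim(coefficients)[2] == length(grid$frequencies_hz),
            all(dim(valid_mask) == dim(coefficients)[2:3]))
  structure(list(coefficients = coefficients, fs = fs, grid = grid,
                 valid_mask = valid_mask), class = "analytic_spectra")
}

#' Analytic wavelet transform of one subject's ROI signals
#'
#' Convolves each node signal with the scaled Morse wavelet at every carrier
#' via frequency-domain multiplication (zero-padded to the next power of
#' two), yielding strictly analytic complex coefficients. Samples within one
#' wavelet half-support of either edge are masked out, not tapered.
#'
#' @param x numeric `n_nodes x n_samples` matrix (one subject), or a
#'   [roi_timeseries_set()] plus `subject` index.
#' @param grid a [carrier_frequencies()] grid; all carriers must lie below
#'   Nyquist.
#' @param params [morse_params()].
#' @param fs sampling rate, Hz (taken from `x` when it is a
#'   `roi_timeseries_set`).
#' @param subject subject index when `x` is a set.
#' @return An [analytic_spectra()].
#' @export
wavelet_transform <- function(x, grid, params = morse_params(), fs = NULL,
                              subject = 1L) {
  if (inherits(x, "roi_timeseries_set")) {
    fs <- x$fs
    x <- x$data[[subject]]
  }
  if (is.null(fs)) stop("fs required for matrix input", call. = FALSE)
  x <- rbind(x)   # promote a single signal vector to a 1 x n matrix
  n_nodes <- nrow(x); ns <- ncol(x)
  freqs <- grid$frequencies_hz
  bad <- freqs >= fs / 2
  if (any(bad)) {
    stop(sprintf("carrier(s) %s Hz at/above Nyquist (%g Hz)",
                 paste(signif(freqs[bad], 4), collapse = ", "), fs / 2),
         call. = FALSE)
  }
  hs <- vapply(freqs, function(f) morse_half_support(params, f, fs),
               numeric(1))
  too_short <- ns < 4 * 2 * hs
  if (any(too_short)) {
    f0 <- freqs[which(too_short)[1]]
    stop(sprintf(paste0("signal too short (%d samples) for carrier %.4g Hz: ",
                        "need >= 4 wavelet supports (%d samples)"),
                 ns, f0, as.integer(4 * 2 * hs[which(too_short)[1]])),
         call. = FALSE)
  }
  nfft <- 2^ceiling(log2(ns + 2 * max(hs)))
  Xf <- t(apply(cbind(x, matrix(0, n_nodes, nfft - ns)), 1, fft))
  if (n_nodes == 1L) Xf <- matrix(Xf, nrow = 1L)
  coef <- array(complex(real = 0), dim = c(n_nodes, length(freqs), ns))
  vm <- matrix(FALSE, length(freqs), ns)
  for (ci in seq_along(freqs)) {
    H <- morse_filter(params, freqs[ci], nfft, fs)
    Wf <- Xf * matrix(H, n_nodes, nfft, byrow = TRUE)
    for (i in seq_len(n_nodes)) {
      w <- fft(Wf[i, ], inverse = TRUE) / nfft
      coef[i, ci, ] <- w[seq_len(ns)]
    }
    keep <- seq_len(ns) > hs[ci] & seq_len(ns) <= ns - hs[ci]
    vm[ci, ] <- keep
  }
  analytic_spectra(coef, fs = fs, grid = grid, valid_mask = vm)
}
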