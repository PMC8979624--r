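#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Classical within-subject decomposition for an `n x k` matrix (subjects by
#' levels): `F = MS_level / MS_error` on `(k - 1, (n - 1)(k - 1))` degrees
#' of freedom, Mauchly's sphericity test on the orthonormal-contrast
#' covariance, and the Greenhouse-Geisser epsilon with the corresponding
#' corrected p-value. Missing cells are an error (no imputation).
#'
#' @param values numeric matrix, `n >= 3` subjects by `k >= 2` levels.
#' @return list of class `rm_anova_result`: `f_stat`, `df_num`, `df_den`,
#'   `ms_error`, `gg_epsilon`, `mauchly_w`, `mauchly_p`, `p_uncorrected`,
#'   `p_gg`, `level_means`, `n`, `k`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (n < 3L) stop("need >= 3 subjects", call. = FALSE)
  if (k < 2L) stop("need >= 2 levels", call. = FALSE)
  gm <- mean(values)
  lm_ <- colMeans(values); sm <- rowMeans(values)
  ss_level <- n * sum((lm_ - gm)^2)
  ss_subject <- k * sum((sm - gm)^2)
  ss_total <- sum((values - gm)^2)
  ss_error <- ss_total - ss_level - ss_subject
  df_num <- k - 1L
  df_den <- (n - 1L) * (k - 1L)
  ms_error <- ss_error / df_den
  f_stat <- if (ss_level == 0) 0 else (ss_level / df_num) / ms_error

  # orthonormal contrasts of the level covariance
  C <- qr.Q(qr(stats::contr.helmert(k)))
  Sc <- crossprod(C, stats::cov(values)) %*% C
  p <- k - 1L
  tr <- sum(diag(Sc))
  gg <- if (tr > 0) tr^2 / (p * sum(Sc * t(Sc))) else 1
  gg <- min(max(gg, 1 / p), 1)
  detSc <- det(Sc)
  if (n - 1L > p && detSc > 0 && tr > 0) {
    w <- detSc / (tr / p)^p
    chi <- -((n - 1) - (2 * p^2 + p + 2) / (6 * p)) * log(w)
    df_m <- p * (p + 1) / 2 - 1
    mauchly_w <- w
    mauchly_p <- pchisq(chi, df_m, lower.tail = FALSE)
  } else {
    mauchly_w <- NA_real_
    mauchly_p <- NA_real_
  }
  p_unc <- pf(f_stat, df_num, df_den, lower.tail = FALSE)
  p_gg <- pf(f_stat, gg * df_num, gg * df_den, lower.tail = FALSE)
  structure(list(f_stat = f_stat, df_num = df_num, df_den = df_den,
                 ms_error = ms_error, gg_epsilon = gg,
                 mauchly_w = mauchly_w, mauchly_p = mauchly_p,
                 p_uncorrected = p_unc, p_gg = p_gg,
                 level_means = lm_, n = n, k = k),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("F(%d,%d) = %.3f, p = %.4g (GG eps = %.3f, p_GG = %.4g)\n",
              x$df_num, x$df_den, x$f_stat, x$p_uncorrected,
              x$gg_epsilon, x$p_gg))
  invisible(x)
}

#' Tukey HSD over within-subject levels
#'
#' Pairwise studentized-range tests among the level means, using the
#' repeated-measures error mean square and its `(n - 1)(k - 1)` degrees of
#' freedom: `q_ij = |m_i - m_j| / sqrt(MS_error / n)`.
#'
#' @inheritParams rm_anova
#' @return symmetric `k x k` matrix of Tukey p-values, unit diagonal.
#' @export
tukey_hsd_within <- function(values) {
  a <- rm_anova(values)
  k <- a$k
  se <- sqrt(a$ms_error / a$n)
  P <- matrix(1, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (se == 0) {
        p <- if (a$level_means[i] == a$level_means[j]) 1 else 0
      } else {
        q <- abs(a$level_means[i] - a$level_means[j]) / se
        p <- ptukey(q, nmeans = k, df = a$df_den, lower.tail = FALSE)
      }
      P[i, j] <- P[j, i] <- p
    }
  }
  P
}

#' Bonferroni per-comparison threshold
#'
#' @param alpha family-wise level.
#' @param m number of comparisons (>= 1).
#' @return list with `exact` (`alpha / m`) and `display` (rounded to 4
#'   decimals, as conventionally reported).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  thr <- alpha / m
  list(exact = thr, display = round(thr, 4))
}

# normalized trapezoidal quadrature weights over an increasing grid
trapezoid_weights <- function(grid) {
  g <- as.numeric(grid)
  n <- length(g)
  if (n == 1L) return(1)
  d <- diff(g)
  w <- c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
  w / sum(w)
}

#' Functional permutation test over metric-versus-density curves
#'
#' Treats each subject's curve as one functional observation. The observed
#' statistic is the grid-weighted integral (normalized trapezoid weights)
#' of the squared pointwise t statistic — paired t on per-subject
#' differences, or two-sample pooled t — optionally the maximum instead of
#' the integral. The null is built by permutation: per-subject sign flips
#' of the differences (paired) or group-label shuffles (unpaired). The
#' p-value includes the identity permutation, so it is never 0. Grid points
#' with zero variance are dropped with a notice; if nothing remains the
#' observed statistic is 0 and p = 1.
#'
#' @param curves_a,curves_b numeric `subject x grid` matrices; equal row
#'   counts when `paired`.
#' @param grid the density (or abscissa) grid; defaults to equally spaced.
#' @param n_perm number of permutations (warning below 100).
#' @param seed RNG seed.
#' @param paired per-subject pairing flag.
#' @param stat `"integrated_t"` (default) or `"max_t"`.
#' @return list of class `fda_result`: `observed_stat`, `null_stats`,
#'   `p_value`, `n_perm`, `seed`, `dropped_points`.
#' @export
fda_curve_test <- function(curves_a, curves_b, grid = NULL, n_perm = 10000L,
                           seed = 1L, paired = FALSE,
                           stat = c("integrated_t", "max_t")) {
  stat <- match.arg(stat)
  A <- as.matrix(curves_a); B <- as.matrix(curves_b)
  if (ncol(A) != ncol(B)) stop("curves must share the grid", call. = FALSE)
  if (paired && nrow(A) != nrow(B)) {
    stop("paired test needs equal subject sets", call. = FALSE)
  }
  if (is.null(grid)) grid <- seq_len(ncol(A))
  if (length(grid) != ncol(A)) stop("grid length mismatch", call. = FALSE)
  if (n_perm < 100L) warning("n_perm < 100: p-value resolution is coarse",
                             call. = FALSE)
  w <- trapezoid_weights(grid)
  combine <- function(t2mat) {      # permutations x grid -> statistic
    if (stat == "integrated_t") drop(t2mat %*% w) else apply(t2mat, 1, max)
  }
  dropped <- integer(0)
  if (paired) {
    D <- A - B
    n <- nrow(D)
    v <- apply(D, 2, var)
    dropped <- which(v == 0)
    if (length(dropped) > 0) {
      message(sprintf("fda_curve_test: dropping %d zero-variance grid point(s)",
                      length(dropped)))
      D <- D[, -dropped, drop = FALSE]
      w <- trapezoid_weights(grid[-dropped])
    }
    if (ncol(D) == 0) {
      return(structure(list(observed_stat = 0,
                            null_stats = rep(0, n_perm), p_value = 1,
                            n_perm = n_perm, seed = seed,
                            dropped_points = dropped),
                       class = "fda_result"))
    }
    ss <- colSums(D^2)
    t2_from_means <- function(M) {   # rows = permutations, cols = grid
      vr <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
      t2 <- M^2 / (vr / n)
      t2[vr <= 0] <- 0
      t2
    }
    obs <- combine(t2_from_means(matrix(colMeans(D), 1)))
    null_stats <- with_local_seed(seed, {
      S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      combine(t2_from_means(S %*% D / n))
    })
  } else {
    n1 <- nrow(A); n2 <- nrow(B)
    X <- rbind(A, B)
    vw <- apply(A, 2, var) + apply(B, 2, var)
    dropped <- which(vw == 0)
    if (length(dropped) > 0) {
      message(sprintf("fda_curve_test: dropping %d zero-variance grid point(s)",
                      length(dropped)))
      X <- X[, -dropped, drop = FALSE]
      w <- trapezoid_weights(grid[-dropped])
    }
    if (ncol(X) == 0) {
      return(structure(list(observed_stat = 0,
                            null_stats = rep(0, n_perm), p_value = 1,
                            n_perm = n_perm, seed = seed,
                            dropped_points = dropped),
                       class = "fda_result"))
    }
    t2_groups <- function(idx1) {
      Xa <- X[idx1, , drop = FALSE]
      Xb <- X[-idx1, , drop = FALSE]
      va <- apply(Xa, 2, var); vb <- apply(Xb, 2, var)
      sp <- ((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2)
      den <- sp * (1 / n1 + 1 / n2)
      t2 <- (colMeans(Xa) - colMeans(Xb))^2 / den
      t2[den <= 0] <- 0
      matrix(t2, 1)
    }
    obs <- combine(t2_groups(seq_len(n1)))
    null_stats <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        combine(t2_groups(sample(n1 + n2, n1)))
      }, numeric(1))
    })
  }
  p <- (1 + sum(null_stats >= obs - 1e-12)) / (1 + n_perm)
  structure(list(observed_stat = obs, null_stats = null_stats, p_value = p,
                 n_perm = n_perm, seed = seed, dropped_points = dropped),
            class = "fda_result")
}

#' @export
print.fda_result <- function(x, ...) {
  cat(sprintf("<fda_result> stat = %.4g, p = %.4g (%d permutations)\n",
              x$observed_stat, x$p_value, x$n_perm))
  invisible(x)
}

#' Paired t-tests per density level with a Bonferroni mask
#'
#' One paired t-test per density column between the two condition curves;
#' densities are declared significant where `p < alpha / m`.
#'
#' @param pre_curves,post_curves numeric `subject x density` matrices with
#'   identical dimensions (paired subjects), `n >= 3`.
#' @param alpha family-wise level.
#' @param m number of comparisons used in the Bonferroni threshold.
#' @param density_grid optional density labels for the output.
#' @return list: `t_stat`, `p_value`, `significant` (logical vector),
#'   `threshold` (exact), `density_grid`.
#' @export
prepost_density_ttests <- function(pre_curves, post_curves, alpha = 0.05,
                                   m = 1, density_grid = NULL) {
  P <- as.matrix(pre_curves); Q <- as.matrix(post_curves)
  if (!all(dim(P) == dim(Q))) stop("curves must be paired with equal dims",
                                   call. = FALSE)
  n <- nrow(P)
  if (n < 3L) stop("need >= 3 subject pairs", call. = FALSE)
  if (is.null(density_grid)) density_grid <- seq_len(ncol(P))
  D <- Q - P
  mns <- colMeans(D)
  sds <- apply(D, 2, sd)
  t_stat <- ifelse(sds > 0, mns / (sds / sqrt(n)),
                   ifelse(mns == 0, 0, Inf * sign(mns)))
  p <- 2 * pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  thr <- bonferroni_threshold(alpha, m)$exact
  list(t_stat = t_stat, p_value = p, significant = p < thr,
       threshold = thr, density_grid = density_grid)
}
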