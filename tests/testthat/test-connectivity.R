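make_analytic_noise <- function(n, seed = 1) {
  set.seed(seed)
  complex(real = rnorm(n), imaginary = rnorm(n))
}

test_that("orthogonalization removes the coherent component exactly", {
  x <- make_analytic_noise(500, 1)
  # real multiples of x vanish; the quadrature copy is fully retained
  expect_equal(orthogonalize(x, 3.7 * x), rep(0, 500), tolerance = 1e-12)
  expect_equal(abs(orthogonalize(x, 1i * x)), Mod(x), tolerance = 1e-12)
  # element-wise scalar-loop oracle on a random pair
  y <- make_analytic_noise(500, 2)
  ref <- vapply(seq_along(x), function(t) {
    Im(y[t] * Conj(x[t]) / Mod(x[t]))
  }, numeric(1))
  expect_equal(orthogonalize(x, y), ref, tolerance = 1e-12)
  expect_error(orthogonalize(complex(real = rep(0, 10)), x[1:10]),
               "all-zero")
  expect_error(orthogonalize(x, y[1:10]), "equal length")
})

test_that("envelope correlation: null level, degeneracy cap, symmetry", {
  n <- 1e4
  x <- make_analytic_noise(n, 3)
  y <- make_analytic_noise(n, 4)
  z <- envelope_correlation(x, y)
  expect_lt(abs(z), 3 / sqrt(n) + 0.02)      # null case ~ 0
  expect_equal(z, envelope_correlation(y, x), tolerance = 1e-12)
  # pure quadrature copy: identical log-envelopes, r capped before atanh
  zq <- envelope_correlation(x, 1i * x)
  expect_true(is.finite(zq) && zq > 5)
  expect_error(envelope_correlation(x[1:10], y[1:10]), ">= 30")
  expect_error(envelope_correlation(rep(1 + 0i, 100),
                                    make_analytic_noise(100)),
               "constant envelope")
})

test_that("envelope correlation tracks the generator's planted coupling", {
  # shared-envelope pair built exactly like the generator's mechanism
  set.seed(8)
  n <- 6000; fs <- 100; rho <- 0.8
  lp <- function() {
    w <- rnorm(n)
    fr <- seq(0, n - 1) / n * fs
    f2 <- pmin(fr, fs - fr)
    v <- Re(fft(fft(w) * exp(-0.5 * (f2 / 1)^2), inverse = TRUE)) / n
    abs(v / sd(v))
  }
  zs <- replicate(20, {
    shared <- lp()
    e1 <- (1 - rho) * lp() + rho * shared
    e2 <- (1 - rho) * lp() + rho * shared
    ph <- runif(2, 0, 2 * pi)
    x <- e1 * exp(1i * (2 * pi * 8 * seq_len(n) / fs + ph[1]))
    y <- e2 * exp(1i * (2 * pi * 8 * seq_len(n) / fs + ph[2]))
    envelope_correlation(x, y)
  })
  # Monte-Carlo CI of the generator's own empirical coupling level
  expect_gt(mean(zs) - 3 * sd(zs) / sqrt(length(zs)), 0.3)
})

test_that("adjacency builder fills all pairs symmetrically", {
  set.seed(5)
  fs <- 64
  x <- matrix(rnorm(4 * 2048), 4, 2048)
  grid <- carrier_frequencies(2, 3, 1)
  sp <- wavelet_transform(x, grid, fs = fs)
  A <- build_adjacency(sp)
  expect_equal(dim(A), c(2, 4, 4))
  for (ci in 1:2) {
    expect_equal(A[ci, , ], t(A[ci, , ]))
    expect_equal(unname(diag(A[ci, , ])), rep(0, 4))
    expect_true(all(A[ci, , ] >= 0))
  }
  # relabeling: permuting nodes permutes rows and columns consistently
  perm <- c(3, 1, 4, 2)
  sp_p <- wavelet_transform(x[perm, ], grid, fs = fs)
  A_p <- build_adjacency(sp_p)
  expect_equal(A_p[1, , ], A[1, perm, perm], tolerance = 1e-10)
  # two nodes: a single off-diagonal value
  sp2 <- wavelet_transform(x[1:2, ], grid, fs = fs)
  A2 <- build_adjacency(sp2, rectify_negative = FALSE)
  expect_equal(A2[1, 1, 2], A2[1, 2, 1])
  # constant-envelope failure is reported with the offending pair
  xx <- x; xx[2, ] <- 0
  spz <- wavelet_transform(xx, grid, fs = fs)
  expect_error(build_adjacency(spz), "pair \\(1, 2\\)")
})

test_that("consistency thresholding keeps lowest-CV edges with exact counts", {
  # 3-subject, 4-node fixture with hand-set weights: 6 edges whose CVs are
  # engineered so the 3 lowest are (1,2), (1,3), (3,4)
  base <- c("12" = 1.0, "13" = 0.8, "14" = 0.5, "23" = 0.4, "24" = 0.3,
            "34" = 0.9)
  noise <- rbind(c(0.01, 0.02, 0.30, 0.25, 0.20, 0.01),
                 c(-0.01, -0.02, -0.28, 0.22, -0.19, 0.02),
                 c(0.02, 0.01, 0.25, -0.30, 0.21, -0.01))
  arr <- array(0, dim = c(3, 1, 4, 4))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (s in 1:3) {
    W <- matrix(0, 4, 4)
    W[pairs] <- base + noise[s, ]
    arr[s, 1, , ] <- W + t(W)
  }
  st <- adjacency_stack(arr, carriers_hz = 8)
  sw <- consistency_threshold(st, density_grid = c(50, 100))
  # independent brute-force CV ranking
  cv <- vapply(seq_len(6), function(e) {
    w <- base[e] + noise[, e]
    sd(w) / mean(w)
  }, numeric(1))
  expected_kept <- pairs[order(cv)[1:3], , drop = FALSE]
  kept <- which(sw$masks[1, 1, , ] & upper.tri(diag(4)), arr.ind = TRUE)
  expect_equal(kept[order(kept[, 1], kept[, 2]), ],
               expected_kept[order(expected_kept[, 1], expected_kept[, 2]), ],
               ignore_attr = TRUE)
  expect_true(all(sw$masks[1, 2, , ][upper.tri(diag(4))]))   # 100%: all kept
})

test_that("identical subjects tie-break by descending mean then edge index", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.9
  W[3, 4] <- W[4, 3] <- 0.9     # tied weight with (1,2): index breaks tie
  W[1, 3] <- W[3, 1] <- 0.5
  arr <- array(0, dim = c(2, 1, 4, 4))
  arr[1, 1, , ] <- W; arr[2, 1, , ] <- W
  st <- adjacency_stack(arr, carriers_hz = 8)
  # all CVs are 0: ranking falls to descending mean weight, and among the
  # two tied 0.9 edges the lexicographically first, (1,2), wins at 1 edge
  sw <- consistency_threshold(st, density_grid = c(17, 33))
  ut_idx <- which(upper.tri(diag(4)))
  kept1 <- which(sw$masks[1, 1, , ] & upper.tri(diag(4)))
  expect_equal(kept1, ut_idx[1])                       # (1,2) alone
  kept2 <- which(sw$masks[1, 2, , ] & upper.tri(diag(4)))
  expect_equal(sort(kept2), sort(ut_idx[c(1, 6)]))     # both 0.9 edges
})

test_that("density masks are nested with exact edge counts", {
  set.seed(14)
  truth <- generate_toy_graph(backbone_spec("erdos_renyi", 9, 4), seed = 2)
  # add noise everywhere (not only edges) so CVs are generic
  arr <- array(0, dim = c(5, 2, 9, 9))
  for (s in 1:5) for (ci in 1:2) {
    N <- matrix(0, 9, 9)
    N[upper.tri(N)] <- abs(rnorm(36, mean = 0.5, sd = 0.2))
    arr[s, ci, , ] <- N + t(N)
  }
  st <- adjacency_stack(arr, carriers_hz = c(4, 8))
  grid <- c(1, 10, 25, 50, 75, 100)
  sw <- consistency_threshold(st, density_grid = grid)
  n_e <- 9 * 8 / 2
  for (ci in 1:2) {
    prev <- NULL
    for (di in seq_along(grid)) {
      m <- sw$masks[ci, di, , ]
      expect_equal(sum(m[upper.tri(m)]), round(grid[di] / 100 * n_e))
      expect_identical(m, t(m))
      expect_false(any(diag(m)))
      if (!is.null(prev)) expect_true(all(m[prev]))   # nestedness
      prev <- m
    }
  }
})
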