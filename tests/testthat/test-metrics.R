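test_that("node strength and average connectivity match brute force", {
  W2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  expect_equal(node_strength(W2), c(0.7, 0.7))
  expect_equal(average_connectivity(W2), 0.7)
  expect_equal(node_strength(matrix(0, 3, 3)), rep(0, 3))
  W <- random_weight_matrix(6, 0.6, seed = 1)
  expect_equal(node_strength(W),
               vapply(1:6, function(i) sum(W[, i]) / 5, numeric(1)),
               tolerance = 1e-12)
  expect_equal(average_connectivity(W), sum(W) / (6 * 5), tolerance = 1e-12)
  # complete graph with uniform weight w has strength w everywhere
  Wc <- matrix(0.3, 4, 4); diag(Wc) <- 0
  expect_equal(average_connectivity(Wc), 0.3)
  expect_equal(node_strength(W, mode = "sum"), colSums(W))
  expect_error(node_strength(matrix(0, 1, 1)), ">= 2")
})

test_that("onnela clustering: hand values, trees, rescale invariance", {
  Wt <- matrix(0, 3, 3)
  Wt[1, 2] <- Wt[2, 1] <- 0.2
  Wt[1, 3] <- Wt[3, 1] <- 0.4
  Wt[2, 3] <- Wt[3, 2] <- 0.8
  expect_equal(weighted_clustering_onnela(Wt)$per_node, rep(0.5, 3),
               tolerance = 1e-12)                      # (0.25*0.5*1)^(1/3)
  We <- matrix(0, 3, 3); We[1, 2] <- We[2, 1] <- 1
  We[1, 3] <- We[3, 1] <- 1; We[2, 3] <- We[3, 2] <- 1
  expect_equal(weighted_clustering_onnela(We)$per_node, rep(1, 3))
  # path graph (a tree): no triangles
  Wp <- matrix(0, 4, 4)
  Wp[cbind(1:3, 2:4)] <- c(0.5, 0.8, 0.2); Wp <- Wp + t(Wp)
  expect_equal(weighted_clustering_onnela(Wp)$mean, 0)
  W <- random_weight_matrix(8, 0.5, seed = 3)
  expect_equal(weighted_clustering_onnela(W)$per_node,
               weighted_clustering_onnela(10 * W)$per_node,
               tolerance = 1e-12)
  expect_equal(weighted_clustering_onnela(matrix(0, 5, 5))$mean, 0)
})

test_that("weighted path length: hand cases and Floyd-Warshall oracle", {
  Wp <- matrix(0, 3, 3)
  Wp[1, 2] <- Wp[2, 1] <- 1; Wp[2, 3] <- Wp[3, 2] <- 1
  expect_equal(weighted_path_length(Wp)$l, 4 / 3)      # {1, 1, 2}
  Wc <- matrix(2, 4, 4); diag(Wc) <- 0
  expect_equal(weighted_path_length(Wc)$l, 0.5)
  W <- random_weight_matrix(8, 0.4, seed = 6)
  res <- weighted_path_length(W)
  D <- oracle_floyd_warshall(W)
  expect_equal(res$distances, D, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(res$l, oracle_path_length(W), tolerance = 1e-10)
  # disconnected graph: unreachable fraction reported
  Wd <- matrix(0, 4, 4); Wd[1, 2] <- Wd[2, 1] <- 1; Wd[3, 4] <- Wd[4, 3] <- 1
  expect_equal(weighted_path_length(Wd)$unreachable_frac, 8 / 12)
  expect_error(weighted_path_length(matrix(0, 3, 3)), "no edges")
})

test_that("lattice equivalent conserves weights and concentrates clustering", {
  W <- random_weight_matrix(12, 0.35, seed = 9)
  L <- lattice_equivalent(W)
  expect_equal(sort(L$weights[upper.tri(L$weights)]),
               sort(W[upper.tri(W)]))                  # multiset conserved
  expect_equal(sum(L$weights[upper.tri(L$weights)] > 0),
               sum(W[upper.tri(W)] > 0))
  # a weight-sorted ring lattice is (up to tie order) its own lattice null
  rl <- generate_toy_graph(backbone_spec("ring_lattice", 10, 4,
                                         weight_dist = c(1, 1)), seed = 2)
  L2 <- lattice_equivalent(rl)
  expect_equal(weighted_clustering_onnela(L2)$mean,
               weighted_clustering_onnela(rl)$mean, tolerance = 1e-12)
  # Monte-Carlo property of the null: lattice clustering >= observed
  hits <- 0
  for (i in 1:100) {
    Wi <- random_weight_matrix(12, 24 / 66, seed = 100 + i)
    if (all(Wi == 0)) next
    latt <- lattice_equivalent(Wi)
    hits <- hits + (weighted_clustering_onnela(latt)$mean >=
                      weighted_clustering_onnela(Wi)$mean)
  }
  expect_gte(hits, 95)
})

test_that("random equivalent conserves weights and matches permutation oracle", {
  W <- random_weight_matrix(6, 1, seed = 12)     # complete graph
  r1 <- random_equivalent(W, seed = 5, n_reps = 3, return_graphs = TRUE)
  for (g in r1$graphs) {
    # complete input: topology unchanged, only the weights shuffle
    expect_equal(g > 0, W > 0)
    expect_equal(sort(g[upper.tri(g)]), sort(W[upper.tri(W)]))
  }
  expect_identical(random_equivalent(W, seed = 5, n_reps = 1)$l_rand,
                   random_equivalent(W, seed = 5, n_reps = 1)$l_rand)
  # permutation oracle on the complete graph: L_rand distribution equals
  # direct weight permutation (same machinery exercised independently)
  set.seed(31)
  direct <- replicate(200, {
    P <- matrix(0, 6, 6)
    P[upper.tri(P)] <- sample(W[upper.tri(W)])
    oracle_path_length(P + t(P))
  })
  pkg <- random_equivalent(W, seed = 77, n_reps = 200)$l_rand
  expect_lt(abs(pkg - mean(direct)), 3 * sd(direct) / sqrt(200) + 0.02)
  # weight multiset conserved on sparse input too
  Ws <- random_weight_matrix(8, 0.3, seed = 13)
  rs <- random_equivalent(Ws, seed = 1, n_reps = 2, return_graphs = TRUE)
  for (g in rs$graphs) {
    expect_equal(sort(g[g > 0]), sort(Ws[Ws > 0]))
  }
})

test_that("swp deltas and formula anchors", {
  expect_equal(swp_from_deltas(0, 0), 1)
  expect_equal(swp_from_deltas(1, 1), 0)
  expect_equal(swp_from_deltas(0, 1), 1 - sqrt(0.5))
  d <- swp_deltas(c_obs = 0.5, c_latt = 0.5, c_rand = 0.1,
                  l_obs = 2, l_latt = 6, l_rand = 2)
  expect_equal(d$delta_c, 0); expect_equal(d$delta_l, 0)
  d2 <- swp_deltas(c_obs = 0.1, c_latt = 0.5, c_rand = 0.1,
                   l_obs = 6, l_latt = 6, l_rand = 2)
  expect_equal(d2$delta_c, 1); expect_equal(d2$delta_l, 1)
  expect_warning(swp_deltas(0.3, 0.2, 0.2, 2, 3, 1), "coincide")
})

test_that("sigma approaches 1 on its own null family", {
  # an Erdos-Renyi graph is (in distribution) one draw of the random
  # equivalent, so sigma should concentrate near 1
  sig <- vapply(1:8, function(i) {
    g <- generate_toy_graph(backbone_spec("erdos_renyi", 40, 8), seed = i)
    sigma_small_worldness(g, seed = i, n_reps = 20)$sigma
  }, numeric(1))
  expect_lt(abs(mean(sig) - 1), 0.2)
})

test_that("sigma decays with density faster than SWP varies (WS family)", {
  v <- function(k) {
    s <- vapply(1:5, function(i) {
      g <- generate_toy_graph(backbone_spec("watts_strogatz", 60, k, 0.1),
                              seed = i)
      c(small_world_propensity(g, seed = i)$swp,
        sigma_small_worldness(g, seed = i)$sigma)
    }, numeric(2))
    rowMeans(s)
  }
  lo <- v(6); hi <- v(24)     # ~10% vs ~40% density
  rel_sigma <- abs(lo[2] - hi[2]) / lo[2]
  rel_swp <- abs(lo[1] - hi[1]) / lo[1]
  expect_gt(rel_sigma, rel_swp)
})

test_that("metric density curves: shapes, flags, subject permutation", {
  truth <- generate_toy_graph(backbone_spec("watts_strogatz", 12, 4, 0.1,
                                            weight_dist = c(0.5, 1)),
                              seed = 3)
  st <- generate_multisubject_adjacency(truth, n_subjects = 4,
                                        noise_sd = 0.05, seed = 4)
  sw <- consistency_threshold(st, density_grid = c(20, 60, 100))
  cur <- metric_density_curves(sw, st, seed = 9, n_reps = 3)
  expect_equal(dim(cur$swp), c(4, 1, 3))
  expect_true(all(is.finite(cur$swp[!cur$edgeless])))
  expect_true(all(cur$swp >= 0 & cur$swp <= 1, na.rm = TRUE))
  # permuting the subject axis permutes curve rows only
  perm <- c(3, 1, 4, 2)
  st_p <- adjacency_stack(st$weights[perm, , , , drop = FALSE],
                          carriers_hz = st$carriers_hz)
  cur_p <- metric_density_curves(sw, st_p, seed = 9, n_reps = 3)
  expect_equal(cur_p$swp, cur$swp[perm, , , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(cur_p$sigma, cur$sigma[perm, , , drop = FALSE],
               ignore_attr = TRUE)
  # full-density masks keep every edge: curves finite everywhere
  expect_true(all(is.finite(cur$swp[, , 3])))
})
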