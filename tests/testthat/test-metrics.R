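test_that("proportional thresholding keeps the top-k edges with stable ties", {
  W <- rand_graph(76, seed = 1, p = 0.5)
  Wt <- threshold_by_sparsity(W, 0.05)
  # k = round(0.05 * 76 * 75 / 2) = round(142.5) = 142 under round-half-even
  expect_equal(sum(Wt[upper.tri(Wt)] > 0), 142L)
  expect_identical(Wt, t(Wt))
  # kept edges are exactly the 142 strongest
  w <- sort(W[upper.tri(W)], decreasing = TRUE)
  expect_true(all(Wt[Wt > 0] >= w[142]))
  # nestedness over the grid
  e05 <- which(threshold_by_sparsity(W, 0.05) > 0)
  e13 <- which(threshold_by_sparsity(W, 0.13) > 0)
  expect_true(all(e05 %in% e13))
  # sparser request than current density: unchanged, with a warning
  Ws <- threshold_by_sparsity(W, 0.05)
  expect_warning(Wu <- threshold_by_sparsity(Ws, 0.12), "keeping all")
  expect_identical(Wu, Ws)
  # tie handling is deterministic
  Wtie <- matrix(0.5, 4, 4); diag(Wtie) <- 0
  expect_identical(threshold_by_sparsity(Wtie, 0.5),
                   threshold_by_sparsity(Wtie, 0.5))
})

test_that("simple graphs give closed-form metric values", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(node_strength(tri)), rep(2, 3))
  expect_equal(unname(node_strength(tri * 0.5)), rep(1, 3))
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  # 3-node path: center carries the single s-t shortest path
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(unname(node_betweenness(path)), c(0, 100, 0))
  # star center has no closed triangles
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(unname(clustering_coefficient(star))[1], 0)
  # complete unit-weight graph is maximally efficient
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(global_efficiency(K5), 1)
  expect_equal(global_efficiency(matrix(0, 2, 2)), 0)
  expect_equal(network_density(matrix(0, 4, 4)), 0)
  expect_equal(network_density(K5), 1)
  W76 <- threshold_by_sparsity(rand_graph(76, seed = 2, p = 0.5), 0.05)
  expect_equal(network_density(W76), 142 / 2850)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  for (seed in 1:25) {
    n <- 4L + (seed %% 5L)
    W <- rand_graph(n, seed = 1000 + seed, p = 0.45)
    expect_equal(unname(node_strength(W)), rowSums(W))
    expect_equal(unname(clustering_coefficient(W)), bf_clustering(W),
                 tolerance = 1e-10)
    expect_equal(global_efficiency(W), bf_global_efficiency(W),
                 tolerance = 1e-10)
    expect_equal(unname(local_efficiency(W)), bf_local_efficiency(W),
                 tolerance = 1e-10)
    expect_equal(unname(node_betweenness(W)), bf_betweenness_pct(W),
                 tolerance = 1e-8)
  }
})

test_that("AUC summarizes metric curves by the trapezoidal rule", {
  grid <- analysis_config()$sparsity_grid
  # constant curve: AUC = range * value (the matrix is already sparser than
  # the whole grid, so every threshold keeps it unchanged)
  W <- threshold_by_sparsity(rand_graph(76, seed = 3, p = 0.5), 0.04)
  cv <- suppressWarnings(metric_curve(W, "density"))
  expect_equal(cv$auc, 0.08 * cv$values[1], tolerance = 1e-12)
  # density of an unsaturated network is k(s)/total: piecewise-linear ramp
  W2 <- rand_graph(76, seed = 4, p = 0.5)
  cv2 <- metric_curve(W2, "density")
  ks <- round(grid * 2850)
  expect_equal(cv2$values, ks / 2850)
  expect_equal(cv2$auc, sum(diff(grid) * (ks[-1] + ks[-9]) / 2 / 2850),
               tolerance = 1e-12)
  expect_error(metric_curve(W2, "density",
                            analysis_config(sparsity_min = 0.05,
                                            sparsity_max = 0.05)),
               "two thresholds")
  # density never decreases along the sparsity grid
  expect_true(all(diff(cv2$values) >= 0))
})

test_that("Holm-Sidak adjustment is monotone and exact for m = 1", {
  expect_equal(holm_sidak(0.03), 0.03)
  p <- c(0.01, 0.04, 0.03, 0.20)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  # step-down: smallest p gets the full Sidak exponent
  expect_equal(min(adj), 1 - (1 - 0.01)^4)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("D'Agostino-Pearson omnibus matches reference values", {
  x_norm <- c(10.00246, 10.597491, 9.451724, 8.218816, 9.090658, 8.016707,
              10.120287, 12.68043, 9.015587, 8.75905, 10.979684, 10.713774)
  r1 <- dagostino_pearson(x_norm)
  expect_equal(r1$statistic, 1.721484968547423, tolerance = 1e-8)
  expect_equal(r1$p.value, 0.42284800773854336, tolerance = 1e-8)
  x_exp <- c(0.89977, 1.073701, 1.88425, 0.222071, 3.144673, 0.735857,
             0.348373, 0.883565, 0.075062, 0.060046, 1.223566, 0.772906,
             2.195965, 0.475154, 0.521318)
  r2 <- dagostino_pearson(x_exp)
  expect_equal(r2$statistic, 7.579502977615181, tolerance = 1e-8)
  expect_equal(r2$p.value, 0.02260121780886637, tolerance = 1e-8)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("group AUC comparison rejects shifts and spares identical groups", {
  set.seed(99)
  a <- data.frame(m1 = rnorm(10), m2 = rnorm(10))
  same <- compare_groups_auc(a, a)
  expect_true(all(same$p_adj > 0.9))
  expect_false(any(same$significant))
  # a 3-SD shift at n = 10 is reliably detected
  hits <- vapply(1:40, function(r) {
    set.seed(500 + r)
    x <- data.frame(m = rnorm(10))
    y <- data.frame(m = rnorm(10) + 3)
    compare_groups_auc(y, x)$significant[1]
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
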