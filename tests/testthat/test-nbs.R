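# small cohorts of 4-node matrices with a single informative edge
edge_cohort <- function(weights, n = 4L) {
  lapply(weights, function(w) {
    W <- matrix(0, n, n)
    W[1, 2] <- W[2, 1] <- w
    W
  })
}

test_that("edge t statistics match hand-computed pooled-variance values", {
  A <- edge_cohort(c(0.5, 0.6, 0.7))
  B <- edge_cohort(c(0.2, 0.3, 0.4))
  Tm <- edge_t_stats(A, B, "a_gt_b")
  # m1 - m2 = 0.3, pooled var 0.01, se = sqrt(0.01 * 2/3)
  expect_equal(Tm[1, 2], 0.3 / sqrt(0.01 * 2 / 3), tolerance = 1e-12)
  expect_identical(Tm, t(Tm))
  expect_equal(sum(Tm != 0), 2L)            # only the informative edge
  expect_equal(edge_t_stats(A, B, "b_gt_a")[1, 2], -Tm[1, 2])
  # identical groups: all zero (up to float summation order)
  expect_lt(max(abs(edge_t_stats(A, A))), 1e-10)
  expect_error(edge_t_stats(A[1], B), "at least 2")
})

test_that("a strongly shifted edge dominates the t matrix", {
  set.seed(31)
  mats <- lapply(1:20, function(k) {
    W <- rand_graph(8, seed = 400 + k, p = 0.6)
    if (k <= 10) W[3, 7] <- W[7, 3] <- W[3, 7] + 5 * 0.26  # ~5 SD shift
    W
  })
  Tm <- edge_t_stats(mats[1:10], mats[11:20])
  expect_equal(max(Tm), Tm[3, 7])
  second <- max(Tm[upper.tri(Tm)][Tm[upper.tri(Tm)] < max(Tm)])
  expect_gt(Tm[3, 7], second)
})

test_that("suprathreshold components equal exhaustive DFS extraction", {
  # chain of two edges forms one component of size 2
  Tm <- matrix(0, 4, 4)
  Tm[1, 2] <- Tm[2, 1] <- 4; Tm[2, 3] <- Tm[3, 2] <- 5
  comps <- suprathreshold_components(Tm, 3)
  expect_equal(length(comps), 1L)
  expect_equal(comps[[1]]$size, 2L)
  expect_equal(suprathreshold_components(Tm, 10), list())
  # random graphs against the DFS oracle
  for (seed in 1:20) {
    W <- rand_graph(10, seed = 600 + seed, p = 0.25)
    Tr <- W * 6                         # pseudo t values
    comps <- suprathreshold_components(Tr, 3)
    ut <- which(upper.tri(Tr) & Tr > 3, arr.ind = TRUE)
    if (nrow(ut) == 0L) {
      expect_equal(comps, list())
    } else {
      expect_equal(sort(vapply(comps, `[[`, integer(1), "size"),
                        decreasing = TRUE),
                   bf_component_sizes(ut[, 1], ut[, 2]))
    }
  }
})

test_that("NBS permutation p-values are valid, bounded and reproducible", {
  cohorts <- make_default_cohorts(seed = 42L)
  res <- nbs_test(cohorts$complete_ccd, cohorts$virtual_callosotomy,
                  t_star = 3, n_perm = 200, seed = 5)
  expect_true(all(vapply(res$components, `[[`, numeric(1), "p") >= 1 / 201))
  expect_true(all(vapply(res$components, `[[`, numeric(1), "p") <= 1))
  res2 <- nbs_test(cohorts$complete_ccd, cohorts$virtual_callosotomy,
                   t_star = 3, n_perm = 200, seed = 5)
  expect_identical(res$null_max, res2$null_max)
  expect_identical(vapply(res$components, `[[`, numeric(1), "p"),
                   vapply(res2$components, `[[`, numeric(1), "p"))
  expect_error(nbs_test(cohorts$normal_cc, cohorts$complete_ccd, 3, 50), "100")
})

test_that("NBS recovers a planted subnetwork and the Probst contrast", {
  # planted dense 8-edge star-like subnetwork, ~2 SD shift, n = 10 vs 10
  planted <- rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4), c(4, 5),
                   c(4, 6), c(5, 6))
  mk <- function(k, shift) {
    W <- rand_graph(12, seed = 700 + k, p = 0.6)
    if (shift) {
      # per-edge SD of this weight model (Bernoulli(0.6) x U(0.1, 1)) ~ 0.32
      W[planted] <- W[planted] + 2 * 0.32
      W[planted[, 2:1]] <- W[planted]
    }
    W
  }
  A <- lapply(1:10, mk, shift = TRUE)
  B <- lapply(11:20, mk, shift = FALSE)
  res <- nbs_test(A, B, t_star = 3, n_perm = 500, seed = 9)
  expect_gt(length(res$components), 0L)
  top <- res$components[[1]]
  expect_lt(top$p, 0.05)
  planted_keys <- paste(planted[, 1], planted[, 2])
  found_keys <- paste(top$edges$i, top$edges$j)
  expect_gt(length(intersect(found_keys, planted_keys)), 3L)
  # condition contrast: complete CCD > virtual callosotomy flags the
  # bilateral frontal-posterior (Probst) subnetworks
  cohorts <- make_default_cohorts(seed = 42L)
  resP <- nbs_test(cohorts$complete_ccd, cohorts$virtual_callosotomy,
                   t_star = 3, n_perm = 500, seed = 5)
  sig <- Filter(function(cm) cm$significant, resP$components)
  expect_gte(length(sig), 1L)
  sig_nodes <- unique(unlist(lapply(sig, function(cm)
    c(cm$edges$label_i, cm$edges$label_j))))
  expect_true(any(grepl("^Fra_", sig_nodes)))
})

test_that("threshold sweep counts significant thresholds per edge", {
  cohorts <- make_default_cohorts(seed = 42L)
  sw <- threshold_sweep(cohorts$complete_ccd, cohorts$virtual_callosotomy,
                        thresholds = 2:5, n_perm = 300, seed = 3)
  expect_true(all(sw$counts >= 0L & sw$counts <= 4L))
  expect_identical(sw$counts, t(sw$counts))
  # the Probst edges are flagged across several thresholds
  parc <- cohorts$complete_ccd$parcellation
  iF <- which(parc$label == "Fra_L"); iP <- which(parc$label == "Pa_L")
  expect_gte(sw$counts[iF, iP], 2L)
  # an edge identical in both groups is never flagged
  iS <- which(parc$label == "Sub_L"); iSr <- which(parc$label == "Sub_R")
  expect_equal(sw$counts[iS, iSr], 0L)
})

test_that("NBS controls the family-wise error rate at a loose threshold", {
  # light null calibration at t* = 2 (the most permissive threshold of the
  # sweep); the full calibration at t* = 3 lives with the acceptance checks
  sim <- nbs_fwer_null(n_replicates = 60L, n_perm = 400L, t_star = 2,
                       seed = 17L)
  expect_lte(sim$fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})
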