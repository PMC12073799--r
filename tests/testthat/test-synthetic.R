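parc <- build_parcellation()
cfg <- cohort_config(rng_seed = 11L)

test_that("templates respect edge-class anatomy across conditions", {
  tpl <- lapply(c(normal_cc = "normal_cc", complete_ccd = "complete_ccd",
                  partial_ccd = "partial_ccd"),
                function(cn) build_template(parc, cn, cfg)$edges)
  for (ed in tpl) {
    expect_true(all(ed$i < ed$j))
    expect_equal(anyDuplicated(ed[, c("i", "j")]), 0L)
    inter <- parc$hemisphere[ed$i] != parc$hemisphere[ed$j]
    # commissural tags only interhemispheric, probst only intrahemispheric
    expect_true(all(inter[ed$tract_tag %in% c("cc", "ac", "pc", "hc", "sigmoid")]))
    expect_true(all(!inter[ed$tract_tag %in% c("probst", "intra")]))
  }
  # callosal edges are homotopic cortical pairs, absent in complete CCD
  ncc <- tpl$normal_cc
  cc <- ncc[ncc$tract_tag == "cc", ]
  expect_true(all(parc$abbrev[cc$i] == parc$abbrev[cc$j]))
  expect_true(all(parc$is_cortical[cc$i]))
  expect_equal(sum(tpl$complete_ccd$tract_tag == "cc"), 0L)
  # non-callosal commissures identical in every condition
  comm <- function(ed) ed[ed$tract_tag %in% c("ac", "pc", "hc"),
                          c("i", "j", "mean_weight", "tract_tag")]
  expect_equal(comm(tpl$complete_ccd), comm(ncc), ignore_attr = TRUE)
  expect_equal(comm(tpl$partial_ccd), comm(ncc), ignore_attr = TRUE)
  expect_error(build_template(parc, "no_such_condition", cfg))
})

test_that("partial CCD plants an anterior remnant and the sigmoid bundle", {
  ed <- build_template(parc, "partial_ccd", cfg)$edges
  ncc <- build_template(parc, "normal_cc", cfg)$edges
  rem <- ed[ed$tract_tag == "cc", ]
  n_cc <- sum(ncc$tract_tag == "cc")
  expect_equal(nrow(rem), ceiling(cfg$remnant_fraction * n_cc))
  # remnant is the anterior-most callosal subset
  expect_lt(max(parc$ap_rank[rem$i]),
            max(parc$ap_rank[ncc$i[ncc$tract_tag == "cc"]]))
  sig <- ed[ed$tract_tag == "sigmoid", ]
  expect_setequal(parc$label[sig$i], "Fra_L")
  expect_setequal(parc$label[sig$j], c("Hp_R", "Pa_R"))
  expect_equal(sig$presence_prob[parc$label[sig$j] == "Hp_R"],
               cfg$sigmoid_penetrance)
})

test_that("degenerate noise reproduces template means exactly", {
  cfg0 <- cohort_config(rng_seed = 3L, weight_sd = 0,
                        ccd_weight_sd_factor = 1,
                        edge_consistency = c(intra = 1, cc = 1, ac = 1,
                                             pc = 1, hc = 1, probst = 1,
                                             sigmoid = 1))
  tpl <- build_template(parc, "normal_cc", cfg0)
  W <- sample_individual(tpl, cfg0, 1L)
  ref <- matrix(0, 76, 76)
  ref[cbind(tpl$edges$i, tpl$edges$j)] <- tpl$edges$mean_weight
  ref[lower.tri(ref)] <- t(ref)[lower.tri(ref)]
  expect_equal(unname(W), ref)
})

test_that("sampling is deterministic given (seed, subject)", {
  tpl <- build_template(parc, "partial_ccd", cfg)
  expect_identical(sample_individual(tpl, cfg, 4L),
                   sample_individual(tpl, cfg, 4L))
  expect_false(identical(sample_individual(tpl, cfg, 4L),
                         sample_individual(tpl, cfg, 5L)))
})

test_that("edge retention matches the binomial expectation", {
  cfg8 <- cohort_config(rng_seed = 21L,
                        edge_consistency = c(intra = 0.8, cc = 0.8, ac = 0.8,
                                             pc = 0.8, hc = 0.8, probst = 0.8,
                                             sigmoid = 0.8))
  tpl <- build_template(parc, "normal_cc", cfg8)
  n_e <- nrow(tpl$edges)
  fracs <- vapply(1:10, function(s) {
    W <- sample_individual(tpl, cfg8, s)
    sum(W[upper.tri(W)] > 0) / n_e
  }, numeric(1))
  # mean retained fraction within 3 binomial SDs of 0.8
  sd_bin <- sqrt(0.8 * 0.2 / (n_e * 10))
  expect_lt(abs(mean(fracs) - 0.8), 3 * sd_bin)
})

test_that("all sampled matrices satisfy connectome invariants", {
  for (cn in c("normal_cc", "complete_ccd", "partial_ccd",
               "virtual_callosotomy")) {
    co <- generate_cohort(cn, cohort_config(n_subjects = 3L, rng_seed = 5L))
    for (W in co$subjects) {
      expect_identical(W, t(W))
      expect_equal(unname(diag(W)), rep(0, 76))
      expect_true(all(W >= 0 & W <= 1))
    }
  }
})

test_that("virtual callosotomy shares all non-callosal draws with normal CC", {
  ncc <- generate_cohort("normal_cc", cfg)
  vc <- generate_cohort("virtual_callosotomy", cfg)
  cc <- ncc$template$edges[ncc$template$edges$tract_tag == "cc", c("i", "j")]
  for (s in seq_along(ncc$subjects)) {
    expected <- virtual_callosotomy(ncc$subjects[[s]], cc)
    expect_identical(vc$subjects[[s]], expected)
  }
  # intrahemispheric submatrices are bitwise identical
  left <- which(parc$hemisphere == "L")
  expect_identical(vc$subjects[[1]][left, left], ncc$subjects[[1]][left, left])
})

test_that("sigmoid carriers follow the configured penetrance", {
  co <- generate_cohort("partial_ccd", cohort_config(rng_seed = 42L))
  carriers <- co$metadata$sigmoid_carriers
  iF <- which(parc$label == "Fra_L"); jH <- which(parc$label == "Hp_R")
  observed <- which(vapply(co$subjects, function(W) W[iF, jH] > 0, logical(1)))
  expect_identical(carriers, observed)
  # across many seeds the carrier rate approaches the penetrance
  rate <- mean(vapply(1:30, function(s) {
    co <- generate_cohort("partial_ccd", cohort_config(rng_seed = 100L + s))
    length(co$metadata$sigmoid_carriers) / 10
  }, numeric(1)))
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.5 * 0.5 / 300))
})

test_that("lowering edge consistency lowers expected pairwise similarity", {
  sim_at <- function(cons) {
    vals <- vapply(1:4, function(s) {
      cfgc <- cohort_config(n_subjects = 6L, rng_seed = 200L + s,
                            edge_consistency = c(intra = cons))
      pairwise_similarity(generate_cohort("normal_cc", cfgc), "intra")$mean
    }, numeric(1))
    mean(vals)
  }
  expect_gt(sim_at(0.95), sim_at(0.7))
  expect_gt(sim_at(0.7), sim_at(0.5))
})
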