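test_that("bias factors convert log biases to multiplicative errors", {
  expect_equal(bias_factor(0), 1)
  expect_equal(round(bias_factor(0.1614), 2), 1.45)
  expect_equal(round(bias_factor(-0.001), 3), 0.998)
  expect_equal(round(bias_factor(1.5), 1), 31.6)
  expect_equal(round(bias_factor(0.15), 2), 1.41)
})

test_that("bias summaries keep the declared run bookkeeping and reproduce under a seed", {
  pop <- sample_population(builtin_profile("exp1_2AFC_g"), n = 4, seed = 81)
  b1 <- bias_for_spread(pop, 1.2, "subject", n_sims = 25, n_trials = 10,
                        seed = 82)
  expect_equal(b1$n_runs, 4L * 25L)
  expect_equal(b1$n_observers, 4L)
  expect_equal(b1$bias_factor, 10^b1$mean_bias)
  b2 <- bias_for_spread(pop, 1.2, "subject", n_sims = 25, n_trials = 10,
                        seed = 82)
  expect_identical(b1$mean_bias, b2$mean_bias)
  expect_identical(b1$sd_bias, b2$sd_bias)
  per <- attr(b1, "per_observer")
  expect_equal(nrow(per), 4)
  expect_equal(mean(per$mean_bias), b1$mean_bias)
  expect_error(bias_for_spread(pop, 1.2, "fixed"),
               class = "zestsim_invalid_parameter")
})

test_that("matched model and observer give nearly unbiased estimates", {
  obs <- tibble::tibble(id = "std", threshold = 1.5, spread = 1,
                        lapse = 0.03, task = 4L)
  bs <- bias_for_spread(obs, 1, "subject", n_sims = 2000, n_trials = 100,
                        seed = 83)
  expect_lt(abs(bs$mean_bias), 0.02)
})

test_that("percentile candidates follow linear-interpolation quantiles", {
  pop <- tibble::tibble(id = letters[1:4], threshold = 1.5,
                        spread = c(0.5, 1, 1.5, 2), lapse = 0.02, task = 2L)
  sw <- percentile_sweep(pop, "fixed", model_lapse = 0.02, n_sims = 5,
                         n_trials = 5, percentiles = c(25, 50, 75), seed = 84)
  expect_equal(sw$sigma_m, unname(quantile(c(0.5, 1, 1.5, 2),
                                           c(0.25, 0.5, 0.75))))
  expect_gt(sw$sigma_m[2], 1); expect_lt(sw$sigma_m[2], 1.5)
  expect_equal(nrow(sw), 3)
  expect_equal(sum(sw$optimal), 1L)
  expect_equal(which(sw$optimal), which.min(sw$abs_bias_sd))
})

test_that("sweep bookkeeping matches the declared factorial design", {
  d <- sweep_design(n_observers = 71, n_sims = 2000, n_percentiles = 19)
  expect_equal(d$per_percentile, 142000)
  expect_equal(d$total, 2698000)
  pop <- sample_population(builtin_profile("exp1_2AFC_g"), n = 3, seed = 85)
  sw <- percentile_sweep(pop, "fixed", model_lapse = 0.02, n_sims = 4,
                         n_trials = 5, percentiles = seq(5, 95, 5), seed = 86)
  expect_equal(nrow(sw), 19)
  expect_equal(attr(sw, "total_runs"),
               sweep_design(3, 4, 19)$total)
  expect_equal(unique(sw$n_runs), sweep_design(3, 4, 19)$per_percentile)
})

test_that("procedure comparisons are tidy and fixed-spread ZEST ignores the spread prior", {
  task <- task_spec(4)
  cu <- compare_procedures(c("zest_fixed_sigma", "zest2d_theta"), task,
                           trial_counts = c(5, 10), n_sims = 15, seed = 87)
  cg <- compare_procedures(c("zest_fixed_sigma", "zest2d_theta"), task,
                           spread_prior = gaussian_prior(1.186, 0.74),
                           trial_counts = c(5, 10), n_sims = 15, seed = 87)
  expect_equal(nrow(cu), 4)   # 2 procedures x 2 trial counts
  zu <- dplyr::filter(cu, procedure == "zest_fixed_sigma")
  zg <- dplyr::filter(cg, procedure == "zest_fixed_sigma")
  expect_identical(zu$mean_bias, zg$mean_bias)
  expect_identical(zu$sd_bias, zg$sd_bias)
  # the gaussian prior does change the spread-axis procedures
  expect_false(identical(
    dplyr::filter(cu, procedure == "zest2d_theta")$mean_bias,
    dplyr::filter(cg, procedure == "zest2d_theta")$mean_bias))
  expect_equal(unique(cu$n_runs), 15L)
})

test_that("a procedure's comparison rows do not depend on its companions", {
  task <- task_spec(4)
  alone <- compare_procedures("zest_fixed_sigma", task, trial_counts = 10,
                              n_sims = 10, seed = 88)
  paired <- compare_procedures(c("psi_marg_theta_S", "zest_fixed_sigma"), task,
                               trial_counts = 10, n_sims = 10, seed = 88)
  expect_identical(alone$mean_bias,
                   dplyr::filter(paired, procedure == "zest_fixed_sigma")$mean_bias)
})
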