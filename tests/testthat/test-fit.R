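test_that("sessions aggregate to per-level counts with practice excluded", {
  s <- tibble::tibble(trial = 1:4, level = c(3, 2, 2, 2),
                      response = c(1, 1, 1, 0),
                      practice = c(TRUE, FALSE, FALSE, FALSE))
  agg <- aggregate_session(s)
  expect_equal(agg, tibble::tibble(level = 2, n = 3L, k = 2L))
  agg_all <- aggregate_session(s, exclude_practice = FALSE)
  expect_equal(sum(agg_all$n), 4L)
  expect_error(aggregate_session(s[0, ]), class = "zestsim_empty_data")
  # count conservation on a simulated 80-trial session
  sess <- run_updown(standard_obs(4), staircase_config(n_trials = 80), seed = 3)
  expect_equal(sum(aggregate_session(sess)$n), 79L)
  expect_equal(sum(aggregate_session(sess, exclude_practice = FALSE)$n), 80L)
})

test_that("the negative log-likelihood matches hand arithmetic and penalizes violations", {
  # one level with psi = 0.7 exactly: parameterize the threshold at pi = 0.7
  d <- tibble::tibble(level = 1.5, n = 10L, k = 7L)
  val <- negative_log_likelihood(1.5, 1, 0.03, d, guess = 0.25,
                                 criterion = 0.7)
  expect_equal(val, -(7 * log(0.7) + 3 * log(0.3)), tolerance = 1e-12)
  expect_equal(round(val, 4), 6.1086)
  # constraint violations give a large finite penalty, not an error
  expect_gt(negative_log_likelihood(1.5, -1, 0.03, d, 0.25), 1e9)
  expect_gt(negative_log_likelihood(1.5, 1, 0.08, d, 0.25), 1e9)
  expect_true(is.finite(negative_log_likelihood(1.5, -1, 0.03, d, 0.25)))
  # the generating parameters beat local perturbations on a rich design
  set.seed(71)
  obs <- standard_obs(4)
  dat <- simulate_constant_design(obs, seq(0.4, 2.9, 0.25), 200L)
  nll0 <- negative_log_likelihood(1.5, 1, 0.03, dat, 0.25)
  for (dlt in list(c(0.2, 0, 0), c(-0.2, 0, 0), c(0, 0.4, 0),
                   c(0, -0.4, 0), c(0, 0, 0.025))) {
    expect_gt(negative_log_likelihood(1.5 + dlt[1], 1 + dlt[2], 0.03 + dlt[3],
                                      dat, 0.25), nll0)
  }
})

test_that("deviance matches hand values and the saturated-likelihood identity", {
  d1 <- tibble::tibble(level = 1, n = 10L, k = 7L)
  expect_equal(deviance_gof(d1, 0.7), 0, tolerance = 1e-12)
  expect_equal(round(deviance_gof(d1, 0.5), 3), 1.646)
  expect_equal(deviance_gof(d1, 0.5), 2 * (7 * log(1.4) + 3 * log(0.6)),
               tolerance = 1e-12)
  # Dev = 2 (loglik_saturated - loglik_fitted) on arbitrary data and fits
  set.seed(72)
  dat <- simulate_constant_design(standard_obs(2), seq(0.5, 2.8, 0.3), 40L)
  psi <- zestsim:::clip_probability(
    model_probability(dat$level, 1.4, 1.2, 0.01, task_spec(2), 0.75))
  ll_fit <- -negative_log_likelihood(1.4, 1.2, 0.01, dat, 0.5)
  p_obs <- dat$k / dat$n
  ll_sat <- sum(ifelse(dat$k > 0, dat$k * log(p_obs), 0) +
                ifelse(dat$n - dat$k > 0, (dat$n - dat$k) * log(1 - p_obs), 0))
  expect_equal(deviance_gof(dat, psi), 2 * (ll_sat - ll_fit), tolerance = 1e-9)
  # edge levels with k = n contribute through the 0 log 0 convention
  d2 <- tibble::tibble(level = c(1, 2), n = c(5L, 5L), k = c(5L, 0L))
  expect_true(is.finite(deviance_gof(d2, c(0.9, 0.1))))
})

test_that("maximum-likelihood fitting recovers generating parameters", {
  set.seed(73)
  obs <- simulated_observer(1.5, 1, 0.03, task_spec(4))
  dat <- simulate_constant_design(obs, seq(0.3, 3, 0.15), 105L)  # ~2000 trials
  fit <- fit_ml(dat, task_spec(4), n_boot = 0)
  expect_lt(abs(fit$theta_hat - 1.5), 0.05)
  expect_lt(abs(fit$sigma_hat - 1.0), 0.15)
  expect_lt(abs(fit$lambda_hat - 0.03), 0.02)
  # the fitted threshold sits at the criterion probability by construction
  expect_equal(model_probability(fit$theta_hat, fit$theta_hat, fit$sigma_hat,
                                 fit$lambda_hat, task_spec(4), 0.75),
               0.75, tolerance = 1e-9)
  # zero-lapse data pushes the lapse to its lower bound
  set.seed(74)
  obs0 <- simulated_observer(1.5, 1, 0, task_spec(4))
  dat0 <- simulate_constant_design(obs0, seq(0.3, 3, 0.15), 105L)
  fit0 <- fit_ml(dat0, task_spec(4), n_boot = 0)
  expect_lt(fit0$lambda_hat, 0.01)
  # degenerate data refuse to fit
  all1 <- tibble::tibble(level = c(1, 2, 3), n = c(5L, 5L, 5L), k = c(5L, 5L, 5L))
  expect_error(fit_ml(all1, task_spec(4), n_boot = 0),
               class = "zestsim_non_identifiable")
  expect_error(fit_ml(dat[1:2, ], task_spec(4), n_boot = 0),
               class = "zestsim_non_identifiable")
})

test_that("bootstrap deviance p-values behave at the extremes and reproduce", {
  d <- tibble::tibble(level = c(1, 1.5, 2), n = c(20L, 20L, 20L),
                      k = c(10L, 15L, 19L))
  # saturated fit: observed deviance 0, p = 1
  expect_equal(p_deviance(d, d$k / d$n, B = 200, seed = 1), 1)
  p1 <- p_deviance(d, c(0.5, 0.8, 0.93), B = 300, seed = 2)
  p2 <- p_deviance(d, c(0.5, 0.8, 0.93), B = 300, seed = 2)
  expect_identical(p1, p2)
  expect_error(p_deviance(d, d$k / d$n, B = 50),
               class = "zestsim_invalid_parameter")
})

test_that("inclusion requires theta in [1,500] arcsec, sigma in [0.01,7], p > 0.05", {
  base <- structure(list(theta_hat = log10(33.7), sigma_hat = 1,
                         lambda_hat = 0.02, p_deviance = 0.2),
                    class = "psyfit")
  expect_true(passes_inclusion(base))
  bad_theta <- base; bad_theta$theta_hat <- log10(600)
  expect_false(passes_inclusion(bad_theta))
  bad_sigma <- base; bad_sigma$sigma_hat <- 0.005
  expect_false(passes_inclusion(bad_sigma))
  bad_p <- base; bad_p$p_deviance <- 0.01
  expect_false(passes_inclusion(bad_p))
})

test_that("tidy and glance summarize fits in broom style", {
  set.seed(75)
  dat <- simulate_constant_design(standard_obs(4), seq(0.5, 2.9, 0.3), 40L)
  fit <- fit_ml(dat, task_spec(4), n_boot = 200, seed = 8)
  td <- tidy(fit)
  expect_equal(td$term, c("threshold", "spread", "lapse", "guess"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$theta_arcsec, 10^gl$theta_hat)
  expect_true(is.logical(gl$included))
})
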