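test_that("spread/slope conversion reproduces the reference values and round-trips", {
  expect_equal(round(spread_to_slope(1), 3), 7.327)
  expect_equal(round(spread_to_slope(1.7), 1), 4.3)
  expect_equal(round(spread_to_slope(1.5), 1), 4.9)
  set.seed(1)
  s <- exp(runif(50, log(0.03), log(5)))
  expect_equal(slope_to_spread(spread_to_slope(s)), s, tolerance = 1e-12)
  expect_error(spread_to_slope(0), class = "zestsim_invalid_parameter")
  expect_error(slope_to_spread(-1), class = "zestsim_invalid_parameter")
})

test_that("base logistic has its symmetry point, asymptotes and monotonicity", {
  expect_equal(base_logistic(1.2, 1.2, 3), 0.5)
  expect_equal(base_logistic(50, 1, 7.3), 1, tolerance = 1e-9)
  expect_equal(base_logistic(-50, 1, 7.3), 0, tolerance = 1e-9)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0, 3); b <- exp(runif(1, log(0.5), log(20)))
    # stay inside the numerically resolvable range of the sigmoid
    x <- a + sort(runif(20, -25, 25)) / b
    expect_true(all(diff(base_logistic(x, a, b)) > 0))
  }
  expect_error(base_logistic(Inf, 1, 2), class = "zestsim_invalid_parameter")
  expect_error(base_logistic(1, 1, -2), class = "zestsim_invalid_parameter")
})

test_that("the standard-observer locations put 75% correct at threshold 1.5", {
  # printed locations are rounded to 3 d.p.; agreement is to within 0.001
  a2 <- location_from_threshold(1.5, spread_to_slope(1), 0.5, 0.02, 0.75)
  a4 <- location_from_threshold(1.5, spread_to_slope(1), 0.25, 0.03, 0.75)
  expect_equal(a2, 1.488, tolerance = 1e-3)
  expect_equal(a4, 1.387, tolerance = 1e-3)
  m2 <- psychometric_model(location = 1.488, spread = 1, guess = 0.5,
                           lapse = 0.02)
  m4 <- psychometric_model(location = 1.387, spread = 1, guess = 0.25,
                           lapse = 0.03)
  # the printed locations carry ~0.001 rounding, which propagates through
  # the slope (~7.3) into up to ~0.0015 on the probability
  expect_lt(abs(response_probability(1.5, m2) - 0.75), 2e-3)
  expect_lt(abs(response_probability(1.5, m4) - 0.75), 2e-3)
  # asymptotes
  expect_equal(response_probability(-50, m4), 0.25, tolerance = 1e-9)
  expect_equal(response_probability(50, m4), 1 - 0.03, tolerance = 1e-9)
})

test_that("threshold/location conversion is exact at the criterion and invertible", {
  # midpoint criterion puts the location at the threshold
  expect_equal(location_from_threshold(1.2, 5, 0.5, 0.1, (0.5 + 0.9) / 2), 1.2)
  set.seed(3)
  for (i in 1:25) {
    th <- runif(1, 0.2, 2.8); sg <- exp(runif(1, log(0.1), log(3)))
    n_alt <- sample(c(2L, 4L), 1); gm <- 1 / n_alt
    lm <- runif(1, 0, 0.05)
    obs <- simulated_observer(th, sg, lm, task_spec(n_alt))
    expect_equal(response_probability(th, obs), 0.75, tolerance = 1e-9)
    al <- location_from_threshold(th, spread_to_slope(sg), gm, lm, 0.75)
    expect_equal(threshold_from_location(al, spread_to_slope(sg), gm, lm, 0.75),
                 th, tolerance = 1e-12)
  }
  expect_error(location_from_threshold(1.5, 5, 0.5, 0.3, 0.75),
               class = "zestsim_infeasible_criterion")
})

test_that("lapse conversions follow lambda = lambda_star (1 - gamma)", {
  expect_equal(lapse_from_lapse_star(0.04, 0.5), 0.02)
  expect_equal(lapse_from_lapse_star(0.04, 0.25), 0.03)
  expect_equal(lapse_from_lapse_star(0, 0.77), 0)
  set.seed(4)
  ls <- runif(20); gm <- runif(20, 0, 0.9)
  expect_equal(lapse_star_from_lapse(lapse_from_lapse_star(ls, gm), gm), ls,
               tolerance = 1e-12)
  expect_error(lapse_from_lapse_star(1.2, 0.5),
               class = "zestsim_invalid_parameter")
  expect_error(lapse_star_from_lapse(0.6, 0.5),
               class = "zestsim_invalid_parameter")
})

test_that("model validation rejects inconsistent parameters", {
  expect_error(psychometric_model(1, spread = 1, slope = 2),
               class = "zestsim_invalid_parameter")
  expect_error(psychometric_model(1, spread = -1),
               class = "zestsim_invalid_parameter")
  expect_error(psychometric_model(1, spread = 1, guess = 0.6, lapse = 0.5),
               class = "zestsim_invalid_parameter")
  expect_error(task_spec(3), class = "zestsim_invalid_parameter")
})

test_that("simulated responses are reproducible Bernoulli draws at the model rate", {
  m <- standard_obs(2)
  set.seed(10); r1 <- simulate_response(m, rep(1.5, 50))
  set.seed(10); r2 <- simulate_response(m, rep(1.5, 50))
  expect_identical(r1, r2)
  # no lapse, far above threshold: always correct
  easy <- psychometric_model(1, spread = 1, guess = 0.5, lapse = 0)
  set.seed(11)
  expect_true(all(simulate_response(easy, rep(10, 1000)) == 1L))
  # far below threshold the 2AFC rate is the guess rate (binomial error)
  set.seed(12)
  f <- mean(simulate_response(m, rep(-10, 1e5)))
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 1e5))
})
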