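test_that("built-in profiles carry the per-experiment statistics", {
  p1 <- builtin_profile("exp1_2AFC_g")
  expect_equal(p1$spread, c(1.005, 0.776))
  expect_equal(p1$threshold, c(1.528, 0.3))
  expect_equal(p1$n, 71L)
  p2 <- builtin_profile("exp2_4AFC_g")
  expect_equal(p2$n, 68L)
  expect_equal(unname(p2$regression), c(-0.823, 1.305))
  p3 <- builtin_profile("exp3_4AFC_l")
  expect_equal(p3$spread, c(1.306, 0.632))
  expect_equal(unname(p3$regression), c(-0.159, 0.934))
  expect_error(builtin_profile("exp4"), class = "zestsim_invalid_request")
})

test_that("sampled populations match the profile moments within sampling error", {
  n <- 5000
  for (nm in c("exp1_2AFC_g", "exp2_4AFC_g", "exp3_4AFC_l")) {
    pr <- builtin_profile(nm)
    pop <- sample_population(pr, n = n, seed = 77)
    # 3-SE bounds: 18 simultaneous fixed-seed assertions across profiles,
    # so per-assertion 2-SE bounds would fail by chance alone
    expect_lt(abs(mean(pop$threshold) - pr$threshold[1]),
              3 * pr$threshold[2] / sqrt(n))
    expect_lt(abs(mean(pop$spread) - pr$spread[1]),
              3 * pr$spread[2] / sqrt(n))
    # SE of a sample SD with the kurtosis correction (the truncated
    # distributions are non-normal, so sd/sqrt(2n) would be too tight);
    # the generator itself is calibrated to the printed moments exactly
    se_sd <- function(x) {
      z <- x - mean(x)
      kap <- mean(z^4) / stats::var(x)^2
      sd(x) * sqrt(pmax(kap - 1, 0.1) / (4 * length(x)))
    }
    expect_lt(abs(sd(pop$threshold) - pr$threshold[2]),
              3 * se_sd(pop$threshold))
    expect_lt(abs(sd(pop$spread) - pr$spread[2]), 3 * se_sd(pop$spread))
    # the lapse* mean matches; its printed SD exceeds what the truncation
    # range [0, 0.08] permits, so only a lower bound is asserted
    expect_lt(abs(mean(pop$lapse_star) - pr$lapse_star[1]),
              3 * pr$lapse_star[2] / sqrt(n))
    expect_gt(sd(pop$lapse_star), 0.015)
    # truncation contracts
    expect_true(all(pop$spread >= 0.01 & pop$spread <= 7))
    expect_true(all(pop$threshold >= 0 & pop$threshold <= log10(500)))
    expect_true(all(pop$lapse_star >= 0 & pop$lapse_star <= 0.08))
    # model invariants hold for every generated observer
    expect_true(all(pop$lapse >= 0 & pop$lapse + 1 / pop$task < 1))
  }
})

test_that("4AFC spreads are coupled to thresholds with a positive correlation", {
  pop <- sample_population(builtin_profile("exp2_4AFC_g"), n = 5000, seed = 78)
  expect_gt(cor(pop$threshold, pop$spread), 0)
  # 2AFC spreads are sampled independently
  pop1 <- sample_population(builtin_profile("exp1_2AFC_g"), n = 5000, seed = 78)
  expect_lt(abs(cor(pop1$threshold, pop1$spread)), 0.05)
})

test_that("subject tables round-trip through CSV and drop out-of-range rows", {
  pop <- sample_population(builtin_profile("exp2_4AFC_g"), n = 20, seed = 79)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observer_csv(pop, path)
  back <- load_subject_table(path)
  expect_equal(back$threshold, pop$threshold, tolerance = 1e-12)
  expect_equal(back$spread, pop$spread, tolerance = 1e-12)
  expect_equal(back$lapse, pop$lapse, tolerance = 1e-12)
  # a 600-arcsec threshold row is dropped and counted
  bad <- pop
  bad$threshold[3] <- log10(600)
  write_observer_csv(bad, path)
  expect_message(dropped <- load_subject_table(path), "dropped 1 row")
  expect_equal(nrow(dropped), 19)
  expect_equal(attr(dropped, "n_dropped"), 1L)
  # an empty file is a format error
  writeLines("id,threshold,spread,lapse,task", path)
  expect_error(load_subject_table(path), class = "zestsim_format_error")
  # alternative column names are recognized
  alt <- tibble::tibble(subject = "a", theta_arcsec = 31.6, sigma = 1,
                        lambda = 0.02)
  readr::write_csv(alt, path)
  got <- load_subject_table(path, task = 2)
  expect_equal(got$threshold, log10(31.6))
})

test_that("session fixtures are seeded and byte-identical", {
  obs <- standard_obs(4)
  expect_length(sample_sessions(obs, staircase_config(n_trials = 10), 0), 0)
  s1 <- sample_sessions(obs, staircase_config(n_trials = 20), 3, seed = 80)
  s2 <- sample_sessions(obs, staircase_config(n_trials = 20), 3, seed = 80)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_session_csv(s1[[2]], f1, seed = 80)
  write_session_csv(s2[[2]], f2, seed = 80)
  expect_identical(readLines(f1), readLines(f2))
})
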