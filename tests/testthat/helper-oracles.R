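# Shared fixtures and independent oracles, kept deliberately naive: plain
# loops and direct formula evaluation, no reuse of the package's optimized
# paths.

standard_obs <- function(n_alt = 4) standard_observer(task_spec(n_alt))

# A small joint (theta, spread) posterior for placement tests.
small_posterior <- function(n_theta = 5, n_sigma = 3, task = task_spec(2),
                            lapse_fixed = 0.02, n_lapse = NULL) {
  grid <- parameter_grid(
    threshold = seq(0.5, 2.5, length.out = n_theta),
    spread = exp(seq(log(0.3), log(2.5), length.out = n_sigma)),
    lapse = if (!is.null(n_lapse)) seq(0, 0.06, length.out = n_lapse),
    stimuli = seq(0.5, 2.5, length.out = n_theta))
  init_prior(grid, task,
             lapse_fixed = if (is.null(n_lapse)) lapse_fixed)
}

# Brute-force expected posterior entropy: enumerate both responses per
# candidate and marginalize by explicit aggregation.
oracle_entropy <- function(posterior, candidates, interest) {
  pts <- posterior$points
  key <- interaction(lapply(interest, function(ax) pts[[ax]]), drop = FALSE)
  vapply(candidates, function(x) {
    psi <- model_probability(x, pts$threshold, pts$spread, pts$lapse,
                             posterior$task, posterior$criterion)
    psi <- pmin(pmax(psi, 1e-12), 1 - 1e-12)
    eh <- 0
    for (r in c(1L, 0L)) {
      lik <- if (r == 1L) psi else 1 - psi
      w <- posterior$mass * lik
      pr <- sum(w)
      m <- tapply(w / pr, key, sum)
      m <- m[!is.na(m) & m > 0]
      eh <- eh + pr * (-sum(m * log2(m)))
    }
    eh
  }, numeric(1))
}

# Exhaustive grid maximum-likelihood estimate of the threshold for a
# fixed-spread session: product of per-trial likelihoods over the theta
# axis, argmax (first index on ties).
oracle_grid_mle <- function(trace, config) {
  theta <- config$grid$threshold
  loglik <- numeric(length(theta))
  for (t in seq_len(nrow(trace))) {
    psi <- model_probability(trace$stimulus[t], theta, config$model_spread,
                             config$model_lapse, config$task,
                             config$criterion)
    psi <- pmin(pmax(psi, 1e-12), 1 - 1e-12)
    loglik <- loglik + if (trace$response[t] > 0) log(psi) else log(1 - psi)
  }
  theta[which.max(loglik)]
}

# Binomial counts from a fixed method-of-constant design under a model.
simulate_constant_design <- function(observer, levels, n_per_level) {
  p <- response_probability(levels, observer)
  tibble::tibble(level = levels, n = n_per_level,
                 k = stats::rbinom(length(levels), n_per_level, p))
}
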