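# Bayesian adaptive procedure configurations and the trial-loop driver.

.procedures <- c("zest_fixed_sigma", "zest2d_theta_sigma", "zest2d_theta",
                 "psi_theta_sigma", "psi_marg_theta_sigma_L",
                 "psi_marg_theta_SL", "psi_marg_theta_S")

#' Configuration of a Bayesian adaptive procedure
#'
#' Seven procedures are available:
#' \describe{
#'   \item{`zest_fixed_sigma`}{ZEST with a fixed assumed spread
#'     (`model_spread`) and lapse (`model_lapse`); posterior over the
#'     threshold only, uniform prior, posterior-mean placement ("ZEST
#'     optimal sigma" when `model_spread` is set from a population sweep).}
#'   \item{`zest2d_theta_sigma`, `zest2d_theta`}{joint posterior over
#'     threshold and spread, posterior-mean placement on the threshold
#'     marginal; the first reports a spread estimate, the second treats
#'     the spread purely as a nuisance parameter.}
#'   \item{`psi_theta_sigma`}{Psi: expected-entropy placement over the
#'     joint (threshold, spread) posterior, fixed lapse.}
#'   \item{`psi_marg_theta_sigma_L`}{Psi-marginal estimating threshold and
#'     spread while marginalizing the lapse rate (lapse axis with a
#'     uniform prior).}
#'   \item{`psi_marg_theta_SL`}{Psi-marginal estimating the threshold only,
#'     marginalizing spread and lapse.}
#'   \item{`psi_marg_theta_S`}{Psi-marginal estimating the threshold only,
#'     marginalizing the spread, lapse fixed at `model_lapse`.}
#' }
#' Exactly the parameters a procedure needs may be set: `model_spread`
#' only for `zest_fixed_sigma`; `model_lapse` for every procedure except
#' the two lapse-marginalizing ones; a non-uniform `spread_prior` only for
#' procedures with a spread axis. Threshold priors are always uniform.
#'
#' @param procedure One of the names above.
#' @param task A [task_spec()].
#' @param n_trials Number of trials (default 30).
#' @param criterion Criterion probability defining the threshold
#'   (default 0.75).
#' @param model_spread Assumed spread of the model function, log10 arcsec
#'   (fixed-spread ZEST only).
#' @param model_lapse Assumed lapse rate of the model function.
#' @param spread_prior `"uniform"` or [gaussian_prior()].
#' @param grid A [parameter_grid()]; defaults to a threshold axis
#'   `seq(0, 3, 0.01)` (stimulus candidates identical), the 21-value
#'   linear spread axis of [default_spread_axis()] where needed, and a
#'   lapse axis `seq(0, 0.06, 0.01)` where needed.
#' @param estimator `"mean"` (posterior mean, the default) or `"mode"`.
#' @param grid_parameterization How the first grid axis parameterizes a
#'   hypothesis: `"threshold"` (the threshold at the criterion, so every
#'   hypothesis satisfies `Psi(theta) = criterion`) or `"location"` (the
#'   location of the base logistic, the parameterization of the published
#'   Psi family; the threshold of a hypothesis then shifts with its spread
#'   and lapse). Defaults to `"threshold"` for the ZEST procedures and
#'   `"location"` for the Psi family. Threshold estimates are always
#'   reported at the criterion probability.
#'
#' @return An object of class `procedure_config`.
#' @export
procedure_config <- function(procedure, task, n_trials = 30, criterion = 0.75,
                             model_spread = NULL, model_lapse = NULL,
                             spread_prior = "uniform", grid = NULL,
                             estimator = c("mean", "mode"),
                             grid_parameterization = NULL) {
  procedure <- match.arg(procedure, .procedures)
  estimator <- match.arg(estimator)
  if (is.null(grid_parameterization)) {
    grid_parameterization <- if (startsWith(procedure, "psi")) "location" else
      "threshold"
  }
  grid_parameterization <- match.arg(grid_parameterization,
                                     c("threshold", "location"))
  stopifnot(inherits(task, "task_spec"))
  if (!is.finite(n_trials) || n_trials < 1) {
    rlang::abort("`n_trials` must be >= 1", class = "zestsim_invalid_config")
  }

  needs_spread_axis <- procedure != "zest_fixed_sigma"
  needs_lapse_axis <- procedure %in% c("psi_marg_theta_sigma_L",
                                       "psi_marg_theta_SL")
  if (procedure == "zest_fixed_sigma") {
    if (is.null(model_spread)) abort_invalid("zest_fixed_sigma needs `model_spread`")
    if (!identical(spread_prior, "uniform")) {
      abort_invalid("zest_fixed_sigma takes no spread prior")
    }
  } else if (!is.null(model_spread)) {
    abort_invalid("`model_spread` is only for zest_fixed_sigma")
  }
  if (needs_lapse_axis) {
    if (!is.null(model_lapse)) {
      abort_invalid(sprintf("%s marginalizes the lapse; do not set `model_lapse`",
                            procedure))
    }
  } else if (is.null(model_lapse)) {
    abort_invalid(sprintf("%s needs `model_lapse`", procedure))
  }
  if (!is.null(model_spread) && (!is.finite(model_spread) || model_spread <= 0)) {
    abort_invalid("`model_spread` must be > 0")
  }

  if (is.null(grid)) {
    grid <- parameter_grid(
      threshold = seq(0, 3, by = 0.01),
      spread = if (needs_spread_axis) default_spread_axis(),
      lapse = if (needs_lapse_axis) seq(0, 0.06, by = 0.01))
  }
  if (needs_spread_axis && is.null(grid$spread)) {
    abort_invalid(sprintf("%s needs a spread axis in the grid", procedure))
  }
  if (!needs_spread_axis && !is.null(grid$spread)) {
    abort_invalid("zest_fixed_sigma takes no spread axis")
  }
  if (needs_lapse_axis && is.null(grid$lapse)) {
    abort_invalid(sprintf("%s needs a lapse axis in the grid", procedure))
  }
  if (!needs_lapse_axis && !is.null(grid$lapse)) {
    abort_invalid(sprintf("%s takes no lapse axis", procedure))
  }

  placement <- if (startsWith(procedure, "zest")) "zest" else "psi"
  interest <- switch(procedure,
    psi_theta_sigma = c("threshold", "spread"),
    psi_marg_theta_sigma_L = c("threshold", "spread"),
    psi_marg_theta_SL = "threshold",
    psi_marg_theta_S = "threshold",
    NULL)
  structure(
    list(procedure = procedure, task = task, n_trials = as.integer(n_trials),
         criterion = criterion, model_spread = model_spread,
         model_lapse = model_lapse, spread_prior = spread_prior, grid = grid,
         estimator = estimator, placement = placement, interest = interest,
         parameterization = grid_parameterization,
         report_sigma = procedure %in% c("zest2d_theta_sigma",
                                         "psi_theta_sigma",
                                         "psi_marg_theta_sigma_L"),
         report_lambda = needs_lapse_axis),
    class = "procedure_config"
  )
}

#' @export
print.procedure_config <- function(x, ...) {
  cat(sprintf("<procedure_config> %s, %dAFC, %d trials, pi = %.3g\n",
              x$procedure, x$task$n_alternatives, x$n_trials, x$criterion))
  invisible(x)
}

config_prior <- function(config) {
  init_prior(config$grid, config$task, config$spread_prior, config$criterion,
             spread_fixed = config$model_spread,
             lapse_fixed = config$model_lapse,
             parameterization = config$parameterization)
}

config_likelihood <- function(config) {
  likelihood_table(config$grid, config$task, config$criterion,
                   spread_fixed = config$model_spread,
                   lapse_fixed = config$model_lapse,
                   parameterization = config$parameterization)
}

snap_index <- function(x, candidates) {
  i <- findInterval(x, candidates, all.inside = TRUE)
  ifelse(x - candidates[i] <= candidates[i + 1] - x, i, i + 1L)
}

#' Run one adaptive Bayesian session against a simulated observer
#'
#' Repeats place -> respond -> update for `config$n_trials` trials: ZEST
#' procedures place at the posterior mean of the threshold marginal, Psi
#' procedures at the expected-entropy minimizer; the simulated observer
#' answers with a Bernoulli draw from its psychometric function; the
#' posterior is Bayes-updated. Per-trial estimates are posterior means
#' (or the mode when `estimator = "mode"`) of the marginal for each
#' estimated parameter.
#'
#' @param observer A [simulated_observer()].
#' @param config A [procedure_config()].
#' @param seed Optional integer seed.
#' @param responses Optional replay vector of 0/1 responses (no random
#'   draws are made).
#'
#' @return A tibble of class `estimate_trace` with columns `trial`,
#'   `stimulus`, `response`, `theta_hat` and, where the procedure
#'   estimates them, `sigma_hat` / `lambda_hat`; the final posterior is
#'   attached as attribute `posterior`.
#' @export
run_procedure <- function(observer, config, seed = NULL, responses = NULL) {
  stopifnot(inherits(observer, "simulated_observer"),
            inherits(config, "procedure_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  replay <- !is.null(responses)
  if (replay && length(responses) != n) {
    rlang::abort("`responses` must have length `n_trials`",
                 class = "zestsim_invalid_config")
  }
  lik <- config_likelihood(config)
  post <- config_prior(config)
  cand <- config$grid$stimuli
  obs_p <- response_probability(cand, observer)

  # per-hypothesis thresholds at the criterion (= the grid axis under the
  # threshold parameterization, shifted by spread/lapse under "location")
  est_axis <- function(p, axis) {
    if (config$estimator == "mean") {
      vals <- if (axis == "threshold") lik$theta else post$points[[axis]]
      sum(p * vals)
    } else {
      idx <- match(post$points[[axis]], config$grid[[axis]])
      config$grid[[axis]][which.max(rowsum(p, idx))]
    }
  }

  p <- post$mass
  stim <- numeric(n); resp <- integer(n)
  th <- numeric(n)
  sg <- if (config$report_sigma) numeric(n) else NULL
  lm <- if (config$report_lambda) numeric(n) else NULL
  for (t in seq_len(n)) {
    post$mass <- p
    # zest placement is always the posterior mean, whatever the estimator
    ci <- if (config$placement == "zest") {
      snap_index(sum(p * lik$theta), cand)
    } else {
      which.min(expected_posterior_entropy(post, cand, config$interest, lik))
    }
    stim[t] <- cand[ci]
    resp[t] <- if (replay) as.integer(responses[t] > 0) else {
      as.integer(stats::runif(1) < obs_p[ci])
    }
    lk <- if (resp[t] > 0) lik$L[, ci] else 1 - lik$L[, ci]
    p <- p * lk
    p <- p / sum(p)
    th[t] <- est_axis(p, "threshold")
    if (config$report_sigma) sg[t] <- est_axis(p, "spread")
    if (config$report_lambda) lm[t] <- est_axis(p, "lapse")
  }
  post$mass <- p
  out <- tibble::tibble(trial = seq_len(n), stimulus = stim, response = resp,
                        theta_hat = th)
  if (config$report_sigma) out$sigma_hat <- sg
  if (config$report_lambda) out$lambda_hat <- lm
  structure(out, class = c("estimate_trace", class(out)),
            config = config, observer_id = observer$id, posterior = post)
}

# Vectorized engine running `n_runs` independent sessions of the same
# procedure at once (posterior columns per run, BLAS matrix products for
# the Psi entropy criterion). Supports posterior-mean estimation and the
# zest placement for any grid, and psi placement when the interest axes
# are the full grid (psi_theta_sigma). With n_runs = 1 it consumes the
# RNG in the same order as run_procedure, so the two paths coincide.
run_procedure_batch <- function(observer, config, n_runs, seed = NULL) {
  stopifnot(inherits(config, "procedure_config"),
            config$estimator == "mean")
  psi <- config$placement == "psi"
  if (psi && !setequal(config$interest, grid_axes(config$grid))) {
    rlang::abort("batch engine supports psi placement only for full-grid interest axes")
  }
  if (!is.null(seed)) set.seed(seed)
  lik <- config_likelihood(config)
  post <- config_prior(config)
  cand <- config$grid$stimuli
  n_cand <- length(cand)
  obs_p <- response_probability(cand, observer)
  theta <- lik$theta
  sigma <- post$points$spread
  n_pts <- post$points$n
  n <- config$n_trials

  P <- matrix(post$mass, n_pts, n_runs)
  theta_hat <- matrix(NA_real_, n, n_runs)
  sigma_hat <- if (config$report_sigma) matrix(NA_real_, n, n_runs) else NULL
  stim <- matrix(NA_real_, n, n_runs)
  resp <- matrix(NA_integer_, n, n_runs)

  for (t in seq_len(n)) {
    if (!psi) {
      est <- as.numeric(crossprod(P, theta))
      idx <- snap_index(est, cand)
    } else {
      lp <- log2(clip_probability(P))
      Plp <- P * lp
      PR1 <- crossprod(lik$L, P)                 # n_cand x n_runs
      CL <- crossprod(lik$L, Plp)
      A1 <- CL + crossprod(lik$Llog2L, P)
      A0 <- matrix(colSums(Plp), n_cand, n_runs, byrow = TRUE) - CL +
        crossprod(lik$Mlog2M, P)
      EH <- -(A1 + A0) + xlog2x(PR1) + xlog2x(1 - PR1)
      idx <- max.col(t(-EH), ties.method = "first")
    }
    u <- stats::runif(n_runs)
    r <- as.integer(u < obs_p[idx])
    Lc <- lik$L[, idx, drop = FALSE]
    wrong <- which(r == 0L)
    if (length(wrong)) Lc[, wrong] <- 1 - Lc[, wrong]
    P <- P * Lc
    P <- P * rep(1 / colSums(P), each = n_pts)
    stim[t, ] <- cand[idx]
    resp[t, ] <- r
    theta_hat[t, ] <- as.numeric(crossprod(P, theta))
    if (config$report_sigma) sigma_hat[t, ] <- as.numeric(crossprod(P, sigma))
  }
  list(theta_hat = theta_hat, sigma_hat = sigma_hat,
       stimulus = stim, response = resp)
}
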