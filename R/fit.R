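# Maximum-likelihood fitting of the logistic psychometric function,
# deviance goodness-of-fit, bootstrap p-value and inclusion criteria.

#' Aggregate a trial-level session into per-level counts
#'
#' @param session A data frame with columns `level` and `response` (and
#'   optionally `practice`), e.g. a [run_updown()] session.
#' @param exclude_practice Drop practice-flagged trials (default `TRUE`).
#'
#' @return A tibble with one row per distinct level, sorted: `level`,
#'   `n` (presented), `k` (correct).
#' @export
aggregate_session <- function(session, exclude_practice = TRUE) {
  stopifnot(is.data.frame(session))
  if (nrow(session) == 0) {
    rlang::abort("empty session", class = "zestsim_empty_data")
  }
  dat <- session
  if (exclude_practice && "practice" %in% names(dat)) {
    dat <- dplyr::filter(dat, !.data$practice)
  }
  dat |>
    dplyr::group_by(level = .data$level) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$response > 0),
                     .groups = "drop") |>
    dplyr::arrange(.data$level)
}

#' Negative log-likelihood of a psychometric fit
#'
#' Binomial log-likelihood of per-level counts under the model
#' parameterized by its threshold at the criterion, spread and lapse
#' (guess fixed by the task). Parameter values outside the constraints
#' `spread > 0`, `0 < lapse < lapse_max` return a large finite penalty
#' rather than an error, so derivative-free searches can probe freely.
#'
#' @param threshold,spread,lapse Candidate parameters (threshold in log10
#'   arcsec).
#' @param data Aggregated data from [aggregate_session()].
#' @param guess Guess rate (fixed).
#' @param criterion Criterion probability defining the threshold.
#' @param lapse_max Upper constraint on the lapse (default 0.06).
#'
#' @return The negative log-likelihood (natural log), up to the constant
#'   binomial coefficient term.
#' @export
negative_log_likelihood <- function(threshold, spread, lapse, data,
                                    guess, criterion = 0.75,
                                    lapse_max = 0.06) {
  if (!is.finite(threshold) || !is.finite(spread) || !is.finite(lapse) ||
      spread <= 0 || lapse <= 0 || lapse >= lapse_max ||
      criterion >= 1 - lapse) {
    return(1e10 + sum(abs(c(threshold, spread, lapse)), na.rm = TRUE))
  }
  psi <- clip_probability(
    model_probability(data$level, threshold, spread, lapse,
                      task_from_guess(guess), criterion))
  -sum(data$k * log(psi) + (data$n - data$k) * log(1 - psi))
}

task_from_guess <- function(guess) {
  if (isTRUE(all.equal(guess, 0.5))) return(task_spec(2))
  if (isTRUE(all.equal(guess, 0.25))) return(task_spec(4))
  structure(list(n_alternatives = NA_integer_, guess = guess),
            class = "task_spec")
}

#' Fit the logistic psychometric function by maximum likelihood
#'
#' Minimizes [negative_log_likelihood()] over (threshold, spread, lapse)
#' with the guess rate fixed by the task, using Nelder-Mead simplex
#' searches ([stats::optim()]) on transformed coordinates (log spread,
#' logit-scaled lapse in `(0, lapse_max)`) from a lattice of starting
#' points; the best final likelihood wins. The threshold is parameterized
#' directly at the criterion probability (default 0.75), so the fitted
#' `theta_hat` needs no post-hoc conversion.
#'
#' @param data Aggregated counts from [aggregate_session()], or a raw
#'   session data frame (aggregated automatically).
#' @param task A [task_spec()] fixing the guess rate.
#' @param criterion Criterion probability (default 0.75).
#' @param lapse_max Upper constraint on the lapse (default 0.06).
#' @param n_boot Bootstrap replicates for the deviance p-value (default
#'   1000; set to 0 to skip).
#' @param seed Optional seed for the bootstrap.
#'
#' @return An object of class `psyfit`: a list with `theta_hat` (log10
#'   arcsec), `sigma_hat`, `lambda_hat`, `guess`, `criterion`, `deviance`,
#'   `p_deviance`, `included`, `logLik`, `data`.
#' @export
fit_ml <- function(data, task, criterion = 0.75, lapse_max = 0.06,
                   n_boot = 1000, seed = NULL) {
  stopifnot(inherits(task, "task_spec"))
  if (!all(c("n", "k") %in% names(data))) data <- aggregate_session(data)
  if (nrow(data) < 3) {
    rlang::abort("need >= 3 distinct levels to fit",
                 class = "zestsim_non_identifiable")
  }
  if (sum(data$k) == 0 || sum(data$k) == sum(data$n)) {
    rlang::abort("degenerate data: all responses identical",
                 class = "zestsim_non_identifiable")
  }
  guess <- task$guess

  to_par <- function(th, sg, lm) c(th, log(sg), stats::qlogis(lm / lapse_max))
  from_par <- function(p) c(p[1], exp(p[2]),
                            lapse_max * stats::plogis(p[3]))
  obj <- function(p) {
    q <- from_par(p)
    negative_log_likelihood(q[1], q[2], q[3], data, guess, criterion,
                            lapse_max)
  }

  # multi-start lattice: 4 threshold x 2 spread starts, 3 lapse starts
  th0 <- stats::quantile(rep(data$level, data$n), c(0.2, 0.4, 0.6, 0.8),
                         names = FALSE)
  starts <- expand.grid(th = unique(th0), sg = c(0.5, 1.5),
                        lm = c(0.001, 0.02, 0.05))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(to_par(starts$th[i], starts$sg[i], starts$lm[i]),
                        obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  est <- from_par(best$par)
  psi_hat <- clip_probability(
    model_probability(data$level, est[1], est[2], est[3], task, criterion))
  dev <- deviance_gof(data, psi_hat)
  out <- structure(
    list(theta_hat = est[1], sigma_hat = est[2], lambda_hat = est[3],
         guess = guess, criterion = criterion, task = task,
         deviance = dev, p_deviance = NA_real_, included = NA,
         logLik = -best$value, fitted = psi_hat, data = data),
    class = "psyfit")
  if (n_boot > 0) {
    out$p_deviance <- p_deviance(data, psi_hat, B = n_boot, seed = seed)
    out$included <- passes_inclusion(out)
  }
  out
}

#' Deviance of a psychometric fit against the saturated model
#'
#' The likelihood-ratio goodness-of-fit statistic
#' \deqn{Dev = 2\sum_j \left[k_j \ln\frac{k_j}{n_j \hat p_j} +
#'   (n_j-k_j)\ln\frac{n_j-k_j}{n_j(1-\hat p_j)}\right]}
#' with the convention \eqn{0 \ln(0/\cdot) = 0}. Zero when the fitted
#' probabilities equal the observed proportions at every level.
#'
#' @param data Aggregated counts (`level`, `n`, `k`).
#' @param fitted Fitted probabilities, one per level (or a `psyfit`, whose
#'   fitted values are used).
#'
#' @return The deviance.
#' @export
deviance_gof <- function(data, fitted) {
  if (inherits(fitted, "psyfit")) fitted <- fitted$fitted
  stopifnot(length(fitted) == nrow(data), all(fitted > 0 & fitted < 1))
  k <- data$k; n <- data$n
  t1 <- ifelse(k > 0, k * log(k / (n * fitted)), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log((n - k) / (n * (1 - fitted))), 0)
  2 * sum(t1 + t2)
}

#' Monte-Carlo p-value for the deviance (parametric bootstrap)
#'
#' Simulates `B` datasets from the fitted probabilities at the same
#' per-level design, computes each simulated dataset's deviance against
#' the same fitted model (no refitting), and returns the fraction of
#' simulated deviances at least as large as the observed one.
#'
#' @param data Aggregated counts (`level`, `n`, `k`).
#' @param fitted Fitted probabilities per level (or a `psyfit`).
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Optional seed.
#'
#' @return The bootstrap p-value.
#' @export
p_deviance <- function(data, fitted, B = 1000, seed = NULL) {
  if (inherits(fitted, "psyfit")) fitted <- fitted$fitted
  if (B < 100) abort_invalid("`B` must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  obs <- deviance_gof(data, fitted)
  n <- data$n
  sim_dev <- vapply(seq_len(B), function(b) {
    kb <- stats::rbinom(length(n), n, fitted)
    deviance_gof(data.frame(level = data$level, n = n, k = kb), fitted)
  }, numeric(1))
  mean(sim_dev >= obs)
}

#' Inclusion rule for fitted sessions
#'
#' A fit is retained when the threshold lies in `[1, 500]` arcsec
#' (`theta_hat` in `[0, log10(500)]` log10 arcsec), the spread in
#' `[0.01, 7]` log10 arcsec, and the deviance p-value exceeds 0.05.
#'
#' @param fit A `psyfit` from [fit_ml()].
#' @return Logical flag.
#' @export
passes_inclusion <- function(fit) {
  stopifnot(inherits(fit, "psyfit"))
  theta_arcsec <- 10^fit$theta_hat
  theta_arcsec >= 1 && theta_arcsec <= 500 &&
    fit$sigma_hat >= 0.01 && fit$sigma_hat <= 7 &&
    !is.na(fit$p_deviance) && fit$p_deviance > 0.05
}

#' @export
print.psyfit <- function(x, ...) {
  cat(sprintf(
    "<psyfit> theta = %.3f log10 arcsec (%.1f arcsec), sigma = %.3f, lambda = %.4f\n",
    x$theta_hat, 10^x$theta_hat, x$sigma_hat, x$lambda_hat))
  cat(sprintf("  deviance = %.3f, p(Dev) = %s, included = %s\n",
              x$deviance,
              if (is.na(x$p_deviance)) "NA" else sprintf("%.3f", x$p_deviance),
              x$included))
  invisible(x)
}

#' Tidy a psychometric fit into a one-row-per-parameter tibble
#'
#' @param x A `psyfit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy psyfit
#' @export
tidy.psyfit <- function(x, ...) {
  tibble::tibble(
    term = c("threshold", "spread", "lapse", "guess"),
    estimate = c(x$theta_hat, x$sigma_hat, x$lambda_hat, x$guess)
  )
}

#' One-row model summary of a psychometric fit
#'
#' @param x A `psyfit`.
#' @param ... Unused.
#' @return A one-row tibble: `theta_hat`, `theta_arcsec`, `sigma_hat`,
#'   `lambda_hat`, `deviance`, `p_deviance`, `included`, `logLik`,
#'   `n_trials`.
#' @method glance psyfit
#' @export
glance.psyfit <- function(x, ...) {
  tibble::tibble(
    theta_hat = x$theta_hat, theta_arcsec = 10^x$theta_hat,
    sigma_hat = x$sigma_hat, lambda_hat = x$lambda_hat,
    deviance = x$deviance, p_deviance = x$p_deviance,
    included = x$included, logLik = x$logLik, n_trials = sum(x$data$n)
  )
}
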