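# Logistic psychometric function, parameter conversions, response simulation.
#
# All intensities, thresholds and spreads are carried in log10 arcsec of
# binocular disparity; linear arcsec appears only at I/O boundaries.

# slope * spread = 2 ln 39: the spread is the intensity interval over which
# the base logistic rises through its central 95% (0.025 -> 0.975).
.spread_slope_const <- 2 * log(39)

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "zestsim_invalid_parameter")
}

#' Task specification for a forced-choice experiment
#'
#' @param n_alternatives Number of response alternatives (2 or 4). The guess
#'   rate is fixed at `1/n_alternatives`.
#'
#' @return An object of class `task_spec` with fields `n_alternatives` and
#'   `guess`.
#' @examples
#' task_spec(4)$guess # 0.25
#' @export
task_spec <- function(n_alternatives) {
  if (!n_alternatives %in% c(2L, 4L)) {
    abort_invalid("`n_alternatives` must be 2 or 4")
  }
  structure(
    list(n_alternatives = as.integer(n_alternatives),
         guess = 1 / n_alternatives),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %dAFC (guess = %.3g)\n", x$n_alternatives, x$guess))
  invisible(x)
}

#' Logistic psychometric model with guess and lapse rates
#'
#' The response probability is
#' \deqn{\Psi(x) = \gamma + (1 - \gamma - \lambda) F(x; \alpha, \beta)}
#' where \eqn{F} is the base logistic [base_logistic()], \eqn{\gamma} the
#' guess rate (lower asymptote) and \eqn{\lambda} the lapse rate (the
#' probability of an incorrect response due to a lapse, so the upper
#' asymptote is \eqn{1 - \lambda}).
#'
#' Exactly one of `spread` or `slope` must be given; they are related by
#' `slope = 2*log(39)/spread` ([spread_to_slope()]).
#'
#' @param location Location \eqn{\alpha} of the base logistic, log10 arcsec.
#' @param spread Spread \eqn{\sigma} (log10 arcsec), the interval over which
#'   the base logistic rises from 0.025 to 0.975.
#' @param slope Slope \eqn{\beta}, per log10 arcsec.
#' @param guess Guess rate \eqn{\gamma} in `[0, 1)`.
#' @param lapse Lapse rate \eqn{\lambda \ge 0}; `guess + lapse` must be < 1.
#'
#' @return An object of class `psychometric_model` with fields `location`,
#'   `slope`, `spread`, `guess`, `lapse`.
#' @examples
#' m <- psychometric_model(location = 1.488, spread = 1, guess = 0.5, lapse = 0.02)
#' response_probability(1.5, m)
#' @export
psychometric_model <- function(location, spread = NULL, slope = NULL,
                               guess = 0.5, lapse = 0) {
  if (is.null(slope) == is.null(spread)) {
    abort_invalid("give exactly one of `spread` or `slope`")
  }
  if (is.null(slope)) slope <- spread_to_slope(spread)
  if (is.null(spread)) spread <- slope_to_spread(slope)
  if (!is.finite(location)) abort_invalid("`location` must be finite")
  if (!is.finite(guess) || guess < 0 || guess >= 1) {
    abort_invalid("`guess` must be in [0, 1)")
  }
  if (!is.finite(lapse) || lapse < 0 || guess + lapse >= 1) {
    abort_invalid("`lapse` must satisfy lapse >= 0 and guess + lapse < 1")
  }
  structure(
    list(location = location, slope = slope, spread = spread,
         guess = guess, lapse = lapse),
    class = "psychometric_model"
  )
}

#' @export
print.psychometric_model <- function(x, ...) {
  cat(sprintf(
    "<psychometric_model> alpha = %.4g, sigma = %.4g (beta = %.4g), gamma = %.3g, lambda = %.3g\n",
    x$location, x$spread, x$slope, x$guess, x$lapse))
  invisible(x)
}

#' Base logistic function
#'
#' `1 / (1 + exp(-slope * (x - location)))`: strictly increasing in `x`,
#' 0.5 at `x = location`.
#'
#' @param x Stimulus intensity, log10 arcsec (vectorized).
#' @param location Location \eqn{\alpha}, log10 arcsec.
#' @param slope Slope \eqn{\beta} > 0, per log10 arcsec.
#'
#' @return Probabilities in (0, 1).
#' @export
base_logistic <- function(x, location, slope) {
  if (!all(is.finite(x))) abort_invalid("`x` must be finite")
  if (!is.finite(location)) abort_invalid("`location` must be finite")
  if (!is.finite(slope) || slope <= 0) abort_invalid("`slope` must be > 0")
  stats::plogis(slope * (x - location))
}

#' Response probability of a psychometric model
#'
#' @param x Stimulus intensity, log10 arcsec (vectorized).
#' @param model A [psychometric_model()] (or a [simulated_observer()], whose
#'   model is used).
#'
#' @return Probability of a correct response, bounded in
#'   `(guess, 1 - lapse)`.
#' @export
response_probability <- function(x, model) {
  if (inherits(model, "simulated_observer")) model <- model$model
  if (!inherits(model, "psychometric_model")) {
    abort_invalid("`model` must be a psychometric_model")
  }
  model$guess + (1 - model$guess - model$lapse) *
    base_logistic(x, model$location, model$slope)
}

#' Convert spread to slope (and back)
#'
#' The spread \eqn{\sigma} is the intensity interval over which the base
#' logistic rises from 0.025 to 0.975, fixing
#' \eqn{\beta \sigma = 2\ln 39 \approx 7.3272}. A spread of 1 log10 arcsec
#' therefore corresponds to a slope of 7.327 per log10 arcsec.
#'
#' @param spread Spread \eqn{\sigma} > 0, log10 arcsec.
#' @param slope Slope \eqn{\beta} > 0, per log10 arcsec.
#'
#' @return The corresponding slope (or spread).
#' @examples
#' spread_to_slope(1)   # 7.327
#' spread_to_slope(1.7) # 4.31
#' @export
spread_to_slope <- function(spread) {
  if (!all(is.finite(spread)) || any(spread <= 0)) {
    abort_invalid("`spread` must be > 0")
  }
  .spread_slope_const / spread
}

#' @rdname spread_to_slope
#' @export
slope_to_spread <- function(slope) {
  if (!all(is.finite(slope)) || any(slope <= 0)) {
    abort_invalid("`slope` must be > 0")
  }
  .spread_slope_const / slope
}

#' Locate the base logistic so that the threshold sits at the criterion
#'
#' Solves for the location \eqn{\alpha} such that the full model's response
#' probability at the threshold equals the criterion \eqn{\pi}:
#' \deqn{\alpha = \theta - \frac{1}{\beta}\ln\frac{F}{1-F}, \quad
#'   F = \frac{\pi - \gamma}{1 - \gamma - \lambda}.}
#'
#' @param threshold Threshold \eqn{\theta}, log10 arcsec.
#' @param slope Slope \eqn{\beta} > 0.
#' @param guess,lapse Guess and lapse rates.
#' @param criterion Criterion probability \eqn{\pi}, strictly between
#'   `guess` and `1 - lapse`.
#'
#' @return Location \eqn{\alpha} in log10 arcsec (or, for
#'   [threshold_from_location()], the threshold).
#' @examples
#' location_from_threshold(1.5, spread_to_slope(1), 0.5, 0.02, 0.75) # ~1.489
#' @export
location_from_threshold <- function(threshold, slope, guess, lapse,
                                    criterion = 0.75) {
  f <- .criterion_fraction(criterion, guess, lapse)
  threshold - log(f / (1 - f)) / slope
}

#' @rdname location_from_threshold
#' @param location Location \eqn{\alpha}, log10 arcsec.
#' @export
threshold_from_location <- function(location, slope, guess, lapse,
                                    criterion = 0.75) {
  f <- .criterion_fraction(criterion, guess, lapse)
  location + log(f / (1 - f)) / slope
}

.criterion_fraction <- function(criterion, guess, lapse) {
  if (any(criterion <= guess) || any(criterion >= 1 - lapse)) {
    rlang::abort(
      "`criterion` must lie strictly between `guess` and `1 - lapse`",
      class = "zestsim_infeasible_criterion")
  }
  (criterion - guess) / (1 - guess - lapse)
}

#' Convert between the lapse rate and the probability of lapsing
#'
#' `lapse_star` is the probability that the observer lapses at all on a
#' trial; a lapse produces an incorrect response only with probability
#' `1 - guess`, so the incorrect-response lapse rate is
#' `lapse = lapse_star * (1 - guess)`.
#'
#' @param lapse_star Probability of lapsing, in `[0, 1]`.
#' @param lapse Lapse rate (probability of an incorrect response due to a
#'   lapse).
#' @param guess Guess rate in `[0, 1)`.
#'
#' @return The lapse rate (or `lapse_star` for the inverse).
#' @examples
#' lapse_from_lapse_star(0.04, 0.5)  # 0.02
#' lapse_from_lapse_star(0.04, 0.25) # 0.03
#' @export
lapse_from_lapse_star <- function(lapse_star, guess) {
  if (!all(is.finite(lapse_star)) || any(lapse_star < 0) || any(lapse_star > 1)) {
    abort_invalid("`lapse_star` must be in [0, 1]")
  }
  .check_guess(guess)
  lapse_star * (1 - guess)
}

#' @rdname lapse_from_lapse_star
#' @export
lapse_star_from_lapse <- function(lapse, guess) {
  .check_guess(guess)
  if (!all(is.finite(lapse)) || any(lapse < 0) || any(lapse > 1 - guess)) {
    abort_invalid("`lapse` must be in [0, 1 - guess]")
  }
  lapse / (1 - guess)
}

.check_guess <- function(guess) {
  if (!all(is.finite(guess)) || any(guess < 0) || any(guess >= 1)) {
    abort_invalid("`guess` must be in [0, 1)")
  }
}

#' Simulated observer
#'
#' A virtual observer defined by a true threshold, spread and lapse rate for
#' a given task. The underlying psychometric model is located so that the
#' response probability at the threshold equals the criterion exactly.
#'
#' @param threshold True threshold \eqn{\theta_S}, log10 arcsec.
#' @param spread True spread \eqn{\sigma_S}, log10 arcsec.
#' @param lapse Lapse rate \eqn{\lambda_S}.
#' @param task A [task_spec()].
#' @param criterion Criterion probability \eqn{\pi} (default 0.75).
#' @param id Observer label.
#'
#' @return An object of class `simulated_observer` with fields `model`,
#'   `threshold`, `criterion`, `task`, `id`.
#' @examples
#' obs <- simulated_observer(1.5, 1, 0.03, task_spec(4))
#' response_probability(1.5, obs) # 0.75
#' @export
simulated_observer <- function(threshold, spread, lapse, task,
                               criterion = 0.75, id = "obs") {
  stopifnot(inherits(task, "task_spec"))
  slope <- spread_to_slope(spread)
  loc <- location_from_threshold(threshold, slope, task$guess, lapse, criterion)
  model <- psychometric_model(location = loc, slope = slope,
                              guess = task$guess, lapse = lapse)
  structure(
    list(model = model, threshold = threshold, criterion = criterion,
         task = task, id = id),
    class = "simulated_observer"
  )
}

#' @export
print.simulated_observer <- function(x, ...) {
  cat(sprintf(
    "<simulated_observer> '%s': theta = %.4g, sigma = %.4g, lambda = %.3g, %dAFC, pi = %.3g\n",
    x$id, x$threshold, x$model$spread, x$model$lapse,
    x$task$n_alternatives, x$criterion))
  invisible(x)
}

#' Simulate binary responses from a psychometric model
#'
#' Draws Bernoulli responses with success probability
#' [response_probability()] at each intensity, using R's global random
#' number generator (set a seed with [set.seed()] for reproducibility).
#'
#' @param model A [psychometric_model()] or [simulated_observer()].
#' @param x Stimulus intensities, log10 arcsec (vectorized).
#'
#' @return Integer vector of 0/1 responses, one per element of `x`.
#' @export
simulate_response <- function(model, x) {
  p <- response_probability(x, model)
  as.integer(stats::runif(length(x)) < p)
}

#' Clip probabilities away from 0 and 1 before taking logs
#'
#' @param p Probabilities.
#' @param eps Clip bound (default 1e-12).
#' @return `pmin(pmax(p, eps), 1 - eps)`.
#' @keywords internal
clip_probability <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}
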