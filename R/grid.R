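# Parameter grids and grid-based posteriors for Bayesian adaptive procedures.

#' Default spread axis for procedures that estimate or marginalize spread
#'
#' 21 linearly spaced values over `[0.01, 7]` log10 arcsec — the validity
#' range for fitted spreads — matching the linear parameter grids of
#' standard adaptive-procedure implementations. Log spacing over the
#' empirically observed range (roughly 0.03 to 3.5 log10 arcsec) is
#' available as an alternative.
#'
#' @param n Number of values.
#' @param range Length-2 range in log10 arcsec.
#' @param spacing `"linear"` or `"log"`.
#' @return Numeric vector of spreads.
#' @export
default_spread_axis <- function(n = 21, range = c(0.01, 7),
                                spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (spacing == "linear") {
    seq(range[1], range[2], length.out = n)
  } else {
    exp(seq(log(range[1]), log(range[2]), length.out = n))
  }
}

#' Hypothesis grid for Bayesian adaptive procedures
#'
#' @param threshold Strictly increasing threshold axis, log10 arcsec
#'   (default `seq(0, 3, 0.01)`).
#' @param spread Strictly increasing spread axis (log10 arcsec), or `NULL`
#'   for fixed-spread procedures.
#' @param lapse Strictly increasing lapse axis (probabilities), or `NULL`
#'   when the lapse is fixed.
#' @param stimuli Ordered stimulus candidates, log10 arcsec; defaults to
#'   the threshold axis. Must lie within its range.
#'
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(threshold = seq(0, 3, by = 0.01),
                           spread = NULL, lapse = NULL, stimuli = threshold) {
  chk_axis <- function(v, nm) {
    if (!is.null(v) && (any(!is.finite(v)) || is.unsorted(v, strictly = TRUE))) {
      abort_invalid(sprintf("`%s` axis must be strictly increasing", nm))
    }
  }
  chk_axis(threshold, "threshold"); chk_axis(spread, "spread")
  chk_axis(lapse, "lapse"); chk_axis(stimuli, "stimuli")
  if (min(stimuli) < min(threshold) || max(stimuli) > max(threshold)) {
    abort_invalid("`stimuli` must lie within the threshold-axis range")
  }
  structure(
    list(threshold = threshold, spread = spread, lapse = lapse,
         stimuli = stimuli),
    class = "parameter_grid"
  )
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("<parameter_grid> theta: %d, sigma: %s, lambda: %s, stimuli: %d\n",
              length(x$threshold),
              if (is.null(x$spread)) "fixed" else length(x$spread),
              if (is.null(x$lapse)) "fixed" else length(x$lapse),
              length(x$stimuli)))
  invisible(x)
}

grid_axes <- function(grid) {
  axes <- c("threshold", "spread", "lapse")
  axes[!vapply(grid[axes], is.null, logical(1))]
}

# Expand the grid into hypothesis points (threshold varying fastest, then
# spread, then lapse). Fixed values substitute for absent axes.
grid_points <- function(grid, spread_fixed = NULL, lapse_fixed = NULL) {
  th <- grid$threshold
  sg <- if (is.null(grid$spread)) spread_fixed else grid$spread
  lp <- if (is.null(grid$lapse)) lapse_fixed else grid$lapse
  if (is.null(sg)) abort_invalid("no spread axis and no fixed spread given")
  if (is.null(lp)) abort_invalid("no lapse axis and no fixed lapse given")
  n_t <- length(th); n_s <- length(sg); n_l <- length(lp)
  list(
    threshold = rep(th, times = n_s * n_l),
    spread = rep(rep(sg, each = n_t), times = n_l),
    lapse = rep(lp, each = n_t * n_s),
    n = n_t * n_s * n_l
  )
}

#' Response probability of a grid hypothesis
#'
#' The hypothesis is parameterized by its threshold directly: the location
#' of the base logistic is derived via [location_from_threshold()] so that
#' every hypothesis satisfies `response_probability(threshold) = criterion`
#' exactly.
#'
#' @param x Stimulus intensity, log10 arcsec.
#' @param threshold,spread,lapse Hypothesis parameters (vectorized together).
#' @param task A [task_spec()].
#' @param criterion Criterion probability (default 0.75).
#'
#' @return Probability of a correct response.
#' @export
model_probability <- function(x, threshold, spread, lapse, task,
                              criterion = 0.75) {
  stopifnot(inherits(task, "task_spec"))
  slope <- spread_to_slope(spread)
  loc <- location_from_threshold(threshold, slope, task$guess, lapse, criterion)
  task$guess + (1 - task$guess - lapse) * stats::plogis(slope * (x - loc))
}

# Offset between the location of the base logistic and the threshold at
# the criterion: theta = location + log(F/(1-F)) / slope.
location_offset <- function(slope, guess, lapse, criterion) {
  f <- .criterion_fraction(criterion, guess, lapse)
  log(f / (1 - f)) / slope
}

# Likelihood table over hypothesis points x stimulus candidates, with the
# xlog2x tables cached for entropy computations. Probabilities are clipped
# to [1e-12, 1 - 1e-12]. The first grid axis is read as the threshold at
# the criterion ("threshold" parameterization, every hypothesis satisfying
# Psi(theta) = criterion) or as the location of the base logistic
# ("location", the parameterization of the published Psi family); `theta`
# holds each hypothesis's threshold either way.
likelihood_table <- function(grid, task, criterion,
                             spread_fixed = NULL, lapse_fixed = NULL,
                             parameterization = c("threshold", "location")) {
  parameterization <- match.arg(parameterization)
  pts <- grid_points(grid, spread_fixed, lapse_fixed)
  slope <- spread_to_slope(pts$spread)
  off <- location_offset(slope, task$guess, pts$lapse, criterion)
  if (parameterization == "threshold") {
    loc <- pts$threshold - off
    theta <- pts$threshold
  } else {
    loc <- pts$threshold
    theta <- pts$threshold + off
  }
  x <- grid$stimuli
  # eta[i, c] = slope_i * (x_c - loc_i)
  eta <- tcrossprod(slope, x) - slope * loc
  scale <- 1 - task$guess - pts$lapse
  L <- task$guess + scale * stats::plogis(eta)
  L <- clip_probability(L)
  # xlog2x tables: sum_i p_i (L log2 L) etc. appear in the expected-entropy
  # decomposition sum w log2 w = sum pL(log2 p + log2 L)
  M <- 1 - L
  list(points = pts, theta = theta, stimuli = x, L = L,
       Llog2L = L * log2(L), Mlog2M = M * log2(M))
}

#' Initialize a grid posterior
#'
#' The threshold prior is always uniform (non-informative). The spread
#' prior is either uniform or a Gaussian evaluated at the spread-axis
#' values and renormalized over the grid; priors are independent across
#' axes. The lapse prior (when a lapse axis is present) is uniform.
#'
#' @param grid A [parameter_grid()].
#' @param task A [task_spec()] (defines the guess rate of every hypothesis).
#' @param spread_prior `"uniform"` or [gaussian_prior()].
#' @param criterion Criterion probability pinning each hypothesis threshold.
#' @param spread_fixed Fixed spread when the grid has no spread axis.
#' @param lapse_fixed Fixed lapse when the grid has no lapse axis.
#' @param parameterization Whether the first grid axis is the threshold at
#'   the criterion (`"threshold"`, every hypothesis satisfying
#'   `Psi(theta) = criterion`) or the location of the base logistic
#'   (`"location"`, the parameterization of the published Psi family).
#'
#' @return An object of class `psy_posterior`: the grid, the hypothesis
#'   points, and a normalized mass vector.
#' @export
init_prior <- function(grid, task, spread_prior = "uniform",
                       criterion = 0.75, spread_fixed = NULL,
                       lapse_fixed = NULL,
                       parameterization = c("threshold", "location")) {
  stopifnot(inherits(grid, "parameter_grid"), inherits(task, "task_spec"))
  parameterization <- match.arg(parameterization)
  pts <- grid_points(grid, spread_fixed, lapse_fixed)
  mass <- rep(1, pts$n)
  if (!identical(spread_prior, "uniform")) {
    if (!inherits(spread_prior, "gaussian_prior")) {
      abort_invalid("`spread_prior` must be \"uniform\" or gaussian_prior()")
    }
    if (is.null(grid$spread)) {
      abort_invalid("a spread prior needs a spread axis in the grid")
    }
    mass <- mass * stats::dnorm(pts$spread, spread_prior$mean, spread_prior$sd)
  }
  mass <- mass / sum(mass)
  structure(
    list(grid = grid, points = pts, mass = mass, task = task,
         criterion = criterion, parameterization = parameterization),
    class = "psy_posterior"
  )
}

#' Gaussian prior specification for the spread axis
#'
#' @param mean,sd Mean and standard deviation in log10 arcsec; `sd > 0`.
#' @return An object of class `gaussian_prior`.
#' @export
gaussian_prior <- function(mean, sd) {
  if (!is.finite(sd) || sd <= 0) abort_invalid("`sd` must be > 0")
  structure(list(mean = mean, sd = sd), class = "gaussian_prior")
}

#' @export
print.psy_posterior <- function(x, ...) {
  axes <- grid_axes(x$grid)
  cat(sprintf("<psy_posterior> %d hypotheses over (%s); mean %s = %.4g\n",
              x$points$n, paste(axes, collapse = ", "), axes[1],
              posterior_mean(x, axes[1])))
  invisible(x)
}

# Likelihood of a response at intensity x under every hypothesis,
# respecting the posterior's grid parameterization.
point_likelihood <- function(posterior, x, response) {
  pts <- posterior$points
  slope <- spread_to_slope(pts$spread)
  loc <- if (identical(posterior$parameterization, "location")) {
    pts$threshold
  } else {
    pts$threshold - location_offset(slope, posterior$task$guess, pts$lapse,
                                    posterior$criterion)
  }
  p <- posterior$task$guess + (1 - posterior$task$guess - pts$lapse) *
    stats::plogis(slope * (x - loc))
  p <- clip_probability(p)
  if (response > 0) p else 1 - p
}

#' Bayes-update a grid posterior with one trial
#'
#' Multiplies the mass by the per-hypothesis likelihood of the observed
#' response at intensity `x` and renormalizes. Updates commute: a batch of
#' trials gives the same posterior in any order.
#'
#' @param posterior A `psy_posterior` from [init_prior()].
#' @param x Stimulus intensity, log10 arcsec.
#' @param response 1 (correct) or 0 (incorrect).
#'
#' @return The updated `psy_posterior`.
#' @export
update_posterior <- function(posterior, x, response) {
  stopifnot(inherits(posterior, "psy_posterior"))
  mass <- posterior$mass * point_likelihood(posterior, x, response)
  tot <- sum(mass)
  if (!is.finite(tot) || tot <= 0) {
    rlang::abort("posterior mass degenerated to zero",
                 class = "zestsim_degenerate_posterior")
  }
  posterior$mass <- mass / tot
  posterior
}

axis_index <- function(posterior, axis) {
  if (!axis %in% grid_axes(posterior$grid)) {
    rlang::abort(sprintf("posterior has no `%s` axis", axis),
                 class = "zestsim_invalid_request")
  }
  match(posterior$points[[axis]], posterior$grid[[axis]])
}

#' Marginal posterior over one axis
#'
#' Sums the mass over all other (nuisance) axes; normalization is
#' preserved.
#'
#' @param posterior A `psy_posterior`.
#' @param axis `"threshold"`, `"spread"` or `"lapse"`.
#'
#' @return A single-axis `psy_posterior` over `axis`.
#' @export
marginal <- function(posterior, axis = "threshold") {
  idx <- axis_index(posterior, axis)
  vals <- posterior$grid[[axis]]
  m <- as.numeric(rowsum(posterior$mass, idx))
  n <- length(vals)
  grid <- structure(list(threshold = NULL, spread = NULL, lapse = NULL,
                         stimuli = posterior$grid$stimuli),
                    class = "parameter_grid")
  grid[[axis]] <- vals
  pts <- list(threshold = rep(NA_real_, n), spread = rep(NA_real_, n),
              lapse = rep(NA_real_, n), n = n)
  pts[[axis]] <- vals
  structure(
    list(grid = grid, points = pts, mass = m, task = posterior$task,
         criterion = posterior$criterion),
    class = "psy_posterior"
  )
}

#' Posterior mean along one axis
#'
#' @param posterior A `psy_posterior`.
#' @param axis Axis of interest (default `"threshold"`).
#' @return The mass-weighted mean of the axis values.
#' @export
posterior_mean <- function(posterior, axis = "threshold") {
  if (!axis %in% grid_axes(posterior$grid)) {
    rlang::abort(sprintf("posterior has no `%s` axis", axis),
                 class = "zestsim_invalid_request")
  }
  sum(posterior$mass * posterior$points[[axis]])
}

#' Posterior mode along one axis (ties broken toward the smaller value)
#'
#' @inheritParams posterior_mean
#' @return The axis value with the largest marginal mass.
#' @export
posterior_mode <- function(posterior, axis = "threshold") {
  idx <- axis_index(posterior, axis)
  vals <- posterior$grid[[axis]]
  m <- as.numeric(rowsum(posterior$mass, idx))
  vals[which.max(m)]
}

#' Turn a posterior into a tibble
#'
#' @param x A `psy_posterior`.
#' @param ... Unused.
#' @return A tibble with one row per hypothesis and columns `threshold`,
#'   `spread`, `lapse`, `mass`.
#' @method tidy psy_posterior
#' @export
tidy.psy_posterior <- function(x, ...) {
  tibble::tibble(
    threshold = x$points$threshold,
    spread = x$points$spread,
    lapse = x$points$lapse,
    mass = x$mass
  )
}
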