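# Virtual-observer populations: built-in per-experiment profiles, sampling,
# and ingest of real per-subject tables.

#' Built-in population profiles for the three stereoacuity experiments
#'
#' Each profile carries the per-experiment population statistics (means and
#' SDs of log10 thresholds, spreads and the probability of lapsing
#' `lapse_star`), the task, truncation ranges, and — for the 4AFC
#' experiments, where spread and threshold correlate — the
#' spread-on-threshold regression used to couple the two.
#'
#' * `exp1_2AFC_g`: global stereopsis, 2AFC, n = 71; threshold
#'   1.528 +/- 0.3, spread 1.005 +/- 0.776, lapse_star 0.0207 +/- 0.042.
#' * `exp2_4AFC_g`: global stereopsis, 4AFC, n = 68; threshold
#'   1.54 +/- 0.203, spread 1.186 +/- 0.74, lapse_star 0.0308 +/- 0.0361,
#'   regression sigma = -0.823 + 1.305 theta.
#' * `exp3_4AFC_l`: local stereopsis, 4AFC, n = 76; threshold
#'   1.568 +/- 0.23, spread 1.306 +/- 0.632, lapse_star 0.0276 +/- 0.036,
#'   regression sigma = -0.159 + 0.934 theta.
#'
#' @param name Profile name.
#' @return An object of class `population_profile`.
#' @export
builtin_profile <- function(name = c("exp1_2AFC_g", "exp2_4AFC_g",
                                     "exp3_4AFC_l")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    rlang::abort(sprintf("unknown profile '%s'", name[1]),
                 class = "zestsim_invalid_request")
  })
  spec <- switch(name,
    exp1_2AFC_g = list(n = 71L, task = task_spec(2),
                       threshold = c(1.528, 0.3), spread = c(1.005, 0.776),
                       lapse_star = c(0.0207, 0.042), regression = NULL),
    exp2_4AFC_g = list(n = 68L, task = task_spec(4),
                       threshold = c(1.54, 0.203), spread = c(1.186, 0.74),
                       lapse_star = c(0.0308, 0.0361),
                       regression = c(intercept = -0.823, slope = 1.305)),
    exp3_4AFC_l = list(n = 76L, task = task_spec(4),
                       threshold = c(1.568, 0.23), spread = c(1.306, 0.632),
                       lapse_star = c(0.0276, 0.036),
                       regression = c(intercept = -0.159, slope = 0.934)))
  structure(
    c(list(name = name), spec,
      list(threshold_range = c(0, log10(500)),
           spread_range = c(0.01, 7),
           lapse_star_range = c(0, 0.08))),
    class = "population_profile"
  )
}

#' @export
print.population_profile <- function(x, ...) {
  cat(sprintf(
    "<population_profile> %s (n = %d, %dAFC): theta %.3f+/-%.3f, sigma %.3f+/-%.3f, lapse* %.4f+/-%.4f\n",
    x$name, x$n, x$task$n_alternatives,
    x$threshold[1], x$threshold[2], x$spread[1], x$spread[2],
    x$lapse_star[1], x$lapse_star[2]))
  invisible(x)
}

# Inverse-CDF sampling from a normal truncated to [a, b] (vectorized over
# the mean).
rtruncnorm <- function(n, mean, sd, a, b) {
  if (all(sd == 0)) return(rep(pmin(pmax(mean, a), b), length.out = n))
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  if (any(hi <= lo)) {
    rlang::abort("truncation range has no mass under the profile",
                 class = "zestsim_invalid_profile")
  }
  stats::qnorm(lo + (hi - lo) * stats::runif(n), mean, sd)
}

# Mean and SD of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Parent (mu, sigma) whose truncation to [a, b] has the target mean and SD.
# When the target SD exceeds what the truncation range permits, the solver
# returns the closest attainable parameters (mean matched first).
solve_truncnorm <- function(target_mean, target_sd, a, b) {
  scale <- max(target_sd, 1e-3)
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), a, b)
    1e4 * ((mm["mean"] - target_mean) / scale)^2 +
      ((mm["sd"] - target_sd) / scale)^2
  }
  fit <- stats::optim(c(target_mean, log(scale)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Calibrate the spread-on-threshold regression intercept and residual SD so
# the truncated marginal spread moments match the profile. The printed
# slope is kept; the intercept absorbs the truncation shift. The threshold
# distribution is integrated over a quantile grid of its (already
# calibrated) truncated parent.
solve_regression <- function(profile, theta_parent) {
  b <- profile$regression[["slope"]]
  rng <- profile$spread_range
  pr <- (seq_len(201) - 0.5) / 201
  lo <- stats::pnorm(profile$threshold_range[1], theta_parent$mu, theta_parent$sigma)
  hi <- stats::pnorm(profile$threshold_range[2], theta_parent$mu, theta_parent$sigma)
  th_q <- stats::qnorm(lo + (hi - lo) * pr, theta_parent$mu, theta_parent$sigma)
  scale <- max(profile$spread[2], 1e-3)
  obj <- function(p) {
    mm <- truncnorm_moments(p[1] + b * th_q, exp(p[2]), rng[1], rng[2])
    cm <- mm[seq_along(th_q)]
    cs <- mm[-seq_along(th_q)]
    marg_mean <- mean(cm)
    marg_sd <- sqrt(mean(cs^2) + mean((cm - marg_mean)^2))
    1e4 * ((marg_mean - profile$spread[1]) / scale)^2 +
      ((marg_sd - profile$spread[2]) / scale)^2
  }
  start_s <- sqrt(max(profile$spread[2]^2 - b^2 * profile$threshold[2]^2,
                      1e-4))
  fit <- stats::optim(c(profile$regression[["intercept"]], log(start_s)),
                      obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(intercept = fit$par[1], resid_sd = exp(fit$par[2]))
}

#' Sample a virtual-observer population from a profile
#'
#' Thresholds and `lapse_star` values are drawn from truncated normals
#' whose parent parameters are solved numerically so that the moments
#' *after* truncation match the profile's printed mean and SD (plain
#' truncation at the printed moments would inflate the means). Where the
#' profile has a spread-on-threshold regression (the 4AFC experiments),
#' spreads are generated as `sigma = a' + b * theta + e` keeping the
#' printed slope `b`, with the intercept and residual SD calibrated so the
#' truncated marginal spread moments match the profile; otherwise spreads
#' are sampled independently from a calibrated truncated normal. When a
#' printed SD exceeds what the truncation range permits (the `lapse_star`
#' SD does), the closest attainable SD is used with the mean matched
#' first. Lapse rates are derived from `lapse_star` through the task's
#' guess rate, never sampled directly.
#'
#' @param profile A [builtin_profile()] (or compatible list).
#' @param n Number of observers (default: the profile's n).
#' @param seed Optional seed.
#'
#' @return An observer table: a tibble with columns `id`, `threshold`,
#'   `spread`, `lapse`, `lapse_star`, `task` (2 or 4), and attribute
#'   `profile`.
#' @export
sample_population <- function(profile, n = profile$n, seed = NULL) {
  stopifnot(inherits(profile, "population_profile"))
  if (n < 1) abort_invalid("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  th_parent <- solve_truncnorm(profile$threshold[1], profile$threshold[2],
                               profile$threshold_range[1],
                               profile$threshold_range[2])
  th <- rtruncnorm(n, th_parent$mu, th_parent$sigma,
                   profile$threshold_range[1], profile$threshold_range[2])
  if (is.null(profile$regression)) {
    sg_parent <- solve_truncnorm(profile$spread[1], profile$spread[2],
                                 profile$spread_range[1],
                                 profile$spread_range[2])
    sg <- rtruncnorm(n, sg_parent$mu, sg_parent$sigma,
                     profile$spread_range[1], profile$spread_range[2])
  } else {
    reg <- solve_regression(profile, th_parent)
    sg <- rtruncnorm(n, reg$intercept + profile$regression[["slope"]] * th,
                     reg$resid_sd,
                     profile$spread_range[1], profile$spread_range[2])
  }
  ls_parent <- solve_truncnorm(profile$lapse_star[1], profile$lapse_star[2],
                               profile$lapse_star_range[1],
                               profile$lapse_star_range[2])
  ls <- rtruncnorm(n, ls_parent$mu, ls_parent$sigma,
                   profile$lapse_star_range[1], profile$lapse_star_range[2])
  out <- tibble::tibble(
    id = sprintf("%s_%03d", profile$name, seq_len(n)),
    threshold = th, spread = sg,
    lapse = lapse_from_lapse_star(ls, profile$task$guess),
    lapse_star = ls,
    task = profile$task$n_alternatives
  )
  structure(out, class = c("observer_table", class(out)), profile = profile)
}

#' Turn observer-table rows into simulated observers
#'
#' @param observers An observer table (tibble with `threshold`, `spread`,
#'   `lapse`, `task`, and optionally `id` columns).
#' @param criterion Criterion probability (default 0.75).
#' @return A list of [simulated_observer()] objects.
#' @export
as_observer_list <- function(observers, criterion = 0.75) {
  purrr::pmap(
    list(observers$threshold, observers$spread, observers$lapse,
         observers$task,
         observers$id %||% as.character(seq_len(nrow(observers)))),
    function(th, sg, lm, tk, id) {
      simulated_observer(th, sg, lm, task_spec(tk), criterion, id)
    })
}

#' Load a per-subject parameter table from CSV or XLSX
#'
#' Schema-tolerant reader for per-participant fitted parameters. Column
#' names are matched case-insensitively: the id column may be named
#' `id`/`subject`/`participant`; the threshold `threshold`/`theta`
#' (log10 arcsec) or `theta_arcsec` (converted); the spread
#' `spread`/`sigma`; the lapse `lapse`/`lambda`; the task
#' `task`/`n_alternatives` (or supplied via `task`). Rows outside the
#' valid parameter ranges (threshold in `[1, 500]` arcsec, spread in
#' `[0.01, 7]`) are dropped; the number dropped is reported in attribute
#' `n_dropped` and as a message.
#'
#' @param path CSV or XLSX file path.
#' @param task Optional task (2 or 4) when the file has no task column.
#'
#' @return An observer table tibble (`id`, `threshold`, `spread`, `lapse`,
#'   `lapse_star`, `task`).
#' @export
load_subject_table <- function(path, task = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      rlang::abort("reading XLSX requires the readxl package",
                   class = "zestsim_format_error")
    }
    readxl::read_excel(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, comment = "#")
  }
  if (nrow(raw) == 0) {
    rlang::abort("empty subject table", class = "zestsim_format_error")
  }
  nm <- tolower(names(raw))
  pick <- function(...) {
    i <- which(nm %in% c(...))
    if (length(i)) raw[[i[1]]] else NULL
  }
  theta <- pick("threshold", "theta", "theta_log10", "theta_log10_arcsec")
  if (is.null(theta)) {
    ta <- pick("theta_arcsec", "threshold_arcsec")
    if (!is.null(ta)) theta <- log10(ta)
  }
  spread <- pick("spread", "sigma")
  lapse <- pick("lapse", "lambda")
  if (is.null(theta) || is.null(spread) || is.null(lapse)) {
    rlang::abort("subject table needs threshold, spread and lapse columns",
                 class = "zestsim_format_error")
  }
  tk <- pick("task", "n_alternatives")
  if (is.null(tk)) {
    if (is.null(task)) {
      rlang::abort("no task column; supply `task`",
                   class = "zestsim_format_error")
    }
    tk <- rep(task, nrow(raw))
  }
  id <- pick("id", "subject", "participant")
  if (is.null(id)) id <- sprintf("s%03d", seq_len(nrow(raw)))
  out <- tibble::tibble(
    id = as.character(id), threshold = as.numeric(theta),
    spread = as.numeric(spread), lapse = as.numeric(lapse),
    task = as.integer(tk)
  )
  keep <- out$threshold >= 0 & out$threshold <= log10(500) &
    out$spread >= 0.01 & out$spread <= 7 &
    out$lapse >= 0 & out$lapse < 1 - 1 / out$task
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("load_subject_table: dropped %d row(s) outside valid ranges",
                    n_dropped))
  }
  out <- out[keep, ]
  out$lapse_star <- lapse_star_from_lapse(out$lapse, 1 / out$task)
  out <- out[, c("id", "threshold", "spread", "lapse", "lapse_star", "task")]
  structure(out, class = c("observer_table", class(out)),
            n_dropped = n_dropped)
}

#' Simulate staircase sessions for one observer
#'
#' Runs `n_sessions` independent weighted up/down staircases against the
#' observer (a fixture generator for fitting pipelines).
#'
#' @param observer A [simulated_observer()].
#' @param config A [staircase_config()].
#' @param n_sessions Number of sessions.
#' @param seed Optional seed.
#' @return A list of `staircase_session` tibbles.
#' @export
sample_sessions <- function(observer, config = staircase_config(),
                            n_sessions, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map(seq_len(n_sessions), function(i) run_updown(observer, config))
}
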