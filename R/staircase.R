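# Weighted one-up/one-down staircase and its simulation runner.

#' Configuration of the weighted one-up/one-down staircase
#'
#' Defaults follow the stereoacuity sessions this package models: a practice
#' trial at 3 log10 arcsec (1000 arcsec), steps of -0.15 after a correct and
#' +0.45 after an incorrect response (a 1:3 weighting that converges on the
#' 75%-correct level), and a fixed trial count.
#'
#' @param start_level First-trial intensity, log10 arcsec.
#' @param step_down Decrement after a correct response (> 0), log10 arcsec.
#' @param step_up Increment after an incorrect response (> 0), log10 arcsec.
#' @param n_trials Number of trials (>= 1).
#' @param practice_first_trial Flag trial 1 as a cued practice trial.
#' @param level_bounds Length-2 ordered clamp range for levels, log10 arcsec.
#'
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start_level = 3, step_down = 0.15,
                             step_up = 0.45, n_trials = 80,
                             practice_first_trial = TRUE,
                             level_bounds = c(0, 3)) {
  if (!is.finite(step_down) || step_down <= 0) abort_invalid("`step_down` must be > 0")
  if (!is.finite(step_up) || step_up <= 0) abort_invalid("`step_up` must be > 0")
  if (!is.finite(n_trials) || n_trials < 1) {
    rlang::abort("`n_trials` must be >= 1", class = "zestsim_invalid_config")
  }
  if (length(level_bounds) != 2 || diff(level_bounds) <= 0) {
    abort_invalid("`level_bounds` must be an ordered pair")
  }
  structure(
    list(start_level = start_level, step_down = step_down, step_up = step_up,
         n_trials = as.integer(n_trials),
         practice_first_trial = isTRUE(practice_first_trial),
         level_bounds = level_bounds),
    class = "staircase_config"
  )
}

#' Next staircase level given the current level and response
#'
#' Correct: `level - step_down`; incorrect: `level + step_up`; the result is
#' clamped to `config$level_bounds` (no reflection).
#'
#' @param level Current intensity, log10 arcsec.
#' @param response 1 (correct) or 0 (incorrect); vectorized with `level`.
#' @param config A [staircase_config()].
#'
#' @return The next intensity, log10 arcsec.
#' @examples
#' cfg <- staircase_config()
#' next_level(2, 1, cfg) # 1.85
#' next_level(2, 0, cfg) # 2.45
#' @export
next_level <- function(level, response, config) {
  nxt <- ifelse(response > 0, level - config$step_down, level + config$step_up)
  pmin(pmax(nxt, config$level_bounds[1]), config$level_bounds[2])
}

#' Equilibrium probability of a weighted up/down staircase
#'
#' The correct-response probability at which the expected level change is
#' zero: `step_up / (step_up + step_down)`. With the default 0.15/0.45
#' steps this is 0.75, matching the criterion the sessions target.
#'
#' @param config A [staircase_config()].
#' @return A probability.
#' @export
equilibrium_probability <- function(config) {
  config$step_up / (config$step_up + config$step_down)
}

#' Run a weighted up/down staircase against a simulated observer
#'
#' Trial 1 is presented at `start_level`; when
#' `config$practice_first_trial` is set it is flagged as practice and the
#' observer responds correctly with probability
#' `max(response_probability(start_level), 0.95)` (the practice trial
#' carries a non-stereo cue that makes it nearly trivially correct).
#' Each later level follows [next_level()]; responses are Bernoulli draws
#' from the observer's psychometric function. Fixed trial count, no
#' dynamic termination.
#'
#' @param observer A [simulated_observer()].
#' @param config A [staircase_config()].
#' @param seed Optional integer seed (sets the global RNG).
#' @param responses Optional replay vector of 0/1 responses of length
#'   `n_trials`; when given, no random draws are made and the level
#'   trajectory is deterministic.
#'
#' @return A tibble of class `staircase_session` with columns `trial`,
#'   `level`, `response`, `practice`, and attributes `task`, `config`,
#'   `observer_id`.
#' @export
run_updown <- function(observer, config = staircase_config(), seed = NULL,
                       responses = NULL) {
  stopifnot(inherits(observer, "simulated_observer"),
            inherits(config, "staircase_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  replay <- !is.null(responses)
  if (replay && length(responses) != n) {
    rlang::abort("`responses` must have length `n_trials`",
                 class = "zestsim_invalid_config")
  }
  level <- numeric(n)
  resp <- integer(n)
  lv <- config$start_level
  u <- if (replay) numeric(n) else stats::runif(n)
  for (i in seq_len(n)) {
    level[i] <- lv
    if (replay) {
      resp[i] <- as.integer(responses[i] > 0)
    } else {
      p <- response_probability(lv, observer)
      if (i == 1L && config$practice_first_trial) p <- max(p, 0.95)
      resp[i] <- as.integer(u[i] < p)
    }
    lv <- next_level(lv, resp[i], config)
  }
  out <- tibble::tibble(
    trial = seq_len(n),
    level = level,
    response = resp,
    practice = c(config$practice_first_trial, rep(FALSE, n - 1L))
  )
  structure(out,
            class = c("staircase_session", class(out)),
            task = observer$task, config = config, observer_id = observer$id)
}
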