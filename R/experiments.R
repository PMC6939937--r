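# Monte-Carlo engines: spread-mismatch bias surfaces, the percentile sweep
# with the |bias x SD| optimality criterion, and the procedure comparison.

#' Convert a mean log10 threshold bias to a multiplicative factor
#'
#' A mean bias of `b` log10 arcsec corresponds to thresholds over- (or
#' under-) estimated by a factor `10^b`: a bias of 0.1614 turns a true
#' threshold of 100 arcsec into an estimate near 145 arcsec.
#'
#' @param mean_bias Mean bias in log10 arcsec.
#' @return `10^mean_bias`.
#' @export
bias_factor <- function(mean_bias) {
  stopifnot(all(is.finite(mean_bias)))
  10^mean_bias
}

# Run n_sims sessions of `config` against one observer, returning the
# trials x runs matrix of threshold estimates. Uses the vectorized batch
# engine where it applies, otherwise loops single runs.
run_many <- function(observer, config, n_sims, seed = NULL) {
  batchable <- config$estimator == "mean" &&
    (config$placement == "zest" ||
       setequal(config$interest, grid_axes(config$grid)))
  if (batchable) {
    run_procedure_batch(observer, config, n_sims, seed)$theta_hat
  } else {
    if (!is.null(seed)) set.seed(seed)
    vapply(seq_len(n_sims),
           function(i) run_procedure(observer, config)$theta_hat,
           numeric(config$n_trials))
  }
}

#' Threshold bias of fixed-spread ZEST over a population of observers
#'
#' For each observer, runs `n_sims` fixed-spread ZEST staircases with the
#' assumed spread `model_spread`, the assumed lapse equal to the
#' observer's own (`lapse_mode = "subject"`) or to a fixed `model_lapse`,
#' and records the final threshold estimate. The bias of a run is the
#' final estimate minus the observer's true threshold. The summary mean
#' bias is the unweighted average of per-observer mean biases; the SD is
#' taken over the pooled per-run bias distribution.
#'
#' @param observers An observer table (see [sample_population()] /
#'   [load_subject_table()]); all rows must share one task.
#' @param model_spread Assumed spread of the model function, log10 arcsec.
#' @param lapse_mode `"subject"` or `"fixed"`.
#' @param model_lapse Fixed assumed lapse (required when
#'   `lapse_mode = "fixed"`).
#' @param n_sims Simulated staircases per observer (default 2000).
#' @param n_trials Trials per staircase (default 30).
#' @param criterion Criterion probability (default 0.75).
#' @param grid Optional [parameter_grid()] override (threshold axis only).
#' @param seed Optional seed.
#'
#' @return A one-row tibble of class `bias_summary`: `sigma_m`,
#'   `lapse_mode`, `n_trials`, `mean_bias`, `sd_bias`, `bias_factor`,
#'   `n_observers`, `n_sims`, `n_runs`; per-observer means and SDs are in
#'   attribute `per_observer`.
#' @export
bias_for_spread <- function(observers, model_spread,
                            lapse_mode = c("subject", "fixed"),
                            model_lapse = NULL, n_sims = 2000, n_trials = 30,
                            criterion = 0.75, grid = NULL, seed = NULL) {
  lapse_mode <- match.arg(lapse_mode)
  if (lapse_mode == "fixed" && is.null(model_lapse)) {
    abort_invalid("`model_lapse` is required when lapse_mode = \"fixed\"")
  }
  task_n <- unique(observers$task)
  if (length(task_n) != 1) abort_invalid("observers must share a single task")
  task <- task_spec(task_n)
  if (!is.null(seed)) set.seed(seed)

  obs_list <- as_observer_list(observers, criterion)
  per <- purrr::map2_dfr(obs_list, seq_along(obs_list), function(obs, i) {
    lm <- if (lapse_mode == "subject") obs$model$lapse else model_lapse
    cfg <- procedure_config("zest_fixed_sigma", task, n_trials = n_trials,
                            criterion = criterion, model_spread = model_spread,
                            model_lapse = lm, grid = grid)
    th <- run_many(obs, cfg, n_sims)
    bias <- th[n_trials, ] - obs$threshold
    tibble::tibble(id = obs$id, mean_bias = mean(bias), sd_bias = stats::sd(bias),
                   sum_sq = sum((bias - mean(bias))^2), m2 = sum(bias^2),
                   s1 = sum(bias))
  })
  pooled <- unlist_pooled_sd(per, n_sims)
  out <- tibble::tibble(
    sigma_m = model_spread, lapse_mode = lapse_mode,
    n_trials = as.integer(n_trials),
    mean_bias = mean(per$mean_bias), sd_bias = pooled,
    bias_factor = bias_factor(mean(per$mean_bias)),
    n_observers = nrow(per), n_sims = as.integer(n_sims),
    n_runs = as.integer(nrow(per) * n_sims))
  structure(out, class = c("bias_summary", class(out)),
            per_observer = per[, c("id", "mean_bias", "sd_bias")])
}

# SD of the pooled per-run bias distribution, reconstructed from the
# per-observer sufficient statistics (sums and sums of squares).
unlist_pooled_sd <- function(per, n_sims) {
  n_tot <- nrow(per) * n_sims
  s1 <- sum(per$s1)
  s2 <- sum(per$m2)
  sqrt((s2 - s1^2 / n_tot) / (n_tot - 1))
}

#' Percentile sweep: find the assumed spread minimizing |bias x SD|
#'
#' Candidate assumed spreads are empirical percentiles (default 5 to 95%
#' in steps of 5%, 19 values; linear-interpolation quantiles) of the
#' observers' spread distribution. Each candidate is evaluated with
#' [bias_for_spread()]; the optimal candidate minimizes the absolute
#' product of mean bias and pooled SD, with ties broken toward the
#' smaller spread.
#'
#' @inheritParams bias_for_spread
#' @param percentiles Percent points to evaluate (default
#'   `seq(5, 95, 5)`).
#'
#' @return A tibble of class `sweep_result` with one row per percentile:
#'   `percentile`, `sigma_m`, `mean_bias`, `sd_bias`, `bias_factor`,
#'   `abs_bias_sd`, `optimal`, plus the bookkeeping columns of
#'   [bias_for_spread()].
#' @export
percentile_sweep <- function(observers, lapse_mode = c("subject", "fixed"),
                             model_lapse = NULL, n_sims = 2000, n_trials = 30,
                             percentiles = seq(5, 95, by = 5),
                             criterion = 0.75, grid = NULL, seed = NULL) {
  lapse_mode <- match.arg(lapse_mode)
  if (nrow(observers) < 2) abort_invalid("need >= 2 observers for a sweep")
  if (!is.null(seed)) set.seed(seed)
  sigma_m <- stats::quantile(observers$spread, percentiles / 100, type = 7,
                             names = FALSE)
  rows <- purrr::map2_dfr(percentiles, sigma_m, function(pc, sm) {
    bs <- bias_for_spread(observers, sm, lapse_mode, model_lapse,
                          n_sims = n_sims, n_trials = n_trials,
                          criterion = criterion, grid = grid)
    dplyr::mutate(tibble::as_tibble(bs), percentile = pc, .before = 1)
  })
  rows$abs_bias_sd <- abs(rows$mean_bias * rows$sd_bias)
  opt <- which.min(rows$abs_bias_sd)  # first minimum = smaller sigma_m
  rows$optimal <- seq_len(nrow(rows)) == opt
  structure(rows, class = c("sweep_result", class(rows)),
            optimal_percentile = rows$percentile[opt],
            optimal_sigma = rows$sigma_m[opt],
            total_runs = sum(rows$n_runs))
}

#' Declared run counts of a percentile-sweep design
#'
#' Bookkeeping for the factorial design: one staircase per
#' (percentile, observer, simulation) cell.
#'
#' @param n_observers,n_sims Design sizes.
#' @param n_percentiles Number of percentile points (default 19).
#' @return A list with `per_percentile` and `total` staircase counts.
#' @export
sweep_design <- function(n_observers, n_sims, n_percentiles = 19) {
  list(per_percentile = n_observers * n_sims,
       total = n_percentiles * n_observers * n_sims)
}

#' The standard simulated observer used in procedure comparisons
#'
#' Threshold 1.5 log10 arcsec, spread 1 (slope 7.327), lapse 0.02 (2AFC)
#' or 0.03 (4AFC), criterion 0.75.
#'
#' @param task A [task_spec()].
#' @return A [simulated_observer()].
#' @export
standard_observer <- function(task) {
  lapse <- if (task$n_alternatives == 2) 0.02 else 0.03
  simulated_observer(1.5, 1, lapse, task, criterion = 0.75, id = "standard")
}

#' Compare Bayesian adaptive procedures by Monte-Carlo simulation
#'
#' Runs `n_sims` sessions of each requested procedure against the
#' standard observer (or each observer of a population table) and records
#' the mean and SD of the threshold bias at each requested trial count
#' (one long session per run, estimates read off at each count).
#' Fixed-spread ZEST uses the recommended assumed spread by default
#' (1.7 log10 arcsec for 2AFC, 1.5 for 4AFC) and ignores the spread
#' prior, so its rows are identical across prior kinds at equal seeds.
#'
#' @param procedures Character vector of procedure names (see
#'   [procedure_config()]).
#' @param task A [task_spec()].
#' @param observers Optional observer table; default is the single
#'   [standard_observer()].
#' @param spread_prior `"uniform"` or [gaussian_prior()] for procedures
#'   with a spread axis.
#' @param trial_counts Trial counts at which to report (default
#'   `seq(10, 100, 10)`).
#' @param n_sims Simulations per procedure and observer (default 1000).
#' @param model_spread Assumed spread for `zest_fixed_sigma` (default by
#'   task as above).
#' @param model_lapse Assumed lapse for procedures that fix it (default:
#'   the standard observer's 0.02 / 0.03).
#' @param criterion Criterion probability (default 0.75).
#' @param seed Base seed; per-(procedure, observer) seeds are derived from
#'   it so a procedure's rows do not depend on which other procedures are
#'   run alongside it.
#'
#' @return A tidy tibble of class `procedure_comparison`: one row per
#'   (procedure, n_trials) with `prior`, `task`, `mean_bias`, `sd_bias`,
#'   `bias_factor`, `n_runs`.
#' @export
compare_procedures <- function(procedures, task,
                               observers = NULL,
                               spread_prior = "uniform",
                               trial_counts = seq(10, 100, by = 10),
                               n_sims = 1000,
                               model_spread = NULL, model_lapse = NULL,
                               criterion = 0.75, seed = 1) {
  stopifnot(inherits(task, "task_spec"))
  procedures <- match.arg(procedures, .procedures, several.ok = TRUE)
  if (is.null(model_spread)) {
    model_spread <- if (task$n_alternatives == 2) 1.7 else 1.5
  }
  if (is.null(model_lapse)) {
    model_lapse <- if (task$n_alternatives == 2) 0.02 else 0.03
  }
  obs_list <- if (is.null(observers)) list(standard_observer(task)) else {
    as_observer_list(observers, criterion)
  }
  n_max <- max(trial_counts)
  prior_label <- if (identical(spread_prior, "uniform")) "uniform" else "gaussian"

  purrr::map_dfr(procedures, function(proc) {
    needs_lapse <- !proc %in% c("psi_marg_theta_sigma_L", "psi_marg_theta_SL")
    cfg <- procedure_config(
      proc, task, n_trials = n_max, criterion = criterion,
      model_spread = if (proc == "zest_fixed_sigma") model_spread,
      model_lapse = if (needs_lapse) model_lapse,
      spread_prior = if (proc == "zest_fixed_sigma") "uniform" else spread_prior)
    all_bias <- vector("list", length(obs_list))
    for (i in seq_along(obs_list)) {
      obs <- obs_list[[i]]
      cell_seed <- (seed + 7919L * match(proc, .procedures) + i) %% .Machine$integer.max
      th <- run_many(obs, cfg, n_sims, seed = cell_seed)
      all_bias[[i]] <- th[trial_counts, , drop = FALSE] - obs$threshold
    }
    purrr::map_dfr(seq_along(trial_counts), function(j) {
      rows <- purrr::map(all_bias, function(b) b[j, ])
      per_mean <- vapply(rows, mean, numeric(1))
      pooled <- unlist(rows)
      tibble::tibble(
        procedure = proc, prior = prior_label,
        task = task$n_alternatives, n_trials = as.integer(trial_counts[j]),
        mean_bias = mean(per_mean), sd_bias = stats::sd(pooled),
        bias_factor = bias_factor(mean(per_mean)),
        n_runs = as.integer(length(pooled)))
    })
  }) |>
    (\(x) structure(x, class = c("procedure_comparison", class(x))))()
}
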