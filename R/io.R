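# File formats: session and trace CSV, fit tables, YAML/JSON run configs.
#
# CSV dialect: header mandatory, UTF-8, '.' decimal. Provenance (config
# hash, seed) is embedded as leading '#' comment lines and skipped on read.

#' Hash of a configuration object
#'
#' @param x Any R object.
#' @return A short stable hash string.
#' @export
config_hash <- function(x) rlang::hash(x)

provenance_lines <- function(hash = NULL, seed = NULL) {
  c(sprintf("# config_hash: %s", hash %||% "none"),
    sprintf("# seed: %s", if (is.null(seed)) "none" else format(seed)))
}

#' Write / read a session log as CSV
#'
#' Columns: `trial`, `level_log10_arcsec`, `correct` (0/1), `practice`
#' (0/1). Two leading comment lines carry the config hash and seed.
#'
#' @param session A `staircase_session` (or any tibble with `trial`,
#'   `level`, `response`, `practice`).
#' @param path Output file.
#' @param seed Seed to record (or `NULL`).
#' @return `path`, invisibly (the session tibble for the reader).
#' @export
write_session_csv <- function(session, path, seed = NULL) {
  out <- tibble::tibble(
    trial = session$trial,
    level_log10_arcsec = session$level,
    correct = as.integer(session$response),
    practice = as.integer(session$practice))
  hash <- config_hash(attr(session, "config"))
  writeLines(provenance_lines(hash, seed), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("trial", "level_log10_arcsec", "correct", "practice")
  if (!all(need %in% names(raw))) {
    rlang::abort("not a session CSV (missing columns)",
                 class = "zestsim_format_error")
  }
  tibble::tibble(trial = raw$trial, level = raw$level_log10_arcsec,
                 response = as.integer(raw$correct),
                 practice = raw$practice > 0)
}

#' Write / read an adaptive-procedure estimate trace as CSV
#'
#' Columns: `trial`, `stimulus`, `response`, `theta_hat`, `sigma_hat`,
#' `lambda_hat` (the latter two `NA` when the procedure does not estimate
#' them).
#'
#' @param trace An `estimate_trace` from [run_procedure()].
#' @param path Output file.
#' @param seed Seed to record (or `NULL`).
#' @return `path`, invisibly (the trace tibble for the reader).
#' @export
write_trace_csv <- function(trace, path, seed = NULL) {
  out <- tibble::tibble(
    trial = trace$trial, stimulus = trace$stimulus,
    response = trace$response, theta_hat = trace$theta_hat,
    sigma_hat = trace[["sigma_hat"]] %||% rep(NA_real_, nrow(trace)),
    lambda_hat = trace[["lambda_hat"]] %||% rep(NA_real_, nrow(trace)))
  hash <- config_hash(attr(trace, "config"))
  writeLines(provenance_lines(hash, seed), path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Per-subject fit table
#'
#' @param fits A list of `psyfit` objects.
#' @param ids Subject identifiers (recycled names).
#' @return A tibble with columns `id`, `theta_log10`, `theta_arcsec`,
#'   `sigma`, `lambda`, `dev`, `p_dev`, `included`.
#' @export
fit_table <- function(fits, ids = names(fits) %||% as.character(seq_along(fits))) {
  purrr::map2_dfr(fits, ids, function(f, id) {
    g <- glance(f)
    tibble::tibble(id = id, theta_log10 = g$theta_hat,
                   theta_arcsec = g$theta_arcsec, sigma = g$sigma_hat,
                   lambda = g$lambda_hat, dev = g$deviance,
                   p_dev = g$p_deviance, included = g$included)
  })
}

#' Write an observer table as CSV
#'
#' @param observers An observer table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_observer_csv <- function(observers, path) {
  readr::write_csv(tibble::as_tibble(observers), path)
  invisible(path)
}

.config_keys <- list(
  simulate = c("command", "procedure", "task", "sigma_m", "lambda_m",
               "trials", "criterion", "spread_prior", "seed", "out",
               "observer"),
  fit = c("command", "sessions", "task", "criterion", "n_boot", "seed",
          "out"),
  sweep = c("command", "profile", "subjects", "lapse_mode", "lambda_m",
            "n_sims", "trials", "seed", "out"),
  compare = c("command", "procedures", "task", "spread_prior",
              "trial_counts", "n_sims", "sigma_m", "lambda_m", "seed",
              "out"))

#' Read and validate a run configuration (YAML or JSON)
#'
#' The file must name a `command` (`simulate`, `fit`, `sweep` or
#' `compare`); keys not belonging to that command are errors, guarding
#' against silent typos.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return The validated config as a named list, with the file's hash in
#'   attribute `hash`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A named list with a `command` entry.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$command) || !cfg$command %in% names(.config_keys)) {
    rlang::abort("config must name a command: simulate, fit, sweep or compare",
                 class = "zestsim_invalid_config")
  }
  unknown <- setdiff(names(cfg), .config_keys[[cfg$command]])
  if (length(unknown)) {
    rlang::abort(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "zestsim_invalid_config")
  }
  structure(cfg, hash = config_hash(cfg))
}

#' Write a run configuration as YAML or JSON
#'
#' @param cfg A named list (validated first).
#' @param path Output `.yml`/`.yaml` or `.json` file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  cfg <- validate_run_config(cfg)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}
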