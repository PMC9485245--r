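#' Build a run configuration
#'
#' One structured configuration drives the whole
#' simulate -> analyze -> recover pipeline. Every random draw traces to
#' `seed`: session `i` uses child seed `seed + i` (the scheme is recorded
#' in the manifest). The configuration round-trips losslessly through YAML
#' via [write_run_config()] / [read_run_config()]; unknown keys are
#' rejected on read.
#'
#' @param seed Master integer seed.
#' @param n_sessions Number of sessions to simulate.
#' @param design A [task_design()] or a list of its arguments.
#' @param params A [decision_params()] or a list of its arguments.
#' @param analysis List of analysis options: `alpha` (significance level),
#'   `cr_gate`, `construction`, `preferred_sign_roll`,
#'   `preferred_sign_trans`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_sessions = 10,
                       design = task_design(), params = decision_params(),
                       analysis = list()) {
  if (is.list(design) && !inherits(design, "task_design")) {
    design <- do.call(task_design, design)
  }
  if (is.list(params) && !inherits(params, "decision_params")) {
    params <- do.call(decision_params, params)
  }
  analysis <- utils::modifyList(
    list(alpha = 0.05, cr_gate = 0.65, construction = "normal",
         preferred_sign_roll = 1, preferred_sign_trans = 1),
    analysis)
  structure(
    list(version = 1L, seed = as.integer(seed),
         n_sessions = as.integer(n_sessions),
         design = design, params = params, analysis = analysis),
    class = "run_config"
  )
}

config_keys <- c("version", "seed", "n_sessions", "design", "params",
                 "analysis")

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$design <- unclass(x$design)
  x$params <- unclass(x$params)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.integer(x$version), 1L)) {
    stop("unsupported config schema version: ", x$version, call. = FALSE)
  }
  run_config(seed = x$seed, n_sessions = x$n_sessions,
             design = x$design, params = x$params,
             analysis = x$analysis %||% list())
}

session_seed <- function(config, i) config$seed + i

#' Simulate all sessions of a configuration to disk
#'
#' Writes one trial-table CSV per session (with a JSON provenance sidecar)
#' plus a `manifest.json` recording the seeding scheme and the MD5 hash of
#' every file. Deterministic: the same configuration always produces
#' byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(config$n_sessions)
  for (i in seq_len(config$n_sessions)) {
    sid <- sprintf("s%03d", i)
    tr <- simulate_session(config$design, config$params,
                           seed = session_seed(config, i), session_id = sid)
    files[i] <- file.path(out_dir, paste0("trials_", sid, ".csv"))
    write_trials(tr, files[i], design = config$design,
                 params = config$params, seed = session_seed(config, i))
  }
  manifest <- list(
    seed = config$seed,
    seed_scheme = "session i uses seed + i",
    n_sessions = config$n_sessions,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Analyze a directory of simulated (or real) sessions
#'
#' Applies [analyze_session()] to every `trials_*.csv` under `dir` and
#' aggregates the population summaries reported for microstimulation
#' datasets: median signed and normalized PSE shift with a two-tail sign
#' test, the proportion of sessions with a significant probit PSE term,
#' the proportion shifted in the expected direction, the median CCI and
#' mean correct-rate changes. Writes `effects.csv` and `report.json`
#' beside the inputs, so re-running on the written outputs reproduces the
#' report.
#'
#' @param dir Directory containing `trials_*.csv` files.
#' @param config A [run_config()] providing the analysis options.
#' @return A list of class `run_report` with elements `effects` (per
#'   session) and `summary`.
#' @export
run_analyze <- function(dir, config = run_config()) {
  files <- sort(list.files(dir, pattern = "^trials_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no trial tables found in ", dir, call. = FALSE)
  an <- config$analysis
  effects <- purrr::map_dfr(files, function(f) {
    analyze_session(read_trials(f),
                    preferred_sign_roll = an$preferred_sign_roll,
                    preferred_sign_trans = an$preferred_sign_trans,
                    construction = an$construction,
                    cr_gate = an$cr_gate)
  })
  summarise_axis <- function(signed, norm, p) {
    ok <- !is.na(signed)
    tibble::tibble(
      n = sum(ok),
      median_dpse = stats::median(signed[ok]),
      median_dpse_normalized = stats::median(norm[!is.na(norm)]),
      p_sign_test = if (sum(signed[ok] != 0) > 0) {
        stats::binom.test(sum(signed[ok] > 0),
                          sum(signed[ok] != 0))$p.value
      } else NA_real_,
      prop_significant = mean(p[ok] < an$alpha, na.rm = TRUE),
      prop_expected_direction = mean(signed[ok] > 0)
    )
  }
  summary <- list()
  if ("dpse_signed_roll" %in% names(effects)) {
    summary$roll <- summarise_axis(effects$dpse_signed_roll,
                                   effects$dpse_normalized_roll,
                                   effects$p_pse_roll)
  }
  if ("dpse_signed_translation" %in% names(effects)) {
    summary$translation <- summarise_axis(effects$dpse_signed_translation,
                                          effects$dpse_normalized_translation,
                                          effects$p_pse_translation)
  }
  summary$cci <- tibble::tibble(
    n = sum(!is.na(effects$cci)),
    median_cci = stats::median(effects$cci, na.rm = TRUE))
  summary$delta_cr <- tibble::tibble(
    mean_delta_cr_intra = mean(effects$delta_cr_intra, na.rm = TRUE),
    mean_delta_cr_general = mean(effects$delta_cr_general, na.rm = TRUE),
    mean_delta_cr_flowpattern = mean(effects$delta_cr_flowpattern,
                                     na.rm = TRUE))
  readr::write_csv(effects, file.path(dir, "effects.csv"))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  structure(list(effects = effects, summary = summary),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", nrow(x$effects), "session(s)\n")
  for (nm in names(x$summary)) {
    cat("--", nm, "--\n")
    print(x$summary[[nm]])
  }
  invisible(x)
}

#' Parameter-recovery harness
#'
#' For each cell of a (delta, sigma, variant) grid, simulates `n_reps`
#' sessions, fits the psychometric layer and reports bias of the recovered
#' PSE shift and threshold against the generative truth, coverage of the
#' PSE confidence interval, and the CCI distribution. The generative
#' signed PSE shift of a within-pattern construction equals the injected
#' `delta` on that axis (variants 2-3; variant 1 on the roll axis only).
#'
#' @param grid A data frame with columns `delta`, `sigma`, `variant`.
#' @param n_reps Replicate sessions per cell.
#' @param design A [task_design()].
#' @param seed Master seed.
#' @return A tibble with one row per grid cell: recovered means, bias,
#'   CI coverage of the true PSE shift, and mean CCI.
#' @export
run_recover <- function(grid, n_reps = 20, design = task_design(),
                        seed = 1) {
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("delta", "sigma", "variant") %in% names(grid)))
  purrr::pmap_dfr(grid, function(delta, sigma, variant) {
    params <- decision_params(sigma_roll = sigma, sigma_trans = sigma,
                              delta_roll = delta, delta_trans = delta,
                              model_variant = variant)
    reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
      tr <- simulate_session(design, params,
                             seed = seed + 1000 * r + round(97 * delta) +
                               round(13 * sigma) + variant)
      fc <- fit_psychometric(tr, "roll", microstim = FALSE)
      fs <- fit_psychometric(tr, "roll", microstim = TRUE)
      dp <- delta_pse(fc, fs, preferred_sign = 1)
      se <- sqrt(fc$se_mu^2 + fs$se_mu^2)
      cc <- if (design$paradigm == "AFC4") cci(tr)$cci else NA_real_
      tibble::tibble(dpse = dp$dpse_signed, sigma_hat = fc$sigma,
                     covered = abs(dp$dpse_signed - delta) <= 1.96 * se,
                     cci = cc)
    })
    tibble::tibble(
      delta = delta, sigma = sigma, variant = variant, n_reps = n_reps,
      mean_dpse = mean(reps$dpse), dpse_bias = mean(reps$dpse) - delta,
      mean_sigma_hat = mean(reps$sigma_hat),
      ci_coverage = mean(reps$covered, na.rm = TRUE),
      mean_cci = mean(reps$cci, na.rm = TRUE)
    )
  })
}
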