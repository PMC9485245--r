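#' Task design for a discrimination session
#'
#' Describes the stimulus grid of one behavioral session. In the `fine`
#' version the signed levels are angles (deg) of the rotary or translational
#' component away from the straight-forward reference; in the `coarse`
#' version they are signed coherences (%) of pure roll or pure laminar
#' motion. Levels must be symmetric about 0 and include 0 (the shared
#' ambiguous reference). Positive roll levels are CW, positive translation
#' levels leftward. Defaults are the fine 4-AFC grid
#' (+/-11.54, +/-5.74, +/-2.87, +/-1.15, 0 deg on the roll axis;
#' +/-5, +/-2.4, +/-1.15, +/-0.55, 0 deg on the translation axis), 17
#' conditions in total since the reference is shared; the coarse grids use
#' +/-8, +/-4, +/-2, +/-1, 0 % coherence on both axes.
#'
#' @param paradigm "AFC4" (joint pattern + direction report), "AFC2_roll" or
#'   "AFC2_translation" (single-pattern blocks).
#' @param version "fine" or "coarse" (sets default level grids).
#' @param roll_levels,trans_levels Signed level grids; `NULL` for the
#'   version's default.
#' @param reps_per_level Repetitions per (condition, stimulation state)
#'   cell (>= 1).
#' @param stim_fraction Fraction of trials carrying microstimulation
#'   (default 0.5: stimulated and control trials interleaved 1:1).
#' @return An object of class `task_design`.
#' @export
task_design <- function(paradigm = c("AFC4", "AFC2_roll", "AFC2_translation"),
                        version = c("fine", "coarse"),
                        roll_levels = NULL, trans_levels = NULL,
                        reps_per_level = 15, stim_fraction = 0.5) {
  paradigm <- match.arg(paradigm)
  version <- match.arg(version)
  defaults <- if (version == "fine") {
    list(roll = c(-11.54, -5.74, -2.87, -1.15, 0, 1.15, 2.87, 5.74, 11.54),
         trans = c(-5, -2.4, -1.15, -0.55, 0, 0.55, 1.15, 2.4, 5))
  } else {
    list(roll = c(-8, -4, -2, -1, 0, 1, 2, 4, 8),
         trans = c(-8, -4, -2, -1, 0, 1, 2, 4, 8))
  }
  roll_levels <- sort(roll_levels %||% defaults$roll)
  trans_levels <- sort(trans_levels %||% defaults$trans)
  check_levels <- function(lv, nm) {
    if (!0 %in% lv || !isTRUE(all.equal(sort(lv), sort(-lv)))) {
      stop(nm, " levels must be symmetric about 0 and include 0",
           call. = FALSE)
    }
  }
  check_levels(roll_levels, "roll")
  check_levels(trans_levels, "translation")
  if (reps_per_level < 1) stop("reps_per_level must be >= 1", call. = FALSE)
  if (stim_fraction < 0 || stim_fraction >= 1) {
    stop("stim_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(paradigm = paradigm, version = version,
         roll_levels = roll_levels, trans_levels = trans_levels,
         reps_per_level = reps_per_level, stim_fraction = stim_fraction),
    class = "task_design"
  )
}

#' Labelled-line decision model parameters
#'
#' The generative choice model: on each trial the roll and translation axes
#' carry independent Gaussian decision variables
#' `d_R = x_R + delta_roll * s_R + eps_R` and
#' `d_T = x_T + delta_trans * s_T + eps_T`, where `x` is the signed stimulus
#' on that axis, `delta` the microstimulation-injected labelled-line signal,
#' `s` a variant-dependent stimulation indicator, and `eps ~ N(0, sigma)`.
#' In the 4-AFC task the flow pattern is arbitrated by comparing
#' `|d_R| - |d_T|` against `pattern_bias` (plus `pattern_shift` on
#' stimulated trials under variant 3); the direction report is the sign of
#' the chosen axis's decision variable. A `lapse` fraction of trials is a
#' uniform guess over the available targets.
#'
#' The three model variants mirror the three qualitative readout outcomes:
#' variant 1 injects `delta` into one axis only (`delta_trans` is ignored),
#' variant 2 injects into both axes with no inter-pattern effect, and
#' variant 3 adds `pattern_shift` to the arbitration stage (positive values
#' push stimulated-trial choices toward the translation targets).
#'
#' @param sigma_roll,sigma_trans Internal noise SD per axis, in axis units
#'   (> 0).
#' @param pattern_bias Criterion offset for roll-vs-translation arbitration
#'   (positive favours translation choices).
#' @param lapse Uniform-guess rate in \[0, 0.2\].
#' @param delta_roll,delta_trans Microstimulation offsets, axis units.
#' @param model_variant 1, 2 or 3.
#' @param pattern_shift Inter-pattern bias on stimulated trials (variant 3
#'   only; positive = toward translation).
#' @return An object of class `decision_params`.
#' @export
decision_params <- function(sigma_roll = 3, sigma_trans = 1.5,
                            pattern_bias = 0, lapse = 0,
                            delta_roll = 0, delta_trans = 0,
                            model_variant = 2, pattern_shift = 0) {
  if (sigma_roll <= 0 || sigma_trans <= 0) {
    stop("noise SDs must be positive", call. = FALSE)
  }
  if (lapse < 0 || lapse > 0.2) stop("lapse must lie in [0, 0.2]", call. = FALSE)
  if (!model_variant %in% 1:3) stop("model_variant must be 1, 2 or 3", call. = FALSE)
  structure(
    list(sigma_roll = sigma_roll, sigma_trans = sigma_trans,
         pattern_bias = pattern_bias, lapse = lapse,
         delta_roll = delta_roll, delta_trans = delta_trans,
         model_variant = model_variant, pattern_shift = pattern_shift),
    class = "decision_params"
  )
}

# effective microstimulation offsets and arbitration criterion for a trial
effective_stim <- function(params, microstim) {
  s <- as.numeric(microstim)
  list(
    d_roll = params$delta_roll * s,
    d_trans = if (params$model_variant == 1) 0 else params$delta_trans * s,
    bias = params$pattern_bias +
      (if (params$model_variant == 3) params$pattern_shift * s else 0)
  )
}

# P(|N(mu, sd)| < c), 0 for c <= 0
p_abs_below <- function(c, mu, sd) {
  ifelse(c > 0,
         stats::pnorm((c - mu) / sd) - stats::pnorm((-c - mu) / sd),
         0)
}

# one half-line integral: P(sign branch of own axis & own pattern chosen)
integrate_branch <- function(mu_own, sd_own, mu_oth, sd_oth, crit, own_wins) {
  f <- if (own_wins) {
    # own chosen iff |d_own| - |d_oth| > crit, with |d_own| = u on this branch
    function(u) stats::dnorm(u, mu_own, sd_own) * p_abs_below(u - crit, mu_oth, sd_oth)
  } else {
    # own (translation) chosen iff NOT |d_oth| - |d_own| > crit,
    # i.e. |d_oth| < u + crit with |d_own| = u on this branch
    function(u) stats::dnorm(u, mu_own, sd_own) *
      p_abs_below(u + crit, mu_oth, sd_oth)
  }
  # split at the integrand's kink (where the other axis' term activates)
  # and at the own-axis density peak so adaptive quadrature never misses
  # a narrow bump far from the origin
  kink <- if (own_wins) max(0, crit) else max(0, -crit)
  cuts <- sort(unique(c(0, kink, max(0, mu_own))))
  pieces <- c(purrr::map2_dbl(
    cuts[-length(cuts)], cuts[-1],
    function(a, b) {
      if (b - a < 1e-14) return(0)
      stats::integrate(f, a, b, rel.tol = 1e-11, abs.tol = 1e-13,
                       subdivisions = 200L)$value
    }),
    stats::integrate(f, cuts[length(cuts)], Inf, rel.tol = 1e-11,
                     abs.tol = 1e-13, subdivisions = 200L)$value)
  sum(pieces)
}

#' Closed-form choice probabilities of the decision model
#'
#' Computes the probability of each of the four saccade targets (CW, CCW,
#' LEFT, RIGHT) for one stimulus condition under the labelled-line decision
#' model, by numerical integration over the two axes' Gaussian noise. In
#' 2-AFC paradigms the two unavailable targets have probability 0 and the
#' direction report is simply the sign of the relevant axis's decision
#' variable. Probabilities sum to 1 to within 1e-9 and serve as the exact
#' oracle for [simulate_session()].
#'
#' @param params A [decision_params()].
#' @param plane_shown "roll", "translation" or "ambiguous".
#' @param stim_value Signed stimulus level on the shown axis (0 for
#'   ambiguous).
#' @param microstim Logical: microstimulated trial?
#' @param paradigm "AFC4", "AFC2_roll" or "AFC2_translation".
#' @return A one-row tibble with columns `cw`, `ccw`, `left`, `right`.
#' @export
choice_probabilities <- function(params, plane_shown, stim_value,
                                 microstim = FALSE, paradigm = "AFC4") {
  stopifnot(inherits(params, "decision_params"))
  x_r <- if (plane_shown == "roll") stim_value else 0
  x_t <- if (plane_shown == "translation") stim_value else 0
  if (plane_shown == "ambiguous" && stim_value != 0) {
    stop("ambiguous trials have stim_value 0", call. = FALSE)
  }
  eff <- effective_stim(params, microstim)
  mu_r <- x_r + eff$d_roll
  mu_t <- x_t + eff$d_trans
  if (paradigm == "AFC2_roll") {
    p_cw <- stats::pnorm(mu_r / params$sigma_roll)
    p <- c(cw = p_cw, ccw = 1 - p_cw, left = 0, right = 0)
    lapse_mix <- c(0.5, 0.5, 0, 0)
  } else if (paradigm == "AFC2_translation") {
    p_l <- stats::pnorm(mu_t / params$sigma_trans)
    p <- c(cw = 0, ccw = 0, left = p_l, right = 1 - p_l)
    lapse_mix <- c(0, 0, 0.5, 0.5)
  } else {
    # roll pattern chosen iff |d_R| - |d_T| > crit (ties measure-zero)
    p <- c(
      cw = integrate_branch(mu_r, params$sigma_roll, mu_t,
                            params$sigma_trans, eff$bias, TRUE),
      ccw = integrate_branch(-mu_r, params$sigma_roll, mu_t,
                             params$sigma_trans, eff$bias, TRUE),
      left = integrate_branch(mu_t, params$sigma_trans, mu_r,
                              params$sigma_roll, eff$bias, FALSE),
      right = integrate_branch(-mu_t, params$sigma_trans, mu_r,
                               params$sigma_roll, eff$bias, FALSE)
    )
    lapse_mix <- rep(0.25, 4)
  }
  p <- (1 - params$lapse) * p + params$lapse * lapse_mix
  tibble::tibble(cw = p[[1]], ccw = p[[2]], left = p[[3]], right = p[[4]])
}

choice_levels <- c("CW", "CCW", "LEFT", "RIGHT")

# condition grid of a design: one row per (plane_shown, stim_value)
design_conditions <- function(design) {
  switch(design$paradigm,
    AFC4 = dplyr::bind_rows(
      tibble::tibble(plane_shown = "roll",
                     stim_value = setdiff(design$roll_levels, 0)),
      tibble::tibble(plane_shown = "translation",
                     stim_value = setdiff(design$trans_levels, 0)),
      tibble::tibble(plane_shown = "ambiguous", stim_value = 0)
    ),
    AFC2_roll = tibble::tibble(
      plane_shown = ifelse(design$roll_levels == 0, "ambiguous", "roll"),
      stim_value = design$roll_levels),
    AFC2_translation = tibble::tibble(
      plane_shown = ifelse(design$trans_levels == 0, "ambiguous",
                           "translation"),
      stim_value = design$trans_levels)
  )
}

#' Simulate one behavioral session
#'
#' Builds the full condition grid of the design (each condition getting
#' `reps_per_level` control trials and
#' `round(reps_per_level * stim_fraction / (1 - stim_fraction))` stimulated
#' trials, i.e. equal numbers at the default 0.5), draws every trial's
#' choice from [choice_probabilities()], applies the reward rule, and
#' randomly interleaves all trials. Reproducible for a fixed seed.
#'
#' @param design A [task_design()].
#' @param params A [decision_params()].
#' @param seed Optional integer seed.
#' @param session_id Session identifier stored in the table.
#' @return A tibble trial table with columns `session_id`, `trial`,
#'   `paradigm`, `version`, `plane_shown`, `stim_value`, `microstim`,
#'   `choice`, `rewarded`.
#' @export
simulate_session <- function(design, params, seed = NULL,
                             session_id = "s1") {
  stopifnot(inherits(design, "task_design"), inherits(params, "decision_params"))
  if (!is.null(seed)) set.seed(seed)
  conds <- design_conditions(design)
  n_stim <- round(design$reps_per_level * design$stim_fraction /
                    (1 - design$stim_fraction))
  cells <- tidyr::expand_grid(conds, microstim = c(FALSE, TRUE)) |>
    dplyr::mutate(n = ifelse(.data$microstim, n_stim, design$reps_per_level)) |>
    dplyr::filter(.data$n > 0)

  trials <- purrr::pmap_dfr(cells, function(plane_shown, stim_value,
                                            microstim, n) {
    p <- choice_probabilities(params, plane_shown, stim_value, microstim,
                              paradigm = design$paradigm)
    counts <- stats::rmultinom(1, n, prob = as.numeric(p[1, ]))[, 1]
    tibble::tibble(
      plane_shown = plane_shown, stim_value = stim_value,
      microstim = microstim,
      choice = rep(choice_levels, counts)
    )
  })
  trials <- trials[sample.int(nrow(trials)), ]
  trials <- trials |>
    dplyr::mutate(session_id = session_id, trial = dplyr::row_number(),
                  paradigm = design$paradigm, version = design$version,
                  .before = 1)
  trials$rewarded <- reward_rule(trials)
  trials
}

#' Apply the reward rule to a trial table
#'
#' On non-ambiguous trials reward is earned only when the choice matches
#' both the shown flow pattern and its correct direction (positive roll
#' levels are CW, positive translation levels leftward). The ambiguous
#' reference carries no information, so it is rewarded at random with
#' probability 0.5 regardless of the choice.
#'
#' @param trials A trial table with columns `plane_shown`, `stim_value`,
#'   `choice`.
#' @return A logical vector of rewards (uses the current RNG stream for the
#'   ambiguous trials).
#' @export
reward_rule <- function(trials) {
  correct <- correct_choice(trials$plane_shown, trials$stim_value)
  amb <- trials$plane_shown == "ambiguous"
  out <- !amb & trials$choice == correct
  out[amb] <- stats::runif(sum(amb)) < 0.5
  out
}

# the rewarded target of a non-ambiguous condition (NA for ambiguous)
correct_choice <- function(plane_shown, stim_value) {
  dplyr::case_when(
    plane_shown == "roll" & stim_value > 0 ~ "CW",
    plane_shown == "roll" & stim_value < 0 ~ "CCW",
    plane_shown == "translation" & stim_value > 0 ~ "LEFT",
    plane_shown == "translation" & stim_value < 0 ~ "RIGHT",
    .default = NA_character_
  )
}

#' Write / read trial tables
#'
#' Trial tables are CSVs with columns `session_id`, `trial`, `paradigm`,
#' `version`, `plane_shown`, `stim_value`, `microstim`, `choice`,
#' `rewarded`; real data exported to the same schema is accepted by the
#' analysis layer. `write_trials` also writes a JSON provenance sidecar
#' when `design`/`params`/`seed` are supplied.
#'
#' @param trials A trial table.
#' @param path CSV path.
#' @param design,params,seed Optional provenance stored in the sidecar.
#' @return `write_trials` returns `path` invisibly; `read_trials` the
#'   validated tibble.
#' @export
write_trials <- function(trials, path, design = NULL, params = NULL,
                         seed = NULL) {
  readr::write_csv(trials, path)
  if (!is.null(design) || !is.null(params) || !is.null(seed)) {
    jsonlite::write_json(
      list(design = unclass(design), params = unclass(params), seed = seed),
      sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          session_id = readr::col_character(),
                          choice = readr::col_character(),
                          plane_shown = readr::col_character()))
  validate_trials(tr)
}

validate_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  need <- c("session_id", "trial", "plane_shown", "stim_value", "microstim",
            "choice")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!trials$choice %in% choice_levels)
  if (length(bad)) {
    stop("unknown choice label at row(s) ", paste(utils::head(bad, 5),
                                                  collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!trials$plane_shown %in% c("roll", "translation", "ambiguous"))
  if (length(bad)) {
    stop("unknown plane_shown at row(s) ", paste(utils::head(bad, 5),
                                                 collapse = ", "),
         call. = FALSE)
  }
  trials
}
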