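#' Tabulate choices per stimulus cell
#'
#' Exhaustive, disjoint tabulation of a trial table into counts of the four
#' saccade targets per (shown plane, stimulus level, microstimulation flag)
#' cell. The tabulation is order-invariant and preserves the trial total;
#' it feeds every psychometric construction.
#'
#' @param trials A trial table ([simulate_session()] schema).
#' @return A tibble with columns `plane_shown`, `stim_value`, `microstim`,
#'   `cw`, `ccw`, `left`, `right`, `n`.
#' @export
build_counts <- function(trials) {
  trials <- validate_trials(trials)
  base <- tibble::tibble(plane_shown = character(), stim_value = double(),
                         microstim = logical(),
                         cw = integer(), ccw = integer(),
                         left = integer(), right = integer(), n = integer())
  if (nrow(trials) == 0) return(base)
  trials |>
    dplyr::count(.data$plane_shown, .data$stim_value, .data$microstim,
                 .data$choice) |>
    tidyr::pivot_wider(names_from = "choice", values_from = "n",
                       values_fill = 0L) |>
    add_missing_choice_cols() |>
    dplyr::rename(cw = "CW", ccw = "CCW", left = "LEFT", right = "RIGHT") |>
    dplyr::mutate(n = .data$cw + .data$ccw + .data$left + .data$right) |>
    dplyr::arrange(.data$plane_shown, .data$stim_value, .data$microstim)
}

add_missing_choice_cols <- function(df) {
  for (ch in choice_levels) {
    if (!ch %in% names(df)) df[[ch]] <- 0L
  }
  df
}

counts_for_plane <- function(counts, plane) {
  dplyr::filter(counts, .data$plane_shown %in% c(plane, "ambiguous"))
}

#' Within-pattern ("normal") psychometric construction
#'
#' The classical 2-AFC-style construction: per stimulus level, the
#' proportion of CW choices among roll-target choices (roll axis), or of
#' LEFT choices among translation-target choices (translation axis).
#' Trials with a cross-pattern choice are excluded from both numerator and
#' denominator; levels whose denominator is zero are returned with `prop`
#' missing rather than 0.
#'
#' @param counts Output of [build_counts()].
#' @param plane "roll" or "translation".
#' @return A tibble with `microstim`, `level`, `n_success`, `n_total`,
#'   `prop`.
#' @export
psychometric_normal <- function(counts, plane = c("roll", "translation")) {
  plane <- match.arg(plane)
  counts_for_plane(counts, plane) |>
    dplyr::group_by(microstim = .data$microstim, level = .data$stim_value) |>
    dplyr::summarise(
      n_success = sum(if (plane == "roll") .data$cw else .data$left),
      n_total = sum(if (plane == "roll") .data$cw + .data$ccw
                    else .data$left + .data$right),
      .groups = "drop") |>
    dplyr::mutate(prop = ifelse(.data$n_total > 0,
                                .data$n_success / .data$n_total, NA_real_))
}

#' General-error psychometric construction
#'
#' Same numerators as [psychometric_normal()] but with all four choices in
#' the denominator, so cross-pattern errors count against the proportion.
#' Only meaningful for 4-AFC data.
#'
#' @inheritParams psychometric_normal
#' @return A tibble with `microstim`, `level`, `n_success`, `n_total`,
#'   `prop`.
#' @export
psychometric_general <- function(counts, plane = c("roll", "translation")) {
  plane <- match.arg(plane)
  counts_for_plane(counts, plane) |>
    dplyr::group_by(microstim = .data$microstim, level = .data$stim_value) |>
    dplyr::summarise(
      n_success = sum(if (plane == "roll") .data$cw else .data$left),
      n_total = sum(.data$n),
      .groups = "drop") |>
    dplyr::mutate(prop = ifelse(.data$n_total > 0,
                                .data$n_success / .data$n_total, NA_real_))
}

#' Flow-pattern psychometric construction
#'
#' Proportion of translation-target choices (LEFT + RIGHT over all four)
#' as a function of a signed flow-pattern axis in \[-1, +1\]: roll levels
#' map to the left side (absolute level divided by the largest roll level,
#' negated), translation levels to the right side, and the ambiguous
#' reference sits at 0.
#'
#' @param counts Output of [build_counts()].
#' @return A tibble with `microstim`, `axis`, `n_success`, `n_total`,
#'   `prop`.
#' @export
psychometric_flowpattern <- function(counts) {
  roll_max <- max(abs(counts$stim_value[counts$plane_shown == "roll"]), 0)
  trans_max <- max(abs(counts$stim_value[counts$plane_shown == "translation"]),
                   0)
  counts |>
    dplyr::mutate(axis = dplyr::case_when(
      .data$plane_shown == "ambiguous" ~ 0,
      .data$plane_shown == "roll" ~ -abs(.data$stim_value) / roll_max,
      .default = abs(.data$stim_value) / trans_max
    )) |>
    dplyr::group_by(microstim = .data$microstim, axis = .data$axis) |>
    dplyr::summarise(n_success = sum(.data$left + .data$right),
                     n_total = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(prop = ifelse(.data$n_total > 0,
                                .data$n_success / .data$n_total, NA_real_))
}

#' Fit a two-parameter cumulative Gaussian to binomial choice data
#'
#' Binomial maximum-likelihood fit of `p(x) = Phi((x - mu) / sigma)`:
#' `mu` is the point of subjective equality (PSE, the level of equal choice
#' probability) and `sigma` the psychophysical threshold (the offset from
#' the PSE giving ~84% choice probability, since Phi(1) = 0.841).
#' Initial values come from a probit-transformed weighted linear
#' regression; the likelihood is then maximized by Nelder-Mead followed by
#' BFGS polishing on `(mu, log sigma)`, with `sigma` bounded below at 1e-6
#' axis units. Degenerate (all-0 / all-1) data yields boundary estimates
#' with an honest `converged = FALSE` flag.
#'
#' @param levels Stimulus levels.
#' @param successes Choice counts toward the positive direction per level
#'   (non-integer weights allowed).
#' @param totals Denominator counts per level.
#' @return An object of class `psychometric_fit`: list with `mu`, `sigma`,
#'   `se_mu`, `se_sigma`, `loglik`, `n_trials`, `converged`, `data`.
#' @export
fit_cumgauss <- function(levels, successes, totals) {
  keep <- !is.na(levels) & !is.na(successes) & !is.na(totals) & totals > 0
  x <- levels[keep]; s <- successes[keep]; n <- totals[keep]
  if (length(unique(x)) < 3) {
    stop("need at least 3 informative stimulus levels", call. = FALSE)
  }
  nll <- function(par) {
    p <- stats::pnorm((x - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(s * log(p) + (n - s) * log(1 - p))
  }
  nll_grad <- function(par) {
    sig <- exp(par[2])
    z <- (x - par[1]) / sig
    p <- pmin(pmax(stats::pnorm(z), 1e-12), 1 - 1e-12)
    dldp <- s / p - (n - s) / (1 - p)
    phi <- stats::dnorm(z)
    c(sum(dldp * phi / sig), sum(dldp * z * phi))
  }
  degenerate <- sum(s) == 0 || sum(s) == sum(n)
  # probit-linear initialization
  z <- stats::qnorm((s + 0.5) / (n + 1))
  ini <- stats::coef(stats::lm(z ~ x, weights = n))
  if (!is.finite(ini[2]) || ini[2] <= 1e-8) {
    ini <- c(-mean(x) / (diff(range(x)) / 2), 1 / (diff(range(x)) / 2))
  }
  par0 <- c(mu = unname(-ini[1] / ini[2]),
            logsig = log(max(1e-6, unname(1 / ini[2]))))
  fit <- stats::optim(par0, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  fit <- stats::optim(fit$par, nll, gr = nll_grad, method = "BFGS",
                      hessian = TRUE,
                      control = list(reltol = 1e-14, maxit = 1000))
  mu <- fit$par[[1]]
  sigma <- max(exp(fit$par[[2]]), 1e-6)
  vc <- try(solve(fit$hessian), silent = TRUE)
  ok_vc <- !inherits(vc, "try-error") && all(is.finite(vc)) &&
    all(diag(vc) > 0)
  se_mu <- if (ok_vc) sqrt(vc[1, 1]) else NA_real_
  se_sigma <- if (ok_vc) sigma * sqrt(vc[2, 2]) else NA_real_  # delta method
  span <- diff(range(x))
  converged <- fit$convergence == 0 && !degenerate && ok_vc &&
    sigma < 50 * span && abs(mu) < max(abs(x)) + 10 * span
  structure(
    list(mu = mu, sigma = sigma, se_mu = se_mu, se_sigma = se_sigma,
         loglik = -fit$value, n_trials = sum(n), converged = converged,
         data = tibble::tibble(level = x, n_success = s, n_total = n)),
    class = "psychometric_fit"
  )
}

#' Fit a psychometric function directly from a trial table
#'
#' Convenience wrapper: tabulates the trials, applies the requested
#' construction and fits [fit_cumgauss()].
#'
#' @param trials A trial table.
#' @param plane "roll" or "translation" (ignored for the flow-pattern
#'   construction).
#' @param construction "normal", "general" or "flow_pattern".
#' @param microstim `TRUE`/`FALSE` to restrict to stimulated or control
#'   trials, `NULL` for all.
#' @return A `psychometric_fit`.
#' @export
fit_psychometric <- function(trials, plane = c("roll", "translation"),
                             construction = c("normal", "general",
                                              "flow_pattern"),
                             microstim = NULL) {
  plane <- match.arg(plane)
  construction <- match.arg(construction)
  if (!is.null(microstim)) {
    trials <- dplyr::filter(trials, .data$microstim == !!microstim)
  }
  counts <- build_counts(trials)
  tab <- switch(construction,
    normal = psychometric_normal(counts, plane),
    general = psychometric_general(counts, plane),
    flow_pattern = dplyr::rename(psychometric_flowpattern(counts),
                                 level = "axis")
  )
  tab <- tab |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(n_success = sum(.data$n_success),
                     n_total = sum(.data$n_total), .groups = "drop")
  fit_cumgauss(tab$level, tab$n_success, tab$n_total)
}

#' Probit regression test for microstimulation effects
#'
#' Fits the probit model `P(positive choice) = Phi(b0 + b1 x + b2 s +
#' b3 x s)` to per-trial data, where `x` is the stimulus level and `s` the
#' microstimulation indicator. `b2` captures a stimulation-induced PSE
#' shift and `b3` a slope (threshold) change; both are tested with
#' two-sided Wald tests. With control trials only, `-b0/b1` and `1/b1`
#' recover the cumulative-Gaussian PSE and threshold.
#'
#' @param trials A trial table containing both stimulated and control
#'   trials.
#' @param plane "roll" or "translation".
#' @param construction "normal" (within-pattern choices only) or "general"
#'   (all trials of the pattern).
#' @return An object of class `probit_stim_test`: list with `coefficients`
#'   (tidy tibble), `p_pse`, `p_slope`, `converged`, `n_trials`.
#' @export
probit_stim_test <- function(trials, plane = c("roll", "translation"),
                             construction = c("normal", "general")) {
  plane <- match.arg(plane)
  construction <- match.arg(construction)
  trials <- validate_trials(trials)
  pattern_choices <- if (plane == "roll") c("CW", "CCW") else c("LEFT", "RIGHT")
  positive <- if (plane == "roll") "CW" else "LEFT"
  d <- dplyr::filter(trials, .data$plane_shown %in% c(plane, "ambiguous"))
  if (construction == "normal") {
    d <- dplyr::filter(d, .data$choice %in% pattern_choices)
  }
  if (length(unique(d$microstim)) < 2) {
    stop("need both stimulated and control trials", call. = FALSE)
  }
  d <- dplyr::mutate(d, y = as.integer(.data$choice == positive),
                     s = as.integer(.data$microstim))
  warned <- FALSE
  m <- withCallingHandlers(
    stats::glm(y ~ stim_value * s, family = stats::binomial("probit"),
               data = d),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  sm <- stats::summary.glm(m)$coefficients
  co <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                       std_error = sm[, 2], statistic = sm[, 3],
                       p_value = sm[, 4])
  pick <- function(term) {
    i <- match(term, co$term)
    if (is.na(i)) NA_real_ else co$p_value[i]
  }
  structure(
    list(coefficients = co, p_pse = pick("s"), p_slope = pick("stim_value:s"),
         converged = m$converged && !warned, n_trials = nrow(d)),
    class = "probit_stim_test"
  )
}

#' Signed and normalized microstimulation-induced PSE shift
#'
#' The raw shift is `mu_ctrl - mu_stim`, positive when stimulation moves
#' the curve so that more positive-direction choices are made. The signed
#' shift orients it by the stimulated site's preferred direction
#' (`preferred_sign = +1` when the site prefers the positive axis
#' direction, CW or leftward), so that a shift toward the site's preference
#' - the "expected" labelled-line outcome - is positive. The normalized
#' shift divides by the control threshold, giving a unitless effect
#' comparable across axes (deg vs % coherence) and task versions.
#'
#' @param fit_ctrl,fit_stim Converged [fit_cumgauss()] fits for control and
#'   stimulated trials of the same construction.
#' @param preferred_sign +1 or -1, from the stimulated site's tuning.
#' @return A one-row tibble: `dpse_raw`, `dpse_signed`, `dpse_normalized`,
#'   `delta_threshold`.
#' @export
delta_pse <- function(fit_ctrl, fit_stim, preferred_sign = 1) {
  stopifnot(inherits(fit_ctrl, "psychometric_fit"),
            inherits(fit_stim, "psychometric_fit"))
  if (!preferred_sign %in% c(-1, 1)) {
    stop("preferred_sign must be +1 or -1", call. = FALSE)
  }
  if (fit_ctrl$sigma <= 0) stop("control threshold must be positive", call. = FALSE)
  raw <- fit_ctrl$mu - fit_stim$mu
  tibble::tibble(
    dpse_raw = raw,
    dpse_signed = preferred_sign * raw,
    dpse_normalized = preferred_sign * raw / fit_ctrl$sigma,
    delta_threshold = fit_stim$sigma - fit_ctrl$sigma
  )
}

#' Choice-change index (CCI) between flow patterns
#'
#' Relative change, under microstimulation, of the frequency of
#' translation-target choices among trials at the ambiguous stimulus
#' conditions: `(Choice_stim - Choice_nonstim) / Choice_nonstim`. The
#' ambiguous set is the zero reference plus, to increase statistical power,
#' the adjacent near-threshold levels on each axis (by default the smallest
#' nonzero level present). Positive CCI means stimulation biased the
#' pattern report toward translation, negative toward roll; the index is
#' bounded below by -1. Sessions whose control-trial flow-pattern correct
#' rate does not exceed `cr_gate` are excluded.
#'
#' @param trials A 4-AFC trial table.
#' @param ambiguous_levels Optional list with numeric elements `roll` and
#'   `translation`: absolute adjacent levels to include per axis.
#' @param cr_gate Control correct-rate gate (default 0.65).
#' @return A one-row tibble: `cci`, `choice_stim`, `choice_nonstim`,
#'   `n_stim`, `n_ctrl`, `control_cr`, `included`, `reason`.
#' @export
cci <- function(trials, ambiguous_levels = NULL, cr_gate = 0.65) {
  trials <- validate_trials(trials)
  if (is.null(ambiguous_levels)) {
    smallest <- function(pl) {
      v <- abs(trials$stim_value[trials$plane_shown == pl])
      v <- v[v > 0]
      if (length(v)) min(v) else numeric()
    }
    ambiguous_levels <- list(roll = smallest("roll"),
                             translation = smallest("translation"))
  }
  cr <- correct_rate(dplyr::filter(trials, !.data$microstim),
                     mode = "flow_pattern")$cr
  out <- function(cci, fs, fn, ns, nc, included, reason) {
    tibble::tibble(cci = cci, choice_stim = fs, choice_nonstim = fn,
                   n_stim = ns, n_ctrl = nc, control_cr = cr,
                   included = included, reason = reason)
  }
  if (!is.na(cr) && cr <= cr_gate) {
    return(out(NA_real_, NA_real_, NA_real_, NA_integer_, NA_integer_,
               FALSE, "control correct rate below gate"))
  }
  amb <- trials |>
    dplyr::filter(
      .data$plane_shown == "ambiguous" |
        (.data$plane_shown == "roll" &
           abs(.data$stim_value) %in% ambiguous_levels$roll) |
        (.data$plane_shown == "translation" &
           abs(.data$stim_value) %in% ambiguous_levels$translation))
  f <- amb |>
    dplyr::group_by(.data$microstim) |>
    dplyr::summarise(p = mean(.data$choice %in% c("LEFT", "RIGHT")),
                     n = dplyr::n(), .groups = "drop")
  fs <- f$p[f$microstim]; fn <- f$p[!f$microstim]
  ns <- f$n[f$microstim]; nc <- f$n[!f$microstim]
  if (length(fs) == 0 || length(fn) == 0) {
    return(out(NA_real_, NA_real_, NA_real_, NA_integer_, NA_integer_,
               FALSE, "missing a stimulation state at ambiguous levels"))
  }
  if (fn == 0) {
    return(out(NA_real_, fs, fn, ns, nc, TRUE,
               "undefined: no control translation choices"))
  }
  out((fs - fn) / fn, fs, fn, ns, nc, TRUE, NA_character_)
}

#' Correct rate and its microstimulation-induced change
#'
#' Three notions of correct rate over the non-ambiguous trials:
#' `intra` - correct-direction choices among trials whose chosen pattern
#' matched the shown one (2-AFC-equivalent; chance 50%); `general` -
#' fully correct choices among all trials of the pattern (chance 25% in
#' 4-AFC); `flow_pattern` - correct-pattern choices regardless of
#' direction (chance 50%).
#'
#' @param trials A trial table.
#' @param mode "intra", "general" or "flow_pattern".
#' @param by_stim Split by the microstimulation flag and report the change?
#' @return With `by_stim = FALSE` a one-row tibble `mode`, `cr`, `n`;
#'   otherwise `mode`, `cr_ctrl`, `cr_stim`, `delta_cr_pp` (percentage
#'   points, stimulated minus control).
#' @export
correct_rate <- function(trials, mode = c("intra", "general", "flow_pattern"),
                         by_stim = FALSE) {
  mode <- match.arg(mode)
  trials <- validate_trials(trials)
  d <- trials |>
    dplyr::filter(.data$plane_shown != "ambiguous") |>
    dplyr::mutate(
      chosen_pattern = ifelse(.data$choice %in% c("CW", "CCW"),
                              "roll", "translation"),
      target = correct_choice(.data$plane_shown, .data$stim_value))
  d <- switch(mode,
    intra = d |>
      dplyr::filter(.data$chosen_pattern == .data$plane_shown) |>
      dplyr::mutate(ok = .data$choice == .data$target),
    general = dplyr::mutate(d, ok = .data$choice == .data$target),
    flow_pattern = dplyr::mutate(d, ok = .data$chosen_pattern ==
                                   .data$plane_shown)
  )
  if (!by_stim) {
    return(tibble::tibble(
      mode = mode,
      cr = if (nrow(d) > 0) mean(d$ok) else NA_real_,
      n = nrow(d)))
  }
  g <- d |>
    dplyr::group_by(.data$microstim) |>
    dplyr::summarise(cr = mean(.data$ok), .groups = "drop")
  cr_ctrl <- g$cr[!g$microstim] %||% NA_real_
  cr_stim <- g$cr[g$microstim] %||% NA_real_
  if (length(cr_ctrl) == 0) cr_ctrl <- NA_real_
  if (length(cr_stim) == 0) cr_stim <- NA_real_
  tibble::tibble(mode = mode, cr_ctrl = cr_ctrl, cr_stim = cr_stim,
                 delta_cr_pp = 100 * (cr_stim - cr_ctrl))
}

#' Sliding-window summary of PSE shifts by direction preference
#'
#' Mean (+/- SEM) of a per-site effect over the sites' preferred
#' directions, using a circular sliding window (default 30 deg bin stepped
#' by 10 deg). Windows containing no sites are omitted.
#'
#' @param effects A data frame with a `preference` column (deg, circular)
#'   and the effect column named by `value`.
#' @param value Name of the effect column (default `dpse_normalized`).
#' @param window Window width, deg.
#' @param step Step between window centres, deg.
#' @return A tibble with `center`, `mean`, `sem`, `n`.
#' @export
bin_dpse_by_preference <- function(effects, value = "dpse_normalized",
                                   window = 30, step = 10) {
  stopifnot("preference" %in% names(effects), value %in% names(effects))
  centers <- seq(-180 + step, 180, by = step)
  purrr::map_dfr(centers, function(ct) {
    d <- ((effects$preference - ct + 180) %% 360) - 180
    inwin <- abs(d) <= window / 2
    if (!any(inwin)) return(NULL)
    v <- effects[[value]][inwin]
    tibble::tibble(center = ct, mean = mean(v),
                   sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  })
}

#' Full per-session microstimulation analysis
#'
#' Runs the whole psychophysical layer on one session: control and
#' stimulated psychometric fits per available axis, probit tests, signed
#' and normalized PSE shifts, the choice-change index (4-AFC only) and the
#' correct-rate changes.
#'
#' @param trials One session's trial table.
#' @param preferred_sign_roll,preferred_sign_trans +1/-1: the stimulated
#'   site's preferred direction on each axis (+1 = CW / leftward).
#' @param construction Psychometric construction for the fits and ΔPSE.
#' @param cr_gate,ambiguous_levels Passed to [cci()].
#' @return A one-row tibble of effects (class `microstim_effect` columns).
#' @export
analyze_session <- function(trials, preferred_sign_roll = 1,
                            preferred_sign_trans = 1,
                            construction = c("normal", "general"),
                            cr_gate = 0.65, ambiguous_levels = NULL) {
  construction <- match.arg(construction)
  trials <- validate_trials(trials)
  paradigm <- trials$paradigm[1] %||% "AFC4"
  planes <- switch(paradigm,
                   AFC2_roll = "roll",
                   AFC2_translation = "translation",
                   c("roll", "translation"))
  one_plane <- function(pl) {
    sign <- if (pl == "roll") preferred_sign_roll else preferred_sign_trans
    res <- try({
      fc <- fit_psychometric(trials, pl, construction, microstim = FALSE)
      fs <- fit_psychometric(trials, pl, construction, microstim = TRUE)
      pt <- probit_stim_test(trials, pl, construction)
      dp <- delta_pse(fc, fs, preferred_sign = sign)
      tibble::tibble(
        plane = pl, mu_ctrl = fc$mu, sigma_ctrl = fc$sigma,
        mu_stim = fs$mu, sigma_stim = fs$sigma,
        converged = fc$converged && fs$converged,
        dpse_raw = dp$dpse_raw, dpse_signed = dp$dpse_signed,
        dpse_normalized = dp$dpse_normalized,
        delta_threshold = dp$delta_threshold,
        p_pse = pt$p_pse, p_slope = pt$p_slope)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      tibble::tibble(plane = pl, mu_ctrl = NA_real_, sigma_ctrl = NA_real_,
                     mu_stim = NA_real_, sigma_stim = NA_real_,
                     converged = FALSE, dpse_raw = NA_real_,
                     dpse_signed = NA_real_, dpse_normalized = NA_real_,
                     delta_threshold = NA_real_, p_pse = NA_real_,
                     p_slope = NA_real_)
    } else res
  }
  eff <- purrr::map_dfr(planes, one_plane) |>
    tidyr::pivot_wider(
      names_from = "plane",
      values_from = c("mu_ctrl", "sigma_ctrl", "mu_stim", "sigma_stim",
                      "converged", "dpse_raw", "dpse_signed",
                      "dpse_normalized", "delta_threshold", "p_pse",
                      "p_slope"))
  cci_row <- if (paradigm == "AFC4") {
    cci(trials, ambiguous_levels = ambiguous_levels, cr_gate = cr_gate)
  } else {
    tibble::tibble(cci = NA_real_, included = NA)
  }
  crs <- purrr::map_dfr(c("intra", "general", "flow_pattern"),
                        function(m) correct_rate(trials, m, by_stim = TRUE))
  dplyr::bind_cols(
    tibble::tibble(session_id = trials$session_id[1], paradigm = paradigm),
    eff,
    tibble::tibble(cci = cci_row$cci, cci_included = cci_row$included,
                   delta_cr_intra = crs$delta_cr_pp[1],
                   delta_cr_general = crs$delta_cr_pp[2],
                   delta_cr_flowpattern = crs$delta_cr_pp[3])
  )
}
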