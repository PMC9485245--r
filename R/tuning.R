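#' Construct a multiunit (MU) recording site
#'
#' An MU site bundles trial-level firing rates measured for spiral-space
#' optic-flow directions in the roll plane and the translation plane, a
#' recording depth along the electrode penetration, a rectangular receptive
#' field (RF), and the spontaneous rate. The two planes share the radial
#' axis: direction 0 is pure expansion (straight forward) and 180 pure
#' contraction in both planes; within the roll plane +/-90 are CW/CCW
#' rotation, within the translation plane +/-90 are leftward/rightward
#' laminar motion (positive = CW or leftward).
#'
#' @param trials A data frame with columns `plane` ("roll"/"translation"),
#'   `direction` (deg), `rep` (integer) and `rate` (spikes/s, >= 0).
#' @param rf A list with elements `center` (length-2, deg), `half_width` and
#'   `half_height` (deg, > 0).
#' @param site_id Identifier.
#' @param depth Depth along the penetration, micrometres (>= 0).
#' @param spontaneous Spontaneous rate, spikes/s.
#' @return An object of class `mu_site`.
#' @export
mu_site <- function(trials, rf = list(center = c(0, 0), half_width = 25,
                                      half_height = 25),
                    site_id = "site1", depth = 0, spontaneous = 0) {
  trials <- tibble::as_tibble(trials)
  stopifnot(all(c("plane", "direction", "rep", "rate") %in% names(trials)))
  if (!all(trials$plane %in% c("roll", "translation"))) {
    stop("plane must be 'roll' or 'translation'", call. = FALSE)
  }
  if (any(trials$rate < 0)) stop("rates must be >= 0", call. = FALSE)
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  if (rf$half_width <= 0 || rf$half_height <= 0) {
    stop("RF half sizes must be positive", call. = FALSE)
  }
  rf$covers_fovea <- abs(rf$center[1]) < rf$half_width &&
    abs(rf$center[2]) < rf$half_height
  structure(
    list(site_id = site_id, depth = depth, spontaneous = spontaneous,
         rf = rf, trials = trials),
    class = "mu_site"
  )
}

#' Summarise a site's tuning curve in one plane
#'
#' @param site A [mu_site()].
#' @param plane "roll" or "translation".
#' @return A tibble with one row per direction: `direction`, `mean_rate`,
#'   `sd_rate`, `n_reps`.
#' @export
tuning_curve <- function(site, plane = c("roll", "translation")) {
  plane <- match.arg(plane)
  site$trials |>
    dplyr::filter(.data$plane == !!plane) |>
    dplyr::group_by(direction = .data$direction) |>
    dplyr::summarise(mean_rate = mean(.data$rate),
                     sd_rate = stats::sd(.data$rate),
                     n_reps = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$direction)
}

#' Generate a synthetic MU site
#'
#' Tuning in each plane is a circular-Gaussian (von Mises shaped) bump over
#' direction, `baseline + amplitude * exp(kappa * (cos(dir - pref) - 1))`,
#' sampled at `directions` with `n_reps` trials each. Trial noise is Poisson
#' (rates over a 1 s window) or Gaussian with a stated Fano factor
#' (variance = fano * mean), truncated at zero.
#'
#' @param pref_roll,pref_trans Preferred direction per plane, deg.
#' @param amp_roll,amp_trans Tuning amplitude per plane, spikes/s (>= 0).
#' @param baseline Baseline rate added in both planes, spikes/s.
#' @param kappa Tuning concentration (> 0; larger = narrower).
#' @param n_reps Trials per direction (>= 3).
#' @param directions Measured directions, deg; default 8 per plane at 45 deg
#'   steps including the radial poles 0 and 180.
#' @param noise "poisson" or "gaussian".
#' @param fano Fano factor for Gaussian noise.
#' @param depth,rf,site_id,spontaneous Passed to [mu_site()].
#' @param seed Optional integer seed; same seed reproduces the site.
#' @return A `mu_site`.
#' @export
synth_mu <- function(pref_roll = 90, pref_trans = 90,
                     amp_roll = 30, amp_trans = 30,
                     baseline = 10, kappa = 1.5, n_reps = 5,
                     directions = seq(-135, 180, by = 45),
                     noise = c("poisson", "gaussian"), fano = 1.5,
                     depth = 0,
                     rf = list(center = c(0, 0), half_width = 25,
                               half_height = 25),
                     site_id = "synth", spontaneous = baseline,
                     seed = NULL) {
  noise <- match.arg(noise)
  if (amp_roll < 0 || amp_trans < 0) stop("amplitudes must be >= 0", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  if (n_reps < 3) stop("need at least 3 reps per direction", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(mu) {
    if (noise == "poisson") {
      stats::rpois(length(mu), lambda = mu)
    } else {
      pmax(0, stats::rnorm(length(mu), mean = mu, sd = sqrt(fano * mu)))
    }
  }
  one_plane <- function(plane, pref, amp) {
    mu <- baseline + amp * exp(kappa * (cos((directions - pref) * pi / 180) - 1))
    tidyr::expand_grid(direction = directions, rep = seq_len(n_reps)) |>
      dplyr::mutate(plane = plane,
                    rate = draw(rep(mu, each = n_reps)))
  }
  trials <- dplyr::bind_rows(
    one_plane("roll", pref_roll, amp_roll),
    one_plane("translation", pref_trans, amp_trans)
  )
  mu_site(trials, rf = rf, site_id = site_id, depth = depth,
          spontaneous = spontaneous)
}

#' Classify an MU site from per-plane ANOVA
#'
#' One-way ANOVA of trial firing rate on direction, run separately in the
#' roll and translation planes with the two radial poles (pure expansion and
#' contraction, shared by the planes) dropped from the test. At the
#' significance level `alpha_level` (default the strict 0.001 rule):
#' `spiral` when both planes are modulated, `roll_only` / `translation_only`
#' when exactly one is, `untuned` otherwise.
#'
#' @param site A [mu_site()].
#' @param alpha_level Per-plane significance level.
#' @return A one-row tibble: `class`, `p_roll`, `p_trans`.
#' @export
classify_site <- function(site, alpha_level = 0.001) {
  stopifnot(inherits(site, "mu_site"))
  p_plane <- function(plane) {
    d <- dplyr::filter(site$trials, .data$plane == !!plane,
                       !(.data$direction %in% c(0, 180)))
    if (nrow(d) == 0 || min(table(d$direction)) < 2) {
      stop("per-trial rates unavailable for ANOVA classification",
           call. = FALSE)
    }
    if (stats::var(d$rate) == 0) return(1) # flat data: no modulation
    stats::anova(stats::lm(rate ~ factor(direction), data = d))$`Pr(>F)`[1]
  }
  p_roll <- p_plane("roll")
  p_trans <- p_plane("translation")
  cls <- if (p_roll < alpha_level && p_trans < alpha_level) "spiral"
  else if (p_roll < alpha_level) "roll_only"
  else if (p_trans < alpha_level) "translation_only"
  else "untuned"
  tibble::tibble(class = cls, p_roll = p_roll, p_trans = p_trans)
}

#' 3D resultant (residual) vector of a site in spiral space
#'
#' Vector sum of mean firing rates times unit direction vectors, with the
#' roll-plane directions embedded in the (forward, roll) coordinate plane
#' and translation-plane directions in the (forward, translation) plane.
#' The radial poles 0/180, measured in both planes, contribute once using
#' the mean of the two planes' measurements. `alpha` is the angle between
#' the resultant and the translation plane, `beta` the angle to the roll
#' plane (both in \[0, 90\] deg).
#'
#' @param site A [mu_site()].
#' @param subtract_spontaneous Subtract the spontaneous rate before summing?
#'   Default `FALSE` (raw mean rates).
#' @return An object of class `spiral_vector`: list with components `f`
#'   (forward), `r` (roll), `t` (translation), `length`, `alpha`, `beta`.
#' @export
resultant_vector <- function(site, subtract_spontaneous = FALSE) {
  stopifnot(inherits(site, "mu_site"))
  curves <- dplyr::bind_rows(
    dplyr::mutate(tuning_curve(site, "roll"), plane = "roll"),
    dplyr::mutate(tuning_curve(site, "translation"), plane = "translation")
  )
  if (subtract_spontaneous) {
    curves$mean_rate <- curves$mean_rate - site$spontaneous
  }
  poles <- curves |>
    dplyr::filter(.data$direction %in% c(0, 180)) |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(mean_rate = mean(.data$mean_rate), .groups = "drop")
  inplane <- dplyr::filter(curves, !(.data$direction %in% c(0, 180)))

  rad <- function(d) d * pi / 180
  f <- sum(inplane$mean_rate * cos(rad(inplane$direction))) +
    sum(poles$mean_rate * cos(rad(poles$direction)))
  r <- sum(inplane$mean_rate[inplane$plane == "roll"] *
             sin(rad(inplane$direction[inplane$plane == "roll"])))
  t <- sum(inplane$mean_rate[inplane$plane == "translation"] *
             sin(rad(inplane$direction[inplane$plane == "translation"])))
  len <- sqrt(f^2 + r^2 + t^2)
  if (len == 0) stop("all-zero rates: no preferred direction", call. = FALSE)
  structure(
    list(f = f, r = r, t = t, length = len,
         alpha = asin(pmin(1, abs(r) / len)) * 180 / pi,
         beta = asin(pmin(1, abs(t) / len)) * 180 / pi),
    class = "spiral_vector"
  )
}

#' Spiral index of a resultant vector
#'
#' `(cos(alpha) - cos(beta)) / (cos(alpha) + cos(beta))`, where `alpha` is
#' the angle of the 3D resultant to the translation plane and `beta` its
#' angle to the roll plane. Ranges over \[-1, 1\]: -1 indicates strong roll
#' preference, +1 strong translation preference, ~0 a site that responds to
#' both flow patterns equally well.
#'
#' @param v A `spiral_vector` from [resultant_vector()].
#' @return A number in \[-1, 1\].
#' @export
spiral_index <- function(v) {
  stopifnot(inherits(v, "spiral_vector"))
  ca <- cos(v$alpha * pi / 180)
  cb <- cos(v$beta * pi / 180)
  if (ca + cb < 1e-12) {
    stop("spiral index undefined for a pure forward/backward vector",
         call. = FALSE)
  }
  (ca - cb) / (ca + cb)
}

#' Direction discriminability (d-prime) in one plane
#'
#' Separation of the responses to the two opposed within-plane directions
#' at +/-90 deg in units of their pooled SD. In the roll plane,
#' `(R_CCW - R_CW) / sqrt((s2_CCW + s2_CW) / 2)` with CW at +90 and CCW at
#' -90; in the translation plane `(R_right - R_left) / sqrt(...)` with
#' leftward at +90 and rightward at -90. Values near 0 indicate weak
#' discriminability; the sign flips when the two condition labels swap.
#'
#' @param site A [mu_site()].
#' @param plane "roll" or "translation".
#' @return A number (signed `Inf` when both SDs are zero but the means
#'   differ; `NaN` when the conditions are identical constants).
#' @export
dprime <- function(site, plane = c("roll", "translation")) {
  plane <- match.arg(plane)
  cv <- tuning_curve(site, plane)
  pos <- dplyr::filter(cv, .data$direction == 90)   # CW or leftward
  neg <- dplyr::filter(cv, .data$direction == -90)  # CCW or rightward
  if (nrow(pos) != 1 || nrow(neg) != 1) {
    stop("plane must contain the +/-90 deg conditions", call. = FALSE)
  }
  pooled <- sqrt((pos$sd_rate^2 + neg$sd_rate^2) / 2)
  (neg$mean_rate - pos$mean_rate) / pooled
}

#' ROC discriminability of two trial-rate samples
#'
#' Area under the ROC curve for discriminating the `positive` distribution
#' from the `negative` one, computed as the normalized Mann-Whitney rank
#' statistic (ties credited 1/2). 0.5 is chance; 1 is perfect separation
#' with `positive` larger.
#'
#' @param positive,negative Numeric vectors of trial rates (>= 3 each).
#' @return AUC in \[0, 1\].
#' @export
roc_discriminability <- function(positive, negative) {
  n1 <- length(positive); n2 <- length(negative)
  if (n1 < 3 || n2 < 3) stop("need at least 3 trials per side", call. = FALSE)
  r <- rank(c(positive, negative))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Tuning-curve clustering index for a pair of sites
#'
#' Pearson correlation of the two mean-rate tuning curves measured in the
#' same plane at the same directions; used to quantify local clustering of
#' tuning for site pairs 100-300 um apart along a penetration. +1 indicates
#' identical tuning shape, -1 opposite tuning.
#'
#' @param site_a,site_b Two [mu_site()] objects.
#' @param plane "roll" or "translation".
#' @return Pearson r in \[-1, 1\], or `NA` when a curve is constant.
#' @export
clustering_index <- function(site_a, site_b,
                             plane = c("roll", "translation")) {
  plane <- match.arg(plane)
  a <- tuning_curve(site_a, plane)
  b <- tuning_curve(site_b, plane)
  if (!identical(a$direction, b$direction)) {
    stop("sites must be measured at the same directions", call. = FALSE)
  }
  if (stats::sd(a$mean_rate) == 0 || stats::sd(b$mean_rate) == 0) {
    return(NA_real_)
  }
  stats::cor(a$mean_rate, b$mean_rate)
}

#' Preferred within-plane direction of a site
#'
#' Angle of the vector sum of mean rates within one plane (deg, in
#' (-180, 180]).
#'
#' @param site A [mu_site()].
#' @param plane "roll" or "translation".
#' @return Preferred direction in degrees.
#' @export
plane_preference <- function(site, plane = c("roll", "translation")) {
  plane <- match.arg(plane)
  cv <- tuning_curve(site, plane)
  rad <- cv$direction * pi / 180
  atan2(sum(cv$mean_rate * sin(rad)), sum(cv$mean_rate * cos(rad))) * 180 / pi
}

#' Flow-similarity index within a site's receptive field
#'
#' Samples the idealized velocity templates of the site's preferred
#' roll-plane and preferred translation-plane flow patterns on a regular
#' grid inside its rectangular RF and returns the proportion of grid points
#' where the two preferred motion vectors differ by less than
#' `angle_threshold` (45 deg by default). 0 means the two preferred flows
#' are locally different (orthogonal or opposed) everywhere in the RF; 1
#' means they are locally the same motion, the situation in which an
#' aperture-limited site could confuse the two patterns. Grid points within
#' `exclusion_radius` of the fovea (where the tangential and radial
#' templates are singular) or with a near-zero vector are excluded.
#'
#' @param site A [mu_site()].
#' @param grid_step Grid spacing, deg.
#' @param exclusion_radius Radius around the fovea to exclude, deg.
#' @param angle_threshold Angle criterion, deg.
#' @return Proportion in \[0, 1\].
#' @export
similarity_index <- function(site, grid_step = 1, exclusion_radius = 0.5,
                             angle_threshold = 45) {
  stopifnot(inherits(site, "mu_site"))
  rf <- site$rf
  gx <- seq(rf$center[1] - rf$half_width, rf$center[1] + rf$half_width,
            by = grid_step)
  gy <- seq(rf$center[2] - rf$half_height, rf$center[2] + rf$half_height,
            by = grid_step)
  grid <- tidyr::expand_grid(x = gx, y = gy) |>
    dplyr::filter(sqrt(.data$x^2 + .data$y^2) > exclusion_radius)
  if (nrow(grid) == 0) stop("degenerate RF: no usable grid points", call. = FALSE)
  vr <- screen_velocity_template(
    flow_spec("roll", plane_preference(site, "roll")), grid)
  vt <- screen_velocity_template(
    flow_spec("translation", plane_preference(site, "translation")), grid)
  mr <- sqrt(vr$vx^2 + vr$vy^2)
  mt <- sqrt(vt$vx^2 + vt$vy^2)
  ok <- mr > 1e-9 & mt > 1e-9
  if (!any(ok)) stop("degenerate RF: no usable grid points", call. = FALSE)
  cosang <- (vr$vx * vt$vx + vr$vy * vt$vy)[ok] / (mr * mt)[ok]
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  mean(ang < angle_threshold)
}

#' Write / read site tables
#'
#' Sites are stored as a CSV with one row per (site, plane, direction, rep)
#' trial plus a JSON sidecar (same path with extension `.json`) holding RF
#' geometry, depth and spontaneous rate per site.
#'
#' @param sites A list of [mu_site()] objects.
#' @param path CSV path.
#' @return `write_sites` returns `path` invisibly; `read_sites` returns a
#'   named list of `mu_site` objects.
#' @export
write_sites <- function(sites, path) {
  trials <- purrr::map_dfr(sites, function(s) {
    dplyr::mutate(s$trials, site_id = s$site_id, .before = 1)
  })
  readr::write_csv(trials, path)
  meta <- purrr::map(sites, function(s) {
    list(site_id = s$site_id, depth = s$depth, spontaneous = s$spontaneous,
         rf_center_x = s$rf$center[1], rf_center_y = s$rf$center[2],
         rf_half_width = s$rf$half_width, rf_half_height = s$rf$half_height)
  })
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sites
#' @param path CSV path written by [write_sites()].
#' @export
read_sites <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = FALSE)
  sites <- purrr::map(meta, function(m) {
    mu_site(
      dplyr::filter(trials, .data$site_id == m$site_id) |>
        dplyr::select(-"site_id"),
      rf = list(center = c(m$rf_center_x, m$rf_center_y),
                half_width = m$rf_half_width,
                half_height = m$rf_half_height),
      site_id = m$site_id, depth = m$depth, spontaneous = m$spontaneous
    )
  })
  stats::setNames(sites, purrr::map_chr(meta, "site_id"))
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @export
print.spiral_vector <- function(x, ...) {
  cat(sprintf(
    "<spiral_vector> f=%.3f r=%.3f t=%.3f |v|=%.3f alpha=%.1f beta=%.1f\n",
    x$f, x$r, x$t, x$length, x$alpha, x$beta))
  invisible(x)
}

#' @export
print.mu_site <- function(x, ...) {
  cat(sprintf("<mu_site> %s: depth %g um, %d trials, RF %gx%g deg at (%g, %g)\n",
              x$site_id, x$depth, nrow(x$trials), 2 * x$rf$half_width,
              2 * x$rf$half_height, x$rf$center[1], x$rf$center[2]))
  invisible(x)
}
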