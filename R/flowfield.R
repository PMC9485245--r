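#' Specify the 3D star-cloud stimulus volume
#'
#' The stimulus is the projected image of a camera moving through a 3D cloud
#' of dots that uniformly fills a rectangular virtual volume in front of the
#' observer. Defaults follow the standard wide-field display configuration:
#' a 100 x 100 x 40 cm volume at 0.01 dots per cubic cm, viewed from ~32 cm
#' so that the screen subtends roughly 90 x 90 degrees of visual angle.
#'
#' The eye sits at the origin looking down the +z axis; the cloud is centred
#' on the viewing distance so every dot starts in front of the eye plane.
#'
#' @param extent_x,extent_y,extent_z Volume extents in cm (all > 0).
#' @param density Dot density in dots per cubic cm (>= 0).
#' @param viewing_distance Distance from the eye to the volume centre, cm.
#' @param fov_x,fov_y Field of view of the display in degrees.
#' @return An object of class `cloud_spec`.
#' @export
#' @examples
#' cloud_spec()
cloud_spec <- function(extent_x = 100, extent_y = 100, extent_z = 40,
                       density = 0.01, viewing_distance = 32,
                       fov_x = 90, fov_y = 90) {
  if (any(c(extent_x, extent_y, extent_z) <= 0)) {
    stop("cloud extents must be positive", call. = FALSE)
  }
  if (density < 0) stop("dot density must be >= 0", call. = FALSE)
  if (viewing_distance <= 0) stop("viewing_distance must be positive", call. = FALSE)
  structure(
    list(extent_x = extent_x, extent_y = extent_y, extent_z = extent_z,
         density = density, viewing_distance = viewing_distance,
         fov_x = fov_x, fov_y = fov_y),
    class = "cloud_spec"
  )
}

cloud_bounds <- function(spec) {
  list(
    x = c(-spec$extent_x / 2, spec$extent_x / 2),
    y = c(-spec$extent_y / 2, spec$extent_y / 2),
    z = spec$viewing_distance + c(-spec$extent_z / 2, spec$extent_z / 2)
  )
}

#' Specify a spiral-space flow pattern
#'
#' A flow pattern lives in one of two orthogonal planes of the spiral space
#' that share the forward/backward radial axis. In the roll plane the angle
#' `theta` mixes radial motion with rotation about the line of sight
#' (positive = clockwise from the observer's view); in the translation plane
#' it mixes radial motion with laminar motion (positive = leftward).
#' `theta = 0` is pure forward (expansion); `theta = +/-90` is pure rotation
#' or pure laminar flow.
#'
#' @param plane `"roll"` or `"translation"`.
#' @param theta Angle from straight-forward within the plane, degrees, in
#'   (-180, 180].
#' @param coherence Fraction of dots moving coherently, in \[0, 1\]. The
#'   remaining dots are re-randomized in the volume on every frame.
#' @param speed_scale Template speed in deg/s at the reference eccentricity
#'   (10 deg); also used as the self-motion speed scale (cm/s for the radial
#'   component, deg/s for rotation) when advancing the dot cloud.
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(plane = c("roll", "translation"), theta = 0,
                      coherence = 1, speed_scale = 10) {
  plane <- match.arg(plane)
  if (theta <= -180 || theta > 180) {
    stop("theta must lie in (-180, 180]", call. = FALSE)
  }
  if (coherence < 0 || coherence > 1) {
    stop("coherence must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(plane = plane, theta = theta, coherence = coherence,
         speed_scale = speed_scale),
    class = "flow_spec"
  )
}

#' Initialize a dot cloud
#'
#' Draws `round(density * volume)` dots i.i.d. uniform in the volume.
#' The same seed always reproduces the same cloud.
#'
#' @param spec A [cloud_spec()].
#' @param seed Optional integer seed.
#' @return A tibble of class `dot_cloud` with columns `dot`, `x`, `y`, `z`
#'   (cm) and attributes `spec` and `frame`.
#' @export
#' @examples
#' nrow(init_cloud(cloud_spec()))  # 4000 dots at the default density
init_cloud <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cloud_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$density * spec$extent_x * spec$extent_y * spec$extent_z)
  b <- cloud_bounds(spec)
  cloud <- tibble::tibble(
    dot = seq_len(n),
    x = stats::runif(n, b$x[1], b$x[2]),
    y = stats::runif(n, b$y[1], b$y[2]),
    z = stats::runif(n, b$z[1], b$z[2])
  )
  new_dot_cloud(cloud, spec, frame = 0L)
}

new_dot_cloud <- function(df, spec, frame) {
  structure(df, spec = spec, frame = frame,
            class = c("dot_cloud", class(tibble::tibble())))
}

#' Advance a dot cloud by one frame
#'
#' A Bernoulli(coherence) draw per dot decides which dots move coherently;
#' the rest are re-drawn uniformly in the volume, so the coherent fraction is
#' binomial around the configured coherence on every frame. Coherent dots
#' follow the camera-motion rule for the flow pattern: the radial component
#' (`cos(theta) * speed_scale` cm/s) moves dots toward the eye, the roll
#' component rotates dots about the line of sight (`sin(theta) * speed_scale`
#' deg/s, positive = clockwise on screen), and the translation component
#' displaces dots laterally (`sin(theta) * speed_scale` cm/s, positive =
#' leftward). Dots leaving the volume are wrapped to the opposite face
#' (re-seeded on the entry face with the other coordinates kept), which keeps
#' the density stationary.
#'
#' @param cloud A `dot_cloud`.
#' @param flow A [flow_spec()].
#' @param dt Frame duration in seconds (> 0).
#' @return A `dot_cloud` with attributes `coherent` and `wrapped` (logical
#'   per-dot vectors for this step).
#' @export
advance_frame <- function(cloud, flow, dt = 1 / 60) {
  stopifnot(inherits(cloud, "dot_cloud"), inherits(flow, "flow_spec"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  spec <- attr(cloud, "spec")
  b <- cloud_bounds(spec)
  n <- nrow(cloud)
  x <- cloud$x; y <- cloud$y; z <- cloud$z
  coh <- stats::runif(n) < flow$coherence

  ct <- cospi(flow$theta / 180)  # exact at the cardinal angles
  st <- sinpi(flow$theta / 180)
  # radial (forward self-motion) component: dots approach the eye
  dz <- -ct * flow$speed_scale * dt
  xn <- x; yn <- y; zn <- z
  zn[coh] <- z[coh] + dz
  if (flow$plane == "roll") {
    # clockwise image rotation for positive theta (+x right, +y up)
    phi <- st * flow$speed_scale * pi / 180 * dt
    xr <- x * cos(phi) + y * sin(phi)
    yr <- -x * sin(phi) + y * cos(phi)
    xn[coh] <- xr[coh]
    yn[coh] <- yr[coh]
  } else {
    # leftward laminar motion for positive theta
    xn[coh] <- x[coh] - st * flow$speed_scale * dt
  }

  wrap <- function(v, lim) lim[1] + (v - lim[1]) %% (lim[2] - lim[1])
  out <- xn < b$x[1] | xn > b$x[2] | yn < b$y[1] | yn > b$y[2] |
    zn < b$z[1] | zn > b$z[2]
  xn <- wrap(xn, b$x); yn <- wrap(yn, b$y); zn <- wrap(zn, b$z)

  # non-coherent dots: fresh uniform position
  k <- sum(!coh)
  if (k > 0) {
    xn[!coh] <- stats::runif(k, b$x[1], b$x[2])
    yn[!coh] <- stats::runif(k, b$y[1], b$y[2])
    zn[!coh] <- stats::runif(k, b$z[1], b$z[2])
  }
  res <- new_dot_cloud(
    tibble::tibble(dot = cloud$dot, x = xn, y = yn, z = zn),
    spec, frame = attr(cloud, "frame") + 1L
  )
  attr(res, "coherent") <- coh
  attr(res, "wrapped") <- out & coh
  res
}

#' Idealized screen-plane velocity template of a flow pattern
#'
#' The first-order template is a linear mix of a radial basis field (vectors
#' away from the fovea, magnitude proportional to eccentricity, speed
#' `speed_scale` at 10 deg) and the plane's secondary basis field: tangential
#' (clockwise for positive theta) in the roll plane, uniform horizontal
#' (leftward for positive theta) in the translation plane. These are the
#' fields drawn in quiver plots of preferred flow and used by the
#' receptive-field flow-similarity analysis.
#'
#' @param flow A [flow_spec()].
#' @param grid A data frame with columns `x`, `y`: screen positions in
#'   degrees (fovea at the origin, +x rightward, +y upward).
#' @return A tibble of class `velocity_field` with columns `x`, `y`,
#'   `vx`, `vy` (deg/s).
#' @export
screen_velocity_template <- function(flow, grid) {
  stopifnot(inherits(flow, "flow_spec"))
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) stop("grid must be non-empty", call. = FALSE)
  ct <- cospi(flow$theta / 180)  # exact at the cardinal angles
  st <- sinpi(flow$theta / 180)
  s <- flow$speed_scale / 10  # deg/s per deg of eccentricity
  rad_x <- s * grid$x
  rad_y <- s * grid$y
  if (flow$plane == "roll") {
    sec_x <- s * grid$y    # clockwise tangential: (y, -x)
    sec_y <- -s * grid$x
  } else {
    sec_x <- rep(-flow$speed_scale, nrow(grid))  # uniform leftward
    sec_y <- rep(0, nrow(grid))
  }
  out <- tibble::tibble(
    x = grid$x, y = grid$y,
    vx = ct * rad_x + st * sec_x,
    vy = ct * rad_y + st * sec_y
  )
  class(out) <- c("velocity_field", class(out))
  out
}

#' Perspective projection of a dot cloud onto the screen
#'
#' Pinhole projection with the eye at the origin: a dot at (x, y, z) maps to
#' (atan(x / z), atan(y / z)) in degrees, so a dot on the optical axis maps
#' to (0, 0). Dots at or behind the eye plane are excluded (their count is
#' reported in a warning); projected dots outside the field of view are
#' clipped.
#'
#' @param cloud A `dot_cloud`.
#' @param clip Drop dots outside the field of view? Default `TRUE`.
#' @return A tibble with columns `dot`, `x_deg`, `y_deg`.
#' @export
project_to_screen <- function(cloud, clip = TRUE) {
  stopifnot(inherits(cloud, "dot_cloud"))
  spec <- attr(cloud, "spec")
  behind <- cloud$z <= 0
  if (any(behind)) {
    warning(sum(behind), " dot(s) at or behind the eye plane excluded",
            call. = FALSE)
  }
  ok <- !behind
  out <- tibble::tibble(
    dot = cloud$dot[ok],
    x_deg = atan2(cloud$x[ok], cloud$z[ok]) * 180 / pi,
    y_deg = atan2(cloud$y[ok], cloud$z[ok]) * 180 / pi
  )
  if (clip) {
    out <- dplyr::filter(out, abs(.data$x_deg) <= spec$fov_x / 2,
                         abs(.data$y_deg) <= spec$fov_y / 2)
  }
  out
}

#' Simulate a multi-frame dot trajectory table
#'
#' Runs [advance_frame()] for `n_frames` steps and returns the long-format
#' per-frame trajectory with both volume (cm) and projected screen (deg)
#' coordinates, suitable for CSV export with [readr::write_csv()].
#'
#' @param spec A [cloud_spec()].
#' @param flow A [flow_spec()].
#' @param n_frames Number of frames to advance.
#' @param dt Frame duration, seconds.
#' @param seed Optional integer seed.
#' @return A tibble with columns `frame`, `dot`, `x_cm`, `y_cm`, `z_cm`,
#'   `x_deg`, `y_deg` (screen coordinates `NA` for clipped dots).
#' @export
cloud_trajectory <- function(spec, flow, n_frames = 10, dt = 1 / 60,
                             seed = NULL) {
  cloud <- init_cloud(spec, seed = seed)
  frames <- vector("list", n_frames + 1)
  snapshot <- function(cl) {
    pr <- suppressWarnings(project_to_screen(cl, clip = FALSE))
    dplyr::left_join(
      tibble::tibble(frame = attr(cl, "frame"), dot = cl$dot,
                     x_cm = cl$x, y_cm = cl$y, z_cm = cl$z),
      pr, by = "dot"
    )
  }
  frames[[1]] <- snapshot(cloud)
  for (i in seq_len(n_frames)) {
    cloud <- advance_frame(cloud, flow, dt = dt)
    frames[[i + 1]] <- snapshot(cloud)
  }
  dplyr::bind_rows(frames)
}

#' Quiver plot of a velocity field
#'
#' @param object A `velocity_field` from [screen_velocity_template()].
#' @param arrow_scale Multiplier from deg/s to arrow length in deg.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.velocity_field <- function(object, arrow_scale = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + arrow_scale * .data$vx,
                   yend = .data$y + arrow_scale * .data$vy),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
      linewidth = 0.3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)") +
    ggplot2::theme_minimal()
}
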