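# build an MU site from exact mean rates (no trial noise) so vector-sum
# statistics can be checked against hand computation
rate_site <- function(roll_rates, trans_rates,
                      directions = seq(-135, 180, by = 45), n_reps = 4,
                      rf = list(center = c(0, 0), half_width = 20,
                                half_height = 20)) {
  stopifnot(length(roll_rates) == length(directions),
            length(trans_rates) == length(directions))
  one <- function(plane, rates) {
    tidyr::expand_grid(direction = directions, rep = seq_len(n_reps)) |>
      dplyr::mutate(plane = plane, rate = rep(rates, each = n_reps))
  }
  mu_site(dplyr::bind_rows(one("roll", roll_rates),
                           one("translation", trans_rates)),
          rf = rf)
}

# rates vector helper: zero everywhere except named directions
rates_at <- function(..., directions = seq(-135, 180, by = 45)) {
  vals <- c(...)
  r <- stats::setNames(rep(0, length(directions)), directions)
  r[names(vals)] <- vals
  unname(r)
}

# independent brute-force 3D vector sum over the measured directions:
# enumerates every (plane, direction) mean rate, embeds roll in the
# (forward, roll) plane and translation in the (forward, translation)
# plane, and averages the shared radial poles across planes
brute_resultant <- function(site) {
  v <- c(f = 0, r = 0, t = 0)
  for (pl in c("roll", "translation")) {
    cv <- tuning_curve(site, pl)
    for (i in seq_len(nrow(cv))) {
      th <- cv$direction[i] * pi / 180
      rate <- cv$mean_rate[i]
      if (cv$direction[i] %in% c(0, 180)) {
        v["f"] <- v["f"] + 0.5 * rate * cos(th)  # pole counted once, averaged
      } else if (pl == "roll") {
        v["f"] <- v["f"] + rate * cos(th)
        v["r"] <- v["r"] + rate * sin(th)
      } else {
        v["f"] <- v["f"] + rate * cos(th)
        v["t"] <- v["t"] + rate * sin(th)
      }
    }
  }
  v
}

# spiral_vector built directly from components (for index invariants)
make_spiral_vector <- function(f, r, t) {
  len <- sqrt(f^2 + r^2 + t^2)
  structure(list(f = f, r = r, t = t, length = len,
                 alpha = asin(abs(r) / len) * 180 / pi,
                 beta = asin(abs(t) / len) * 180 / pi),
            class = "spiral_vector")
}

# all-pairs ROC oracle (ties credited 1/2)
brute_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# a trial table with uniformly random choices over the given targets
uniform_chooser <- function(design, n_per_cond, targets, seed) {
  set.seed(seed)
  conds <- dplyr::bind_rows(
    tibble::tibble(plane_shown = "roll",
                   stim_value = setdiff(design$roll_levels, 0)),
    tibble::tibble(plane_shown = "translation",
                   stim_value = setdiff(design$trans_levels, 0)))
  tr <- conds[rep(seq_len(nrow(conds)), each = n_per_cond), ]
  tr |>
    dplyr::mutate(session_id = "u1", trial = dplyr::row_number(),
                  paradigm = "AFC4", version = design$version,
                  microstim = FALSE,
                  choice = sample(targets, dplyr::n(), replace = TRUE),
                  .before = 1)
}
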