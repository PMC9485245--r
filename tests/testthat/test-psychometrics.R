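make_trials <- function(plane_shown, stim_value, microstim, choice) {
  tibble::tibble(session_id = "t", trial = seq_along(choice),
                 paradigm = "AFC4", version = "fine",
                 plane_shown = plane_shown, stim_value = stim_value,
                 microstim = microstim, choice = choice)
}

test_that("choice tabulation is exhaustive, disjoint and order-invariant", {
  tr <- make_trials("ambiguous", 0, FALSE, c("CW", "CCW", "LEFT", "RIGHT"))
  ct <- build_counts(tr)
  expect_equal(nrow(ct), 1)
  expect_equal(unlist(ct[1, c("cw", "ccw", "left", "right")],
                      use.names = FALSE), rep(1L, 4))
  expect_equal(ct$n, 4L)
  expect_identical(ct, build_counts(tr[sample(4), ]))
  expect_equal(nrow(build_counts(tr[0, ])), 0)
})

test_that("the three psychometric constructions implement their defining
           ratios", {
  tr <- make_trials(
    rep(c("roll", "ambiguous"), c(50, 80)),
    rep(c(2, 0), c(50, 80)),
    FALSE,
    c(rep("CW", 30), rep("CCW", 10), rep("LEFT", 5), rep("RIGHT", 5),
      rep("CW", 10), rep("CCW", 10), rep("LEFT", 30), rep("RIGHT", 30)))
  ct <- build_counts(tr)
  nm <- psychometric_normal(ct, "roll")
  expect_equal(nm$prop[nm$level == 2], 0.75)   # 30 / (30 + 10)
  ge <- psychometric_general(ct, "roll")
  expect_equal(ge$prop[ge$level == 2], 0.6)    # 30 / 50, all four choices
  fp <- psychometric_flowpattern(ct)
  expect_equal(fp$prop[fp$axis == 0], 0.75)    # 60 translation / 80
  expect_equal(fp$prop[fp$axis == -1], 0.2)    # roll level maps to -1

  # levels with an empty within-pattern denominator are missing, not zero
  tr2 <- make_trials("roll", 2, FALSE, c("LEFT", "RIGHT"))
  nm2 <- psychometric_normal(build_counts(tr2), "roll")
  expect_true(is.na(nm2$prop))
  expect_equal(nm2$n_total, 0)

  # general proportion never exceeds the within-pattern proportion
  tr3 <- simulate_session(task_design(reps_per_level = 10),
                          decision_params(), seed = 31)
  ct3 <- build_counts(dplyr::filter(tr3, !microstim))
  j <- dplyr::inner_join(psychometric_normal(ct3, "roll"),
                         psychometric_general(ct3, "roll"),
                         by = c("microstim", "level"),
                         suffix = c("_n", "_g"))
  expect_true(all(j$prop_g <= j$prop_n + 1e-12, na.rm = TRUE))
})

test_that("the cumulative-Gaussian fit recovers exact data to 1e-6 and
           matches probit regression on sampled data", {
  levels <- seq(-8, 8, by = 2)
  mu <- 0.75; sigma <- 3
  # infinite-n limit: exact proportions as fractional successes
  n <- rep(1e6, length(levels))
  s <- n * pnorm((levels - mu) / sigma)
  f <- fit_cumgauss(levels, s, n)
  expect_true(f$converged)
  expect_equal(f$mu, mu, tolerance = 1e-6)
  expect_equal(f$sigma, sigma, tolerance = 1e-6)

  # finite binomial sample: agrees with glm probit ML to high precision
  set.seed(14)
  n2 <- rep(200, length(levels))
  s2 <- rbinom(length(levels), n2, pnorm((levels - mu) / sigma))
  f2 <- fit_cumgauss(levels, s2, n2)
  g <- glm(cbind(s2, n2 - s2) ~ levels, family = binomial("probit"))
  expect_equal(f2$mu, unname(-coef(g)[1] / coef(g)[2]), tolerance = 1e-4)
  expect_equal(f2$sigma, unname(1 / coef(g)[2]), tolerance = 1e-4)

  # the fitted curve passes 0.5 at the PSE and ~84% one threshold above
  expect_equal(pnorm((f2$mu - f2$mu) / f2$sigma), 0.5)
  expect_equal(pnorm((f2$mu + f2$sigma - f2$mu) / f2$sigma), 0.8413,
               tolerance = 1e-4)

  # degenerate data: honest non-convergence
  f3 <- fit_cumgauss(levels, n2, n2)
  expect_false(f3$converged)
  expect_error(fit_cumgauss(c(0, 1), c(1, 2), c(4, 4)), "3 informative")

  td <- tidy(f2)
  expect_equal(td$term, c("pse", "threshold"))
  expect_true(all(is.finite(td$std_error)))
  expect_equal(glance(f2)$n_trials, sum(n2))
})

test_that("probit regression nests the psychometric fit and is invariant to
           trial duplication", {
  tr <- simulate_session(task_design("AFC2_roll", reps_per_level = 30),
                         decision_params(), seed = 15)
  ctrl <- dplyr::filter(tr, !microstim)
  mirrored <- dplyr::bind_rows(ctrl, dplyr::mutate(ctrl, microstim = TRUE))
  pt <- probit_stim_test(mirrored, "roll")
  co <- pt$coefficients
  b0 <- co$estimate[co$term == "(Intercept)"]
  b1 <- co$estimate[co$term == "stim_value"]
  fc <- fit_psychometric(ctrl, "roll")
  expect_equal(unname(-b0 / b1), fc$mu, tolerance = 1e-4)
  expect_equal(unname(1 / b1), fc$sigma, tolerance = 1e-4)
  # identical stim and control halves: stimulation terms are exactly zero
  expect_lt(abs(co$estimate[co$term == "s"]), 1e-8)

  # duplicating every trial leaves coefficient point estimates unchanged
  tr_stim <- simulate_session(
    task_design("AFC2_roll", reps_per_level = 20),
    decision_params(delta_roll = 2), seed = 16)
  p1 <- probit_stim_test(tr_stim, "roll")$coefficients$estimate
  p2 <- probit_stim_test(dplyr::bind_rows(tr_stim, tr_stim),
                         "roll")$coefficients$estimate
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("PSE shifts are signed by the site's preference and normalized by
           the control threshold", {
  mkfit <- function(mu, sigma) {
    structure(list(mu = mu, sigma = sigma, se_mu = 0.1, se_sigma = 0.1,
                   loglik = 0, n_trials = 100, converged = TRUE),
              class = "psychometric_fit")
  }
  expect_equal(delta_pse(mkfit(1, 4), mkfit(1, 4))$dpse_signed, 0)
  dp <- delta_pse(mkfit(0, 4), mkfit(-2, 5), preferred_sign = 1)
  expect_equal(dp$dpse_raw, 2)
  expect_equal(dp$dpse_normalized, 0.5)
  expect_equal(dp$delta_threshold, 1)
  dpn <- delta_pse(mkfit(0, 4), mkfit(-2, 5), preferred_sign = -1)
  expect_equal(dpn$dpse_signed, -2)
  expect_error(delta_pse(mkfit(0, 4), mkfit(0, 4), preferred_sign = 0.5),
               "preferred_sign")
})

test_that("the choice-change index implements its frequency ratio, its gate
           and its lower bound", {
  # 4 ambiguous control trials with 1 translation choice, 4 stim with 2
  tr <- make_trials("ambiguous", 0, rep(c(FALSE, TRUE), each = 4),
                    c("CW", "CW", "CCW", "LEFT",
                      "CW", "CCW", "LEFT", "RIGHT"))
  # attach easy non-ambiguous trials so the gate passes
  easy <- make_trials(rep(c("roll", "translation"), each = 20),
                      rep(c(8, -8, 4, -4), each = 10), FALSE,
                      rep(c("CW", "CCW", "LEFT", "RIGHT"), each = 10))
  only_ref <- list(roll = numeric(), translation = numeric())
  res <- cci(dplyr::bind_rows(tr, easy), ambiguous_levels = only_ref)
  expect_equal(res$cci, 1)          # (0.5 - 0.25) / 0.25
  expect_true(res$included)

  same <- cci(dplyr::bind_rows(
    make_trials("ambiguous", 0, rep(c(FALSE, TRUE), each = 4),
                rep(c("CW", "LEFT", "CW", "LEFT"), 2)), easy),
    ambiguous_levels = only_ref)
  expect_equal(same$cci, 0)

  # gate: a session at chance flow-pattern performance is excluded
  bad <- make_trials(rep("roll", 40), rep(c(8, -8), each = 20), FALSE,
                     rep(c("LEFT", "RIGHT"), 20))
  gated <- cci(dplyr::bind_rows(tr, bad))
  expect_false(gated$included)
  expect_match(gated$reason, "gate")

  # CCI >= -1 over simulated sessions (frequency ratio bound)
  for (sd in 1:5) {
    v <- cci(simulate_session(task_design(version = "coarse",
                                          reps_per_level = 8),
                              decision_params(sigma_roll = 2,
                                              sigma_trans = 2,
                                              model_variant = 3,
                                              pattern_shift = -2),
                              seed = 40 + sd))$cci
    if (!is.na(v)) expect_gte(v, -1)
  }
})

test_that("correct rates hit their chance levels for random choosers and
           1 for a perfect chooser", {
  d <- task_design()
  perfect <- uniform_chooser(d, 10, "CW", seed = 1) |>
    dplyr::mutate(choice = spiralflow:::correct_choice(plane_shown,
                                                       stim_value))
  for (m in c("intra", "general", "flow_pattern")) {
    expect_equal(correct_rate(perfect, m)$cr, 1)
  }
  unif <- uniform_chooser(d, 2000, c("CW", "CCW", "LEFT", "RIGHT"), seed = 2)
  expect_equal(correct_rate(unif, "general")$cr, 0.25, tolerance = 0.01)
  expect_equal(correct_rate(unif, "intra")$cr, 0.5, tolerance = 0.015)
  expect_equal(correct_rate(unif, "flow_pattern")$cr, 0.5, tolerance = 0.01)

  # noise injection on stimulated trials lowers the correct rate
  tr <- dplyr::bind_rows(
    dplyr::filter(simulate_session(d, decision_params(), seed = 17),
                  !microstim),
    dplyr::filter(simulate_session(
      d, decision_params(sigma_roll = 9, sigma_trans = 4.5), seed = 18),
      microstim))
  cr <- correct_rate(tr, "general", by_stim = TRUE)
  expect_lt(cr$delta_cr_pp, 0)
})

test_that("the sliding-window preference profile averages circularly", {
  flat <- tibble::tibble(preference = seq(-170, 180, by = 10),
                         dpse_normalized = 0.4)
  b <- bin_dpse_by_preference(flat)
  expect_true(all(b$mean == 0.4))
  single <- tibble::tibble(preference = 90, dpse_normalized = 1.2)
  b1 <- bin_dpse_by_preference(single)
  expect_true(all(b1$mean == 1.2))
  expect_true(all(abs(((b1$center - 90 + 180) %% 360) - 180) <= 15))

  set.seed(19)
  pop <- tibble::tibble(preference = runif(400, -180, 180)) |>
    dplyr::mutate(dpse_normalized = abs(sin(preference * pi / 180)) +
                    rnorm(400, 0, 0.05))
  prof <- bin_dpse_by_preference(pop)
  peaks <- prof$center[rank(-prof$mean) <= 6]
  expect_true(all(abs(abs(peaks) - 90) <= 30))
})

test_that("analyze_session assembles the per-session effect row", {
  tr <- simulate_session(task_design(reps_per_level = 12),
                         decision_params(delta_roll = 2, delta_trans = 1),
                         seed = 21)
  eff <- analyze_session(tr)
  expect_equal(nrow(eff), 1)
  expect_true(all(c("dpse_signed_roll", "dpse_signed_translation",
                    "p_pse_roll", "cci", "delta_cr_general") %in%
                    names(eff)))
  expect_true(is.finite(eff$dpse_signed_roll))
})
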