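test_that("ANOVA classification separates spiral, single-plane and untuned
           sites", {
  strong <- synth_mu(amp_roll = 60, amp_trans = 60, baseline = 10,
                     n_reps = 8, seed = 1)
  expect_equal(classify_site(strong)$class, "spiral")

  flat <- synth_mu(amp_roll = 0, amp_trans = 0, baseline = 20, n_reps = 8,
                   seed = 2)
  cf <- classify_site(flat)
  expect_equal(cf$class, "untuned")
  expect_gt(cf$p_roll, 0.001)

  # roll-only generative population: translation-only essentially never
  # appears beyond the alpha level
  set.seed(3)
  cls <- purrr::map_chr(1:150, function(i) {
    classify_site(synth_mu(amp_roll = 50, amp_trans = 0, baseline = 8,
                           n_reps = 6))$class
  })
  expect_gte(mean(cls %in% c("roll_only", "untuned")), 0.95)
  expect_lte(mean(cls == "translation_only"), 0.001 + 3 * sqrt(0.001 / 150))
})

test_that("resultant vector embeds the two planes correctly and matches
           brute-force summation", {
  # mass only at roll +/-90 with CW (+90) stronger: pure +roll vector
  s <- rate_site(rates_at(`90` = 30, `-90` = 10), rates_at())
  v <- resultant_vector(s)
  expect_equal(c(v$f, v$r, v$t), c(0, 20, 0))
  expect_equal(v$alpha, 90)
  expect_equal(v$beta, 0)

  # equal mass at roll +90 and translation +90: alpha = beta = 45
  s2 <- rate_site(rates_at(`90` = 25), rates_at(`90` = 25))
  v2 <- resultant_vector(s2)
  expect_equal(v2$alpha, 45)
  expect_equal(v2$beta, 45)
  expect_equal(spiral_index(v2), 0)

  # a pure forward resultant lies in both planes: equal preference, index 0
  expect_equal(spiral_index(make_spiral_vector(5, 0, 0)), 0)

  # radial poles are shared: equal pole rates in both planes count once
  s3 <- rate_site(rates_at(`0` = 10), rates_at(`0` = 10))
  expect_equal(resultant_vector(s3)$f, 10)

  # random curves: match the independent enumeration oracle to 1e-10
  set.seed(42)
  for (i in 1:10) {
    s <- rate_site(runif(8, 0, 50), runif(8, 0, 50))
    v <- resultant_vector(s)
    b <- brute_resultant(s)
    expect_equal(c(v$f, v$r, v$t), unname(b), tolerance = 1e-10)
  }
  expect_error(resultant_vector(rate_site(rates_at(), rates_at())),
               "all-zero")
})

test_that("spiral index hits its extremes, is antisymmetric in the two
           planes and bounded", {
  expect_equal(spiral_index(make_spiral_vector(0, 5, 0)), -1)
  expect_equal(spiral_index(make_spiral_vector(0, 0, 5)), 1)
  set.seed(9)
  for (i in 1:50) {
    f <- runif(1, 0, 10); r <- runif(1, 0, 10); t <- runif(1, 0, 10)
    si <- spiral_index(make_spiral_vector(f, r, t))
    expect_lte(abs(si), 1)
    expect_equal(si, -spiral_index(make_spiral_vector(f, t, r)),
                 tolerance = 1e-12)
  }
})

test_that("d-prime matches its defining arithmetic and flips sign with the
           condition labels", {
  # CCW (-90) trials {20,30,40}: mean 30, sd 10; CW (+90) {0,10,20}: mean 10
  mk <- function(ccw, cw) {
    trials <- dplyr::bind_rows(
      tidyr::expand_grid(plane = "roll", direction = seq(-135, 180, 45),
                         rep = 1:3) |>
        dplyr::mutate(rate = 5),
      tibble::tibble(plane = "roll", direction = -90, rep = 1:3, rate = ccw),
      tibble::tibble(plane = "roll", direction = 90, rep = 1:3, rate = cw),
      tidyr::expand_grid(plane = "translation",
                         direction = seq(-135, 180, 45), rep = 1:3) |>
        dplyr::mutate(rate = 5))
    mu_site(dplyr::filter(trials, !(plane == "roll" &
                                      direction %in% c(-90, 90) &
                                      rate == 5)))
  }
  s <- mk(c(20, 30, 40), c(0, 10, 20))
  expect_equal(dprime(s, "roll"), 2)
  expect_equal(dprime(mk(c(0, 10, 20), c(20, 30, 40)), "roll"), -2)
  expect_equal(dprime(s, "translation"), NaN)  # equal constant conditions
})

test_that("ROC discriminability equals the all-pairs oracle and hits the
           chance and perfect limits", {
  expect_equal(roc_discriminability(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_discriminability(c(10, 11, 12), c(1, 2, 3)), 1)
  expect_equal(roc_discriminability(c(1, 2, 3), c(10, 11, 12)), 0)
  set.seed(5)
  for (i in 1:20) {
    pos <- rpois(sample(3:20, 1), 8)   # integer rates force ties
    neg <- rpois(sample(3:20, 1), 6)
    expect_equal(roc_discriminability(pos, neg), brute_auc(pos, neg))
  }
  expect_error(roc_discriminability(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("clustering index behaves like a tuning-curve correlation", {
  base <- c(20, 25, 35, 45, 35, 25, 20, 19)
  a <- rate_site(base, rep(1, 8))
  expect_equal(clustering_index(a, a, "roll"), 1)
  flipped <- rate_site(2 * mean(base) - base, rep(1, 8))
  expect_equal(clustering_index(a, flipped, "roll"), -1)
  expect_true(is.na(clustering_index(a, rate_site(rep(3, 8), rep(1, 8)),
                                     "roll")))
  set.seed(6)
  rs <- replicate(300, clustering_index(rate_site(runif(8), rep(1, 8)),
                                        rate_site(runif(8), rep(1, 8)),
                                        "roll"))
  expect_lt(abs(mean(rs)), 3 / sqrt(300))  # null pairs: mean r near 0
})

test_that("flow-similarity index matches its analytic cases and is stable
           under grid refinement", {
  # both preferred flows pure expansion: identical templates everywhere
  s_same <- rate_site(rates_at(`0` = 40), rates_at(`0` = 40))
  expect_equal(similarity_index(s_same), 1)

  # pure CW rotation vs pure leftward laminar over a fovea-centred RF:
  # the tangential direction is uniform in polar angle, so the wedge
  # within 45 degrees of a fixed direction covers a quarter of the RF
  s_quarter <- rate_site(rates_at(`90` = 40), rates_at(`90` = 40))
  expect_lt(abs(similarity_index(s_quarter) - 0.25), 0.02)
  expect_lt(abs(similarity_index(s_quarter, grid_step = 0.5) -
                  similarity_index(s_quarter, grid_step = 1)), 0.02)

  # a mixed, off-centre configuration: in (0,1) and grid-stable
  s_mix <- synth_mu(pref_roll = 60, pref_trans = -120, amp_roll = 40,
                    amp_trans = 30, baseline = 6, n_reps = 5, seed = 8,
                    rf = list(center = c(12, 8), half_width = 15,
                              half_height = 10))
  si1 <- similarity_index(s_mix, grid_step = 1)
  expect_gt(si1, 0); expect_lt(si1, 1)
  expect_lt(abs(similarity_index(s_mix, grid_step = 0.5) - si1), 0.02)
})

test_that("synthetic sites are reproducible and recover their spiral-index
           targets", {
  expect_identical(synth_mu(seed = 10)$trials, synth_mu(seed = 10)$trials)

  set.seed(20)
  targets <- runif(40, -1, 1)
  recovered <- purrr::map_dbl(targets, function(si) {
    # amplitude split (1-si)/2 roll vs (1+si)/2 translation at +/-90 peaks
    s <- synth_mu(pref_roll = 90, pref_trans = 90,
                  amp_roll = 60 * (1 - si) / 2,
                  amp_trans = 60 * (1 + si) / 2,
                  baseline = 3, kappa = 6, n_reps = 10)
    spiral_index(resultant_vector(s))
  })
  expect_gt(cor(targets, recovered), 0.9)
})

test_that("site tables round-trip through CSV + JSON sidecar", {
  sites <- list(synth_mu(site_id = "a", depth = 100, seed = 1),
                synth_mu(site_id = "b", depth = 200, seed = 2,
                         rf = list(center = c(10, -5), half_width = 12,
                                   half_height = 18)))
  path <- file.path(tempdir(), "sites.csv")
  write_sites(sites, path)
  back <- read_sites(path)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$b$rf$center, c(10, -5))
  expect_equal(back$a$trials$rate, sites[[1]]$trials$rate)
  expect_equal(back$b$depth, 200)
})
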