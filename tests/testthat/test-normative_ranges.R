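# Hand-built normative model with known curve, spread and transform, for
# exercising interval and scoring mechanics without a stochastic fit.
toy_model <- function(kind = "none", shift = 0,
                      coefs = c(a0 = 0, a1 = 1, a2 = 0, a3 = 0, a4 = 10),
                      intercept = 1, slope = 0) {
  curve <- structure(
    list(family = "quadratic", coefficients = coefs, includes_hand = TRUE,
         n_params = 5L, test_r2 = 0.9, sse = 0, converged = TRUE,
         fold = 1L, fold_r2 = NULL, seed = 1L),
    class = "devnorm_curve"
  )
  resid <- structure(
    list(intercept = intercept, slope = slope, n = 500L, dof = 7L,
         test_r2 = NA_real_, floor = 1e-9, eq4_root = "outside"),
    class = "devnorm_residual"
  )
  structure(
    list(parameter = "toy", curve = curve, residual = resid,
         transform = structure(list(kind = kind, shift = shift),
                               class = "devnorm_transform"),
         gate = NULL, outliers = NULL, zset = NULL,
         coding = list(sex = c(female = 0, male = 1),
                       hand = c(non_dominant = 0, dominant = 1)),
         includes_hand = TRUE, age_range = c(5, 18), n = 500L,
         config = pipeline_config(seed = 1)),
    class = "devnorm_model"
  )
}

test_that("interval bounds are symmetric around the center and vanish as coverage does", {
  nm <- toy_model()
  iv <- interval_curve(nm, ages = c(5, 10, 18))
  expect_equal(iv$center, (iv$lower + iv$upper) / 2, tolerance = 1e-10)
  expect_true(all(iv$lower <= iv$center & iv$center <= iv$upper))
  expect_equal(iv$width, 2 * qnorm(0.975) * scale_factor(nm$residual, iv$age),
               tolerance = 1e-10)

  tiny <- interval_curve(nm, ages = c(5, 18), coverage = 1e-9)
  expect_true(all(tiny$width < 1e-6))
  expect_error(interval_curve(nm, coverage = 1.2), "coverage")
})

test_that("back-transformed bounds stay ordered for every transform kind", {
  for (kind in c("none", "log", "sqrt", "inverse")) {
    nm <- toy_model(kind = kind, shift = 2,
                    coefs = c(a0 = 0, a1 = 0.1, a2 = 0, a3 = 0, a4 = 2),
                    intercept = 0.4, slope = -0.01)
    iv <- interval_curve(nm, ages = seq(5, 18, by = 1))
    expect_true(all(iv$lower <= iv$center + 1e-12), info = kind)
    expect_true(all(iv$center <= iv$upper + 1e-12), info = kind)
    expect_true(all(iv$width > 0), info = kind)
  }
})

test_that("interval width change reproduces worked report arithmetic", {
  expect_equal(round_half_away(interval_width_change(0.2680, 0.0685)), -74)
  expect_equal(round_half_away(interval_width_change(0.6874, 0.1867)), -73)
  expect_equal(interval_width_change(0.4, 0.4), 0)
  expect_error(interval_width_change(0, 0.1), "positive")
})

test_that("mean curve change handles flat, doubling and undefined baselines", {
  flat <- toy_model(coefs = c(a0 = 0, a1 = 0, a2 = 0, a3 = 0, a4 = 4))
  expect_equal(mean_curve_change(flat), 0)

  # linear curve doubling from age 5 to 18: value 13 -> 26
  dbl <- toy_model(coefs = c(a0 = 0, a1 = 1, a2 = 0, a3 = 0, a4 = 8))
  expect_equal(mean_curve_change(dbl), 100)

  # exponential ground truth: change matches direct endpoint arithmetic
  tab <- sim_cohort(288, hits_truth(), seed = 3)
  nm <- run_pipeline(tab, "hits", pipeline_config(seed = 3))
  got <- mean_curve_change(nm)
  a <- nm$curve$coefficients
  manual <- 100 * ((a[["a0"]] * exp(a[["a1"]] * 18) + a[["a4"]]) -
                   (a[["a0"]] * exp(a[["a1"]] * 5) + a[["a4"]])) /
    (a[["a0"]] * exp(a[["a1"]] * 5) + a[["a4"]])
  expect_equal(got, manual, tolerance = 1e-10)

  zero <- toy_model(coefs = c(a0 = 0, a1 = 1, a2 = 0, a3 = 0, a4 = -5))
  expect_error(mean_curve_change(zero), "undefined")
})

test_that("fixed-width comparisons reproduce worked report arithmetic", {
  expect_equal(round_half_away(fixed_vs_changing_width(0.268, 0.2)), 34)
  expect_equal(round_half_away(fixed_vs_changing_width(0.693, 0.4)), 73)
  expect_equal(round_half_away(fixed_vs_changing_width(0.210, 0.4)), -48)
  expect_error(fixed_vs_changing_width(0.2, 0), "positive")
})

test_that("scoring flags |z| beyond the cutoff and reproduces training z-scores", {
  nm <- toy_model()  # s = sqrt(pi/2) * 500/493 at every age
  s <- scale_factor(nm$residual, 10)
  mu <- predict(nm$curve, 10, 0, 0)
  sc <- score_participant(nm, age = c(10, 10, 10), sex = 0, hand = 0,
                          value = mu + c(0, 2.4 * s, -2.4 * s))
  expect_equal(sc$z, c(0, 2.4, -2.4), tolerance = 1e-10)
  expect_equal(sc$deficit, c(FALSE, TRUE, TRUE))
  expect_warning(score_participant(nm, 20, 0, 0, mu), "extrapolat")
  expect_error(score_participant(nm, 10, 2, 0, mu), "sex and hand")

  # a fitted model reproduces the stored z of every training row exactly
  tab <- sim_cohort(150, hits_truth(), seed = 5)
  fitted <- run_pipeline(tab, "hits", pipeline_config(seed = 5))
  sc2 <- score_participant(fitted, tab$age, tab$sex, tab$hand, tab$value)
  expect_equal(sc2$z, fitted$zset$z, tolerance = 1e-10)
})

test_that("bootstrap bands are seeded, degenerate at zero noise, and shrink with n", {
  # a4 = -5 keeps values spanning zero so the quadratic family is selected
  zero_truth <- ground_truth("quadratic", a0 = 0.1, a1 = -1, a4 = -5,
                             noise_intercept = 0, noise_slope = 0,
                             per_hand = TRUE, parameter = "p")
  tab0 <- sim_cohort(60, zero_truth, seed = 7)
  expect_warning(
    ci0 <- bootstrap_curve_ci(tab0, pipeline_config(seed = 7),
                              ages = c(6, 12, 17), B = 50),
    "small"
  )
  expect_true(all(ci0$center[2, ] - ci0$center[1, ] < 1e-6))

  noisy <- ground_truth("quadratic", a0 = 0.1, a1 = -1, a4 = -5,
                        noise_intercept = 1.2, noise_slope = 0,
                        per_hand = TRUE, parameter = "p")
  tab1 <- sim_cohort(80, noisy, seed = 8)
  tab2 <- sim_cohort(320, noisy, seed = 8)
  ci1 <- bootstrap_curve_ci(tab1, pipeline_config(seed = 9),
                            ages = c(8, 12, 16), B = 120)
  ci1b <- bootstrap_curve_ci(tab1, pipeline_config(seed = 9),
                             ages = c(8, 12, 16), B = 120)
  expect_identical(ci1, ci1b)
  ci2 <- bootstrap_curve_ci(tab2, pipeline_config(seed = 9),
                            ages = c(8, 12, 16), B = 120)
  w1 <- mean(ci1$center[2, ] - ci1$center[1, ])
  w2 <- mean(ci2$center[2, ] - ci2$center[1, ])
  expect_lt(w2, w1)
})
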