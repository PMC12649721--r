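make_table <- function(n, seed, ages = NULL) {
  set.seed(seed)
  data.frame(
    age = if (is.null(ages)) runif(n, 5, 18) else ages,
    sex = rep_len(c(0L, 1L), n),
    hand = rep_len(c(0L, 0L, 1L), n),
    value = NA_real_
  )
}

test_that("family selection keys on strict positivity", {
  expect_equal(select_family(c(0.3, 0.5, 1.2)), "exponential")
  expect_equal(select_family(c(-0.1, 0.2)), "quadratic")
  expect_equal(select_family(c(0.0, 1.0)), "quadratic")
  expect_error(select_family(numeric(0)), "non-empty")
})

test_that("log-linearized initial estimates recover a noiseless exponential", {
  age <- seq(5, 18, length.out = 30)
  init <- foss_initial_estimates(age, 2 * exp(-0.1 * age))
  expect_equal(init[["a0"]], 2, tolerance = 1e-8)
  expect_equal(init[["a1"]], -0.1, tolerance = 1e-8)

  flat <- foss_initial_estimates(age, rep(5, 30))
  expect_equal(flat[["a1"]], 0, tolerance = 1e-10)
  expect_equal(flat[["a0"]], 5, tolerance = 1e-8)

  expect_error(foss_initial_estimates(age, c(-1, rep(1, 29))), "positive")

  # noisy case: inits within 20% of truth at n = 500
  set.seed(7)
  age2 <- runif(500, 5, 18)
  y <- 3 * exp(-0.12 * age2) * exp(rnorm(500, 0, 0.1))
  init2 <- foss_initial_estimates(age2, y)
  expect_lt(abs(init2[["a0"]] - 3) / 3, 0.2)
  expect_lt(abs(init2[["a1"]] + 0.12) / 0.12, 0.2)
})

test_that("quadratic fit interpolates noiseless data and matches the normal equations", {
  tab <- make_table(30, 21)
  tab$value <- tab$age^2 - 2 * tab$age + 3
  fit <- fit_quadratic(tab, includes_hand = TRUE)
  expect_equal(unname(fit$coefficients[c("a0", "a1", "a4")]), c(1, -2, 3),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[c("a2", "a3")]), c(0, 0),
               tolerance = 1e-8)

  # independent oracle: explicit normal-equations solve on random data
  set.seed(22)
  for (i in 1:5) {
    tab <- make_table(30, 100 + i)
    tab$value <- rnorm(30, sd = 3)
    X <- cbind(tab$age^2, tab$age, tab$sex, tab$hand, 1)
    beta <- solve(t(X) %*% X, t(X) %*% tab$value)
    fit <- fit_quadratic(tab, includes_hand = TRUE)
    expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
  }

  tab$value <- rep(7, 30)
  fit7 <- fit_quadratic(tab, includes_hand = TRUE)
  expect_equal(unname(fit7$coefficients), c(0, 0, 0, 0, 7), tolerance = 1e-8)

  same_age <- make_table(30, 23, ages = rep(10, 30))
  same_age$value <- rnorm(30)
  expect_error(fit_quadratic(same_age, TRUE), "collinear")
})

test_that("exponential fit recovers a noiseless curve and matches nls on noisy data", {
  tab <- make_table(60, 31)
  tab$value <- 1.5 * exp(-0.2 * tab$age) + 0.05 * tab$sex + 0.1
  fit <- fit_exponential(tab, includes_hand = FALSE)
  expect_equal(unname(fit$coefficients[c("a0", "a1", "a2", "a4")]),
               c(1.5, -0.2, 0.05, 0.1), tolerance = 1e-4)
  expect_true(fit$converged)

  # cross-check against stats::nls as an independent optimizer
  set.seed(33)
  tab2 <- make_table(200, 32)
  tab2$value <- 2 * exp(0.08 * tab2$age) + 0.5 * tab2$sex + 0.3 * tab2$hand +
    1 + rnorm(200, 0, 0.4)
  mine <- fit_exponential(tab2, includes_hand = TRUE)
  ref <- nls(value ~ a0 * exp(a1 * age) + a2 * sex + a3 * hand + a4,
             data = tab2,
             start = list(a0 = 2, a1 = 0.08, a2 = 0.5, a3 = 0.3, a4 = 1))
  expect_equal(mine$sse, sum(resid(ref)^2), tolerance = 1e-6)
  expect_equal(unname(mine$coefficients), unname(coef(ref)[c("a0", "a1", "a2", "a3", "a4")]),
               tolerance = 1e-3)
})

test_that("nested-model SSE bounds hold for the exponential fit", {
  set.seed(41)
  tab <- make_table(120, 41)
  tab$value <- 5 + rnorm(120, 0, 0.5)  # flat truth (a1 = 0)
  fit <- fit_exponential(tab, includes_hand = TRUE)
  flat_sse <- sum((tab$value - mean(tab$value))^2)
  expect_lte(fit$sse, flat_sse + 1e-8)

  # adding the hand covariate never increases training SSE
  tab$value <- 2 * exp(0.05 * tab$age) + 0.3 * tab$hand + rnorm(120, 0, 0.3)
  with_hand <- fit_exponential(tab, includes_hand = TRUE)
  without <- fit_exponential(tab, includes_hand = FALSE)
  expect_lte(with_hand$sse, without$sse + 1e-6)
})

test_that("cross-validated selection returns the best fold model deterministically", {
  cfg <- pipeline_config(seed = 5)
  tab <- make_table(100, 51)
  tab$value <- 0.5 * tab$age^2 - 3 * tab$age + 2 * tab$sex + 1 * tab$hand + 4

  # noiseless: every fold is perfect and the truth is reproduced
  cv <- kfold_cv_fit(tab, cfg, family = "quadratic", includes_hand = TRUE)
  expect_equal(cv$fold_r2, rep(1, 10), tolerance = 1e-8)
  expect_equal(unname(cv$coefficients), c(0.5, -3, 2, 1, 4), tolerance = 1e-6)

  set.seed(52)
  tab$value <- tab$value + rnorm(100, 0, 2)
  cv1 <- kfold_cv_fit(tab, cfg, family = "quadratic", includes_hand = TRUE)
  cv2 <- kfold_cv_fit(tab, cfg, family = "quadratic", includes_hand = TRUE)
  expect_identical(cv1$coefficients, cv2$coefficients)
  expect_identical(cv1$fold, cv2$fold)

  # definitional: winner's held-out R^2 is the max over all stored folds
  expect_equal(cv1$test_r2, max(cv1$fold_r2, na.rm = TRUE))
  expect_length(cv1$fold_r2, 10)
  expect_length(attr(cv1, "fold_models"), 10)
  expect_error(kfold_cv_fit(tab[1:5, ], cfg, "quadratic", TRUE), "k_folds")
})

test_that("predict evaluates the family formulas at given covariates", {
  quad <- fit_quadratic(
    within(make_table(30, 61), value <- age^2 - 2 * age + 3), TRUE)
  expect_equal(predict(quad, age = 2, sex = 0, hand = 0), 3, tolerance = 1e-8)

  tab <- make_table(40, 62)
  tab$value <- 2 * exp(0 * tab$age) + 1  # flat: a0 + a4 = 3
  expf <- fit_exponential(tab, init = c(a0 = 2, a1 = 0, a4 = 1),
                          includes_hand = FALSE)
  expect_equal(predict(expf, age = c(5, 12, 18)), rep(3, 3), tolerance = 1e-6)

  # a dummy sex offset shifts predictions by the same amount at every age
  tab$value <- 2 * exp(0.05 * tab$age) + 8 * tab$sex + 1
  fit <- fit_exponential(tab, includes_hand = FALSE)
  ages <- seq(5, 18, by = 1)
  expect_equal(predict(fit, ages, sex = 1) - predict(fit, ages, sex = 0),
               rep(8, length(ages)), tolerance = 1e-4)
})
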