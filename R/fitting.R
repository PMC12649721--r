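#' Choose the curve family for a parameter
#'
#' Strictly positive parameters get a decaying/growing exponential trend in
#' age; any parameter containing zero or negative values gets a quadratic
#' trend instead, because the log-linearized initial estimates for the
#' exponential are undefined there (the logarithm of a non-positive value
#' is not finite).
#'
#' @param values Numeric vector of observed parameter values.
#' @return `"exponential"` or `"quadratic"`.
#' @export
#' @examples
#' select_family(c(0.3, 0.5, 1.2))  # exponential
#' select_family(c(-0.1, 0.2))      # quadratic
select_family <- function(values) {
  if (length(values) == 0) stopf("values must be non-empty")
  if (all(values > 0)) "exponential" else "quadratic"
}

#' Log-linearized initial estimates for the exponential curve
#'
#' Fits a straight line to `log(value)` versus age; the intercept and slope
#' of that line give starting values `a0 = exp(intercept)`, `a1 = slope`
#' for the nonlinear exponential fit, which needs a good starting point to
#' converge reliably. The exponential curve carries an additive offset the
#' pure log-linearization cannot see: when the smallest value sits close to
#' zero relative to the largest (min < 0.1 * max), 90% of the minimum is
#' subtracted before taking logs and returned as the offset estimate
#' `a4_init`; otherwise `a4_init = 0`.
#'
#' @param ages Numeric vector of ages.
#' @param values Strictly positive numeric vector, same length.
#' @return Named vector `c(a0, a1, a4)` of initial estimates.
#' @export
#' @examples
#' age <- 5:18
#' foss_initial_estimates(age, 2 * exp(-0.1 * age))
foss_initial_estimates <- function(ages, values) {
  if (length(ages) != length(values)) stopf("ages and values must have equal length")
  if (any(values <= 0)) {
    stopf("log-linearization requires strictly positive values (min = %g)", min(values))
  }
  shift <- 0
  if (min(values) < 0.1 * max(values)) shift <- 0.9 * min(values)
  w <- values - shift
  fit <- stats::lm.fit(cbind(1, ages), log(w))
  b <- fit$coefficients
  c(a0 = unname(exp(b[1])), a1 = unname(b[2]), a4 = shift)
}

# --- curve model object -----------------------------------------------------

new_curve_model <- function(family, coefficients, includes_hand,
                            test_r2 = NA_real_, sse = NA_real_,
                            converged = TRUE, fold = NA_integer_,
                            fold_r2 = NULL, seed = NA_integer_) {
  structure(
    list(
      family = family,
      coefficients = coefficients,  # named a0..a4 (a3 fixed at 0 without hand term)
      includes_hand = includes_hand,
      n_params = if (family == "linear") 2L else if (includes_hand) 5L else 4L,
      test_r2 = test_r2,
      sse = sse,
      converged = converged,
      fold = fold,
      fold_r2 = fold_r2,
      seed = seed
    ),
    class = "devnorm_curve"
  )
}

#' Evaluate a fitted curve at given covariates
#'
#' @param object A fitted `devnorm_curve`.
#' @param age Numeric vector of ages (years).
#' @param sex,hand Dummy codes in `{0, 1}` (recycled).
#' @param ... Unused.
#' @return Predicted parameter values.
#' @export
predict.devnorm_curve <- function(object, age, sex = 0, hand = 0, ...) {
  a <- object$coefficients
  switch(object$family,
    exponential = a[["a0"]] * exp(a[["a1"]] * age) + a[["a2"]] * sex + a[["a3"]] * hand + a[["a4"]],
    quadratic   = a[["a0"]] * age^2 + a[["a1"]] * age + a[["a2"]] * sex + a[["a3"]] * hand + a[["a4"]],
    linear      = a[["a4"]] + a[["a1"]] * age,
    stopf("unknown curve family '%s'", object$family)
  )
}

#' @export
print.devnorm_curve <- function(x, ...) {
  cat(sprintf("%s curve (%s hand term)\n", x$family,
              if (x$includes_hand) "with" else "without"))
  print(signif(x$coefficients, 6))
  if (!is.na(x$test_r2)) cat(sprintf("held-out R^2: %.4f (fold %d)\n", x$test_r2, x$fold))
  invisible(x)
}

# Design matrix for the linear-in-coefficients families.
linear_design <- function(family, table, includes_hand) {
  cols <- switch(family,
    quadratic = {
      X <- cbind(age2 = table$age^2, age = table$age, sex = table$sex)
      if (includes_hand) X <- cbind(X, hand = table$hand)
      cbind(X, intercept = 1)
    },
    linear = cbind(intercept = 1, age = table$age),
    stopf("no linear design for family '%s'", family)
  )
  cols
}

# Solve OLS with an explicit rank check naming the collinear columns.
ols_solve <- function(X, y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stopf("rank-deficient design: collinear column(s) %s", paste(bad, collapse = ", "))
  }
  qr.coef(qrx, y)
}

#' Ordinary least-squares quadratic curve fit
#'
#' Fits `value = a0 * age^2 + a1 * age + a2 * sex (+ a3 * hand) + a4` by
#' OLS. A noiseless quadratic is reproduced exactly (up to numerical
#' round-off).
#'
#' @param table Data frame with columns `age`, `sex`, `hand`, `value`.
#' @param includes_hand Include the hand dummy covariate?
#' @return A `devnorm_curve`.
#' @export
fit_quadratic <- function(table, includes_hand = TRUE) {
  need <- if (includes_hand) 5L else 4L
  if (nrow(table) < need) stopf("need at least %d observations, got %d", need, nrow(table))
  X <- linear_design("quadratic", table, includes_hand)
  beta <- ols_solve(X, table$value)
  coefs <- c(a0 = unname(beta["age2"]), a1 = unname(beta["age"]),
             a2 = unname(beta["sex"]),
             a3 = if (includes_hand) unname(beta["hand"]) else 0,
             a4 = unname(beta["intercept"]))
  fitted <- as.numeric(X %*% beta)
  new_curve_model("quadratic", coefs, includes_hand,
                  sse = sum((table$value - fitted)^2))
}

# OLS line fit |r| ~ age, packaged as a curve model (family "linear",
# a4 = intercept, a1 = slope).
fit_line <- function(table) {
  X <- linear_design("linear", table, FALSE)
  beta <- ols_solve(X, table$value)
  coefs <- c(a0 = 0, a1 = unname(beta["age"]), a2 = 0, a3 = 0,
             a4 = unname(beta["intercept"]))
  fitted <- as.numeric(X %*% beta)
  new_curve_model("linear", coefs, FALSE,
                  sse = sum((table$value - fitted)^2))
}

#' Exponential curve fit by damped least squares
#'
#' Minimizes the sum of squared errors of
#' `value = a0 * exp(a1 * age) + a2 * sex (+ a3 * hand) + a4` with a
#' Levenberg-Marquardt-style damped Gauss-Newton iteration and an analytic
#' Jacobian. Starting values come from [foss_initial_estimates()] unless
#' supplied. Convergence is declared when the relative SSE change falls
#' below the configured tolerance; hitting the iteration cap flags the fit
#' as non-converged.
#'
#' @param table Data frame with columns `age`, `sex`, `hand`, `value`.
#' @param init Optional named vector with elements `a0`, `a1`, `a4`
#'   (covariate coefficients always start at 0).
#' @param includes_hand Include the hand dummy covariate?
#' @param max_iterations Iteration cap.
#' @param convergence_tolerance Relative SSE-change tolerance.
#' @return A `devnorm_curve` with the converged coefficients and final SSE.
#' @export
fit_exponential <- function(table, init = NULL, includes_hand = TRUE,
                            max_iterations = 1000L,
                            convergence_tolerance = 1e-10) {
  if (is.null(init)) init <- foss_initial_estimates(table$age, table$value)
  y <- table$value
  age <- table$age
  sex <- table$sex
  hand <- if (includes_hand) table$hand else NULL
  p <- c(init[["a0"]], init[["a1"]], 0, if (includes_hand) 0, init[["a4"]])

  model_fun <- function(p) {
    mu <- p[1] * exp(p[2] * age) + p[3] * sex + p[length(p)]
    if (includes_hand) mu <- mu + p[4] * hand
    mu
  }
  jac_fun <- function(p) {
    e <- exp(p[2] * age)
    J <- cbind(e, p[1] * age * e, sex)
    if (includes_hand) J <- cbind(J, hand)
    cbind(J, 1)
  }

  r <- y - model_fun(p)
  sse <- sum(r^2)
  if (!is.finite(sse)) stopf("initial estimates produce non-finite predictions")
  lambda <- 1e-3
  converged <- FALSE
  for (iter in seq_len(max_iterations)) {
    J <- jac_fun(p)
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    improved <- FALSE
    for (inner in 1:30) {
      step <- tryCatch(
        solve(JtJ + lambda * diag(diag(JtJ) + 1e-12), g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        p_new <- p + as.numeric(step)
        r_new <- y - model_fun(p_new)
        sse_new <- sum(r_new^2)
        if (is.finite(sse_new) && sse_new <= sse) {
          delta <- sse - sse_new
          p <- p_new; r <- r_new
          lambda <- max(lambda / 10, 1e-12)
          improved <- TRUE
          if (delta <= convergence_tolerance * (sse + convergence_tolerance)) {
            sse <- sse_new
            converged <- TRUE
          } else {
            sse <- sse_new
          }
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (converged || !improved) {
      if (!improved) converged <- TRUE  # stalled at a (local) minimum
      break
    }
  }
  if (any(!is.finite(p))) stopf("exponential fit diverged to non-finite coefficients")
  coefs <- c(a0 = p[1], a1 = p[2], a2 = p[3],
             a3 = if (includes_hand) p[4] else 0,
             a4 = p[length(p)])
  new_curve_model("exponential", coefs, includes_hand,
                  sse = sse, converged = converged)
}

# Dispatch a single fit of the requested family on a training table.
fit_family <- function(table, family, includes_hand, config) {
  switch(family,
    exponential = fit_exponential(table, includes_hand = includes_hand,
                                  max_iterations = config$max_iterations,
                                  convergence_tolerance = config$convergence_tolerance),
    quadratic = fit_quadratic(table, includes_hand),
    linear = fit_line(table),
    stopf("unknown family '%s'", family)
  )
}

# Held-out R^2 = 1 - SSE/SST on the test fold (SST about the test mean).
# Degenerate folds with zero spread score 1 on a perfect fit, -Inf otherwise.
holdout_r2 <- function(model, test) {
  pred <- predict(model, test$age, test$sex, test$hand)
  sse <- sum((test$value - pred)^2)
  sst <- sum((test$value - mean(test$value))^2)
  if (sst == 0) {
    if (sse <= .Machine$double.eps * max(1, sum(test$value^2))) 1 else -Inf
  } else {
    1 - sse / sst
  }
}

#' Curve fit with ten-fold cross-validated model selection
#'
#' Splits the data into `k` near-equal groups by a seeded random
#' permutation, trains one model per fold on the other `k - 1` groups, and
#' scores each on its held-out group by `R^2 = 1 - SSE/SST`. The fold model
#' with the best held-out R-squared is returned as the model of the data
#' (no refit on the full data); ties break to the lowest fold index. Folds
#' whose fit fails are excluded from the contest.
#'
#' @param table Data frame with columns `age`, `sex`, `hand`, `value`.
#' @param config A [pipeline_config()]; supplies `k_folds` and the fold
#'   seed.
#' @param family `"exponential"`, `"quadratic"`, or `"linear"` (the last is
#'   used internally for the absolute-residual line).
#' @param includes_hand Include the hand dummy covariate?
#' @return The winning `devnorm_curve`, carrying `test_r2`, the winning
#'   fold index, the full per-fold R-squared table (`fold_r2`) and the fold
#'   seed. All fold models are attached as attribute `"fold_models"`.
#' @export
kfold_cv_fit <- function(table, config = pipeline_config(),
                         family = c("exponential", "quadratic", "linear"),
                         includes_hand = TRUE) {
  family <- match.arg(family)
  n <- nrow(table)
  k <- config$k_folds
  if (n < k) stopf("need at least k_folds = %d observations, got %d", k, n)
  fold_of <- with_seed(config$seed, rep(seq_len(k), length.out = n)[sample.int(n)])
  fold_models <- vector("list", k)
  fold_r2 <- rep(NA_real_, k)
  failures <- character(0)
  for (j in seq_len(k)) {
    train <- table[fold_of != j, , drop = FALSE]
    test <- table[fold_of == j, , drop = FALSE]
    m <- tryCatch(fit_family(train, family, includes_hand, config),
                  error = function(e) e)
    if (inherits(m, "error")) {
      failures <- c(failures, sprintf("fold %d: %s", j, conditionMessage(m)))
      next
    }
    fold_models[[j]] <- m
    fold_r2[j] <- holdout_r2(m, test)
  }
  if (all(is.na(fold_r2))) {
    stopf("every fold failed to fit:\n%s", paste(failures, collapse = "\n"))
  }
  if (length(failures)) warnf("excluded fold(s) from CV contest:\n%s",
                              paste(failures, collapse = "\n"))
  best <- which.max(replace(fold_r2, is.na(fold_r2), -Inf))
  out <- fold_models[[best]]
  out$test_r2 <- fold_r2[best]
  out$fold <- as.integer(best)
  out$fold_r2 <- fold_r2
  out$seed <- config$seed
  attr(out, "fold_models") <- fold_models
  attr(out, "fold_assignment") <- fold_of
  out
}
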