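#' Residuals of a fitted mean curve
#'
#' `observed - predicted` for every row of a cohort table, using the
#' table's own covariates.
#'
#' @param model A fitted `devnorm_curve`.
#' @param table Data frame with columns `age`, `sex`, `hand`, `value`.
#' @return Numeric vector of residuals in parameter units.
#' @export
compute_residuals <- function(model, table) {
  if (!all(table$sex %in% c(0, 1)) || !all(table$hand %in% c(0, 1))) {
    stopf("sex and hand codes must be 0 or 1")
  }
  table$value - predict(model, table$age, table$sex, table$hand)
}

new_residual_model <- function(intercept, slope, n, dof, test_r2, floor,
                               eq4_root, fold_r2 = NULL, seed = NA_integer_) {
  structure(
    list(intercept = intercept, slope = slope,
         n = as.integer(n), dof = as.integer(dof),
         test_r2 = test_r2, floor = floor, eq4_root = eq4_root,
         fold_r2 = fold_r2, seed = seed),
    class = "devnorm_residual"
  )
}

#' @export
print.devnorm_residual <- function(x, ...) {
  cat(sprintf("absolute-residual line: E|r| = %.6g %+.6g * age  (n = %d, DOF = %d)\n",
              x$intercept, x$slope, x$n, x$dof))
  invisible(x)
}

#' Linear model of absolute residuals versus age
#'
#' Fits `|residual| = intercept + slope * age` with the same ten-fold
#' cross-validated selection used for the mean curve (fold seed offset by
#' +1 so the two contests are independent but reproducible). This line is
#' the age-varying variability model: a negative slope means performance
#' becomes more consistent with age.
#'
#' @param ages Numeric vector of ages.
#' @param abs_residuals Non-negative absolute residuals, same length.
#' @param config A [pipeline_config()].
#' @param mean_curve_params Number of coefficients the mean curve consumed
#'   (5 with the hand term, 4 without); enters the degrees-of-freedom
#'   charge of the spread scaling.
#' @param value_range Spread of the response values, used to floor the
#'   predicted mean absolute residual at `1e-9 * value_range` so the
#'   spread estimate stays positive even where the line dips below zero.
#' @return A `devnorm_residual` model.
#' @export
fit_residual_model <- function(ages, abs_residuals, config = pipeline_config(),
                               mean_curve_params = 5L,
                               value_range = NULL) {
  if (length(ages) != length(abs_residuals)) {
    stopf("ages and abs_residuals must have equal length")
  }
  if (any(abs_residuals < 0)) stopf("absolute residuals must be non-negative")
  n <- length(ages)
  dof <- switch(config$dof_rule,
    curve_plus_residual = mean_curve_params + 2L,
    curve_only = mean_curve_params
  )
  if (n <= dof) stopf("need n > DOF (= %d), got n = %d", dof, n)
  if (is.null(value_range)) value_range <- diff(range(abs_residuals))
  floor_val <- max(1e-9 * value_range, 1e-12)
  if (all(abs_residuals == 0)) {
    warnf("all residuals are zero; returning a degenerate residual model")
    return(new_residual_model(0, 0, n, dof, NA_real_, floor_val,
                              config$eq4_root, seed = config$seed + 1L))
  }
  rconfig <- config
  rconfig$seed <- config$seed + 1L
  tab <- data.frame(age = ages, sex = 0L, hand = 0L, value = abs_residuals)
  line <- kfold_cv_fit(tab, rconfig, family = "linear", includes_hand = FALSE)
  new_residual_model(
    intercept = line$coefficients[["a4"]],
    slope = line$coefficients[["a1"]],
    n = n, dof = dof, test_r2 = line$test_r2, floor = floor_val,
    eq4_root = config$eq4_root, fold_r2 = line$fold_r2, seed = rconfig$seed
  )
}

#' Age-specific spread estimate
#'
#' Converts the predicted mean absolute residual at an age into an unbiased
#' standard-deviation-like spread:
#' `s(age) = sqrt(pi/2) * n/(n - DOF) * (intercept + slope * age)`.
#' For normal residuals `E|r| = sigma * sqrt(2/pi)`, so the `sqrt(pi/2)`
#' factor maps mean absolute deviation back to the SD scale, and
#' `n/(n - DOF)` compensates for residual shrinkage from the fitted
#' coefficients. The predicted mean absolute residual is clipped to a small
#' positive floor before scaling. An alternative reading with the bias
#' factor inside the root (`sqrt(pi/2 * n/(n - DOF))`) is available for
#' sensitivity checks via the model's `eq4_root` field.
#'
#' @param resmodel A `devnorm_residual` model.
#' @param age Numeric vector of ages.
#' @return Spread estimate `s` at each age (parameter units), always > 0.
#' @export
scale_factor <- function(resmodel, age) {
  if (resmodel$n <= resmodel$dof) stopf("n must exceed DOF")
  m <- pmax(resmodel$intercept + resmodel$slope * age, resmodel$floor)
  ratio <- resmodel$n / (resmodel$n - resmodel$dof)
  if (identical(resmodel$eq4_root, "inside")) {
    sqrt(pi / 2 * ratio) * m
  } else {
    sqrt(pi / 2) * ratio * m
  }
}

#' Standardize residuals into z-scores
#'
#' `z = residual / s(age)`: each observation's deviation from the mean
#' curve expressed in units of the age-specific spread, so a well-specified
#' model yields z-scores with mean 0 and SD 1 at every age.
#'
#' @param residuals Numeric vector of residuals.
#' @param resmodel A `devnorm_residual` model.
#' @param ages Ages matching the residuals.
#' @return Data frame with columns `age`, `residual`, `s`, `z`.
#' @export
z_scores <- function(residuals, resmodel, ages) {
  if (length(residuals) != length(ages)) {
    stopf("residuals and ages must have equal length")
  }
  s <- scale_factor(resmodel, ages)
  data.frame(age = ages, residual = residuals, s = s, z = residuals / s)
}
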