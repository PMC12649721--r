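#' Age-resolved normative performance interval
#'
#' Builds the central `coverage` band around the fitted mean curve on an
#' age grid. In working (possibly transformed) space the band is
#' `center +/- z * s(age)` with `z` the Normal quantile for the requested
#' coverage; bounds and center are then mapped back to parameter units
#' through the recorded transform (bounds swap for the order-reversing
#' inverse transform). With a negative residual-line slope the band
#' narrows with age, reflecting more consistent performance in older
#' children.
#'
#' @param nm A `devnorm_model` from [run_pipeline()].
#' @param ages Numeric age grid (years).
#' @param coverage Central coverage in (0, 1), default 0.95.
#' @param sex,hand Reference covariate codes (default 0/0, i.e. female,
#'   non-dominant hand).
#' @return A `devnorm_interval` data frame: `age`, `center`, `lower`,
#'   `upper`, `width`, with attributes `pct_change_mean` and
#'   `pct_change_width` (full-precision signed percentages from the first
#'   to the last grid age).
#' @export
interval_curve <- function(nm, ages = seq(5, 18, by = 0.5), coverage = 0.95,
                           sex = 0, hand = 0) {
  stopifnot(inherits(nm, "devnorm_model"))
  if (coverage <= 0 || coverage >= 1) stopf("coverage must be in (0, 1)")
  q <- stats::qnorm(1 - (1 - coverage) / 2)
  center_w <- predict(nm$curve, ages, sex, hand)
  s <- scale_factor(nm$residual, ages)
  lo_w <- center_w - q * s
  hi_w <- center_w + q * s
  kind <- nm$transform$kind
  # keep working-space bounds inside the transform's invertible domain
  if (kind == "sqrt") {
    lo_w <- pmax(lo_w, 0)
  } else if (kind == "inverse") {
    lo_w <- pmax(lo_w, .Machine$double.eps)
  }
  center <- invert_transform(center_w, nm$transform)
  lower <- invert_transform(lo_w, nm$transform)
  upper <- invert_transform(hi_w, nm$transform)
  if (kind == "inverse") {  # 1/y reverses order
    tmp <- lower; lower <- upper; upper <- tmp
  }
  out <- data.frame(age = ages, center = center, lower = lower,
                    upper = upper, width = upper - lower)
  attr(out, "pct_change_mean") <-
    if (center[1] != 0) 100 * (center[length(center)] - center[1]) / center[1] else NA_real_
  attr(out, "pct_change_width") <-
    interval_width_change(out$width[1], out$width[nrow(out)])
  attr(out, "coverage") <- coverage
  class(out) <- c("devnorm_interval", "data.frame")
  out
}

#' Signed percentage change in interval width across the age range
#'
#' `100 * (width_old - width_young) / width_young`: how much the normative
#' band narrows (negative) or widens (positive) from the youngest to the
#' oldest age. Full precision is returned; round with [round_half_away()]
#' for report display.
#'
#' @param width_young Band width at the young end (> 0).
#' @param width_old Band width at the old end.
#' @return Signed percentage (full precision).
#' @export
#' @examples
#' round_half_away(interval_width_change(0.2680, 0.0685))  # -74
interval_width_change <- function(width_young, width_old) {
  if (width_young <= 0) stopf("baseline width must be positive, got %g", width_young)
  100 * (width_old - width_young) / width_young
}

#' Signed percentage change of the fitted mean curve across the age range
#'
#' `100 * (predict(age_hi) - predict(age_lo)) / predict(age_lo)` at the
#' stated reference covariates, on the original parameter scale. Undefined
#' (an error) when the curve crosses zero at the baseline age — for
#' bias-like parameters whose mean changes sign, a relative change has no
#' meaningful denominator.
#'
#' @param nm A `devnorm_model`.
#' @param age_lo,age_hi Endpoint ages (default 5 and 18).
#' @param sex,hand Reference covariate codes.
#' @return Signed percentage (full precision).
#' @export
mean_curve_change <- function(nm, age_lo = 5, age_hi = 18, sex = 0, hand = 0) {
  stopifnot(inherits(nm, "devnorm_model"))
  p_lo <- invert_transform(predict(nm$curve, age_lo, sex, hand), nm$transform)
  p_hi <- invert_transform(predict(nm$curve, age_hi, sex, hand), nm$transform)
  if (p_lo == 0) stopf("mean curve is zero at age %g; relative change is undefined", age_lo)
  100 * (p_hi - p_lo) / p_lo
}

#' Age-varying band width relative to a fixed-width band
#'
#' `100 * (changing_width - fixed_width) / fixed_width`: positive when the
#' age-varying normative band is wider than a constant-width alternative
#' at the age in question, negative when narrower.
#'
#' @param changing_width Width of the age-varying band at some age (> 0).
#' @param fixed_width Constant comparison width (> 0).
#' @return Signed percentage (full precision).
#' @export
#' @examples
#' round_half_away(fixed_vs_changing_width(0.268, 0.2))  # 34
fixed_vs_changing_width <- function(changing_width, fixed_width) {
  if (fixed_width <= 0) stopf("fixed width must be positive, got %g", fixed_width)
  100 * (changing_width - fixed_width) / fixed_width
}

#' Score a new individual against a normative model
#'
#' Transforms the observed value per the model's recorded transform,
#' subtracts the predicted mean, divides by the age-specific spread, and
#' flags a deficit when |z| exceeds the cutoff (default +/-2, roughly the
#' 3rd/97th percentiles under normality). Ages outside the model's fitted
#' range are scored with an extrapolation warning — developmental curves
#' change fastest at the young end, where extrapolation is least safe.
#'
#' @param nm A `devnorm_model`.
#' @param age,sex,hand,value Observation to score (vectors recycle).
#' @param cutoff Deficit cutoff on |z| (default from the model's config).
#' @return Data frame with columns `z` and `deficit`.
#' @export
score_participant <- function(nm, age, sex, hand, value, cutoff = NULL) {
  stopifnot(inherits(nm, "devnorm_model"))
  if (!all(sex %in% c(0, 1)) || !all(hand %in% c(0, 1))) {
    stopf("sex and hand codes must be 0 or 1")
  }
  if (is.null(cutoff)) cutoff <- nm$config$z_cutoff
  if (any(age < nm$age_range[1] | age > nm$age_range[2])) {
    warnf("age outside the fitted range [%g, %g]; z-scores are extrapolated",
          nm$age_range[1], nm$age_range[2])
  }
  tv <- apply_transform_spec(value, nm$transform)
  resid <- tv - predict(nm$curve, age, sex, hand)
  s <- scale_factor(nm$residual, age)
  z <- resid / s
  data.frame(z = z, deficit = abs(z) > cutoff)
}

#' Bootstrap confidence bands for the normative curve
#'
#' Case-resampling bootstrap over participants (all rows of a participant
#' — both hands — resampled together). Each replicate refits the mean
#' curve and residual line directly (no cross-validation contest inside
#' the bootstrap, for cost) and re-evaluates the band center and bounds on
#' the age grid; percentile intervals across replicates are returned.
#'
#' @param table Cohort table for a single parameter.
#' @param config A [pipeline_config()].
#' @param ages Age grid.
#' @param B Number of bootstrap replicates (>= 100 recommended; fewer
#'   triggers a warning).
#' @param seed Seed for the resampling.
#' @param includes_hand Include the hand dummy in the curve?
#' @param coverage Band coverage.
#' @return List with `ages` and, for each of `center`, `lower`, `upper`, a
#'   two-row matrix of percentile 2.5%/97.5% limits across replicates.
#' @export
bootstrap_curve_ci <- function(table, config = pipeline_config(),
                               ages = seq(5, 18, by = 1), B = 200L,
                               seed = config$seed, includes_hand = TRUE,
                               coverage = 0.95) {
  if (B < 100L) warnf("B = %d is small; bootstrap intervals will be unstable", B)
  ids <- unique(table$participant_id)
  rows_of <- split(seq_len(nrow(table)), table$participant_id)
  q <- stats::qnorm(1 - (1 - coverage) / 2)
  family <- select_family(table$value)
  center_mat <- matrix(NA_real_, B, length(ages))
  lower_mat <- matrix(NA_real_, B, length(ages))
  upper_mat <- matrix(NA_real_, B, length(ages))
  draws <- with_seed(seed, matrix(sample(ids, length(ids) * B, replace = TRUE), nrow = B))
  for (b in seq_len(B)) {
    idx <- unlist(rows_of[draws[b, ]], use.names = FALSE)
    boot <- table[idx, , drop = FALSE]
    fit <- tryCatch(fit_family(boot, family, includes_hand, config),
                    error = function(e) NULL)
    if (is.null(fit)) next
    res <- abs(compute_residuals(fit, boot))
    line <- tryCatch(fit_line(data.frame(age = boot$age, value = res)),
                     error = function(e) NULL)
    if (is.null(line)) next
    rm_ <- new_residual_model(line$coefficients[["a4"]], line$coefficients[["a1"]],
                              n = nrow(boot), dof = fit$n_params + 2L,
                              test_r2 = NA_real_,
                              floor = max(1e-9 * diff(range(boot$value)), 1e-12),
                              eq4_root = config$eq4_root)
    s <- scale_factor(rm_, ages)
    mu <- predict(fit, ages, 0, 0)
    center_mat[b, ] <- mu
    lower_mat[b, ] <- mu - q * s
    upper_mat[b, ] <- mu + q * s
  }
  pct <- function(mat) apply(mat, 2, stats::quantile,
                             probs = c(0.025, 0.975), na.rm = TRUE)
  list(ages = ages, center = pct(center_mat),
       lower = pct(lower_mat), upper = pct(upper_mat),
       B = B, seed = seed)
}
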