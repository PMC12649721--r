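#' Iterative 3-SD outlier removal on z-scores
#'
#' Runs a fixed number of rounds (three by default). Each round computes
#' the mean and SD of the currently retained z-scores and flags points more
#' than `sd_mult` SDs from that mean; flags accumulate across rounds, so a
#' point once flagged stays flagged. The purpose is to keep a handful of
#' extreme values from dominating the subsequent normality testing; the
#' mean curve is not refit without the flagged points.
#'
#' @param z Numeric vector of z-scores, length >= 4.
#' @param rounds Number of rounds (default 3).
#' @param sd_mult SD multiple defining an outlier (default 3).
#' @return A `devnorm_outliers` object: `round_flagged` (list of indices
#'   newly flagged each round), `final_mask` (logical, `TRUE` = retained),
#'   `retained` (indices), `rounds`.
#' @export
#' @examples
#' remove_outliers(c(rep(0, 5), 100))$round_flagged[[1]]
remove_outliers <- function(z, rounds = 3L, sd_mult = 3.0) {
  n <- length(z)
  if (n < 4L) stopf("need at least 4 z-scores, got %d", n)
  flagged <- rep(FALSE, n)
  round_flagged <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    keep <- !flagged
    mu <- mean(z[keep])
    sdev <- stats::sd(z[keep])
    if (!is.finite(sdev) || sdev == 0) {
      round_flagged[[r]] <- integer(0)  # zero spread: nothing to flag
      next
    }
    new_flags <- which(keep & abs(z - mu) > sd_mult * sdev)
    round_flagged[[r]] <- new_flags
    flagged[new_flags] <- TRUE
  }
  structure(
    list(round_flagged = round_flagged,
         final_mask = !flagged,
         retained = which(!flagged),
         rounds = as.integer(rounds)),
    class = "devnorm_outliers"
  )
}

#' The "normal enough" rule on sample moments
#'
#' A distribution that fails Shapiro-Wilk is still accepted when its
#' sample skewness is small in magnitude and its kurtosis (Pearson
#' convention, normal = 3) sits strictly inside a window around 3 —
#' tolerances under which normal-theory z-score ranges remain serviceable.
#'
#' @param skew Sample skewness.
#' @param kurtosis Sample kurtosis (normal = 3).
#' @param skew_limit Bound on |skew| (default 0.6).
#' @param kurtosis_window Open interval for the kurtosis (default
#'   `c(2.4, 3.6)`).
#' @return Logical.
#' @export
#' @examples
#' normal_enough(0.3, 3.0)  # TRUE
#' normal_enough(0.8, 3.0)  # FALSE: too skewed
normal_enough <- function(skew, kurtosis, skew_limit = 0.6,
                          kurtosis_window = c(2.4, 3.6)) {
  abs(skew) < skew_limit &
    kurtosis > kurtosis_window[1] & kurtosis < kurtosis_window[2]
}

#' Normality verdict on z-scores
#'
#' Shapiro-Wilk test plus sample skewness and kurtosis (Pearson
#' convention, normal = 3). Passing Shapiro-Wilk at `alpha` passes
#' outright; otherwise the distribution is still accepted as "normal
#' enough" when |skew| < `skew_limit` and the kurtosis lies strictly
#' inside `kurtosis_window` — a tolerance for mild non-normality under
#' which z-score-based ranges remain serviceable. Shapiro-Wilk is only
#' valid up to n = 5000, so larger samples are tested on a seeded
#' subsample of 5000 (moments always use all points).
#'
#' @param z Retained z-scores (post outlier removal), 3 <= length.
#' @param alpha Shapiro-Wilk significance level.
#' @param skew_limit,kurtosis_window "Normal enough" bounds.
#' @param subsample_seed Seed for the n > 5000 subsample.
#' @return A `devnorm_verdict`: `shapiro_p`, `skew`, `kurtosis`,
#'   `passed_shapiro`, `normal_enough`, `final_pass`, `n`,
#'   `shapiro_subsampled`.
#' @export
normality_assess <- function(z, alpha = 0.05, skew_limit = 0.6,
                             kurtosis_window = c(2.4, 3.6),
                             subsample_seed = 1L) {
  n <- length(z)
  if (n < 3L) stopf("Shapiro-Wilk needs at least 3 observations, got %d", n)
  z_test <- z
  subsampled <- FALSE
  if (n > 5000L) {
    z_test <- with_seed(subsample_seed, sample(z, 5000L))
    subsampled <- TRUE
  }
  shapiro_p <- tryCatch(stats::shapiro.test(z_test)$p.value,
                        error = function(e) NA_real_)
  skew <- sample_skewness(z)
  kurt <- sample_kurtosis(z)
  passed_shapiro <- isTRUE(shapiro_p > alpha)
  enough <- normal_enough(skew, kurt, skew_limit, kurtosis_window)
  structure(
    list(shapiro_p = shapiro_p, skew = skew, kurtosis = kurt,
         passed_shapiro = passed_shapiro,
         normal_enough = enough,
         final_pass = passed_shapiro || enough,
         n = n, shapiro_subsampled = subsampled),
    class = "devnorm_verdict"
  )
}

#' @export
print.devnorm_verdict <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk p = %.4g (%s); skew = %.3f; kurtosis = %.3f\n",
              x$shapiro_p, if (x$passed_shapiro) "pass" else "fail",
              x$skew, x$kurtosis))
  cat(sprintf("verdict: %s\n",
              if (x$final_pass) {
                if (x$passed_shapiro) "normal" else "normal enough"
              } else "not normal"))
  invisible(x)
}

#' Shift-then-transform a set of values
#'
#' Every transform first shifts the data so its minimum is exactly 1
#' (subtract the minimum, add one), guaranteeing real, finite outputs, then
#' applies the variance-stabilizing map: `log(shifted)`, `sqrt(shifted)`,
#' or `1/shifted`. `kind = "none"` is the identity (no shift), used for the
#' untransformed pipeline. The shift is recorded so the transform can be
#' inverted with [invert_transform()].
#'
#' @param values Numeric vector.
#' @param kind One of `"none"`, `"log"`, `"sqrt"`, `"inverse"`.
#' @return List with `values` (transformed) and `spec` (a
#'   `devnorm_transform` holding `kind` and `shift`).
#' @export
#' @examples
#' apply_transform(c(3, 4, 7), "log")$values  # log(c(1, 2, 5))
apply_transform <- function(values, kind = c("none", "log", "sqrt", "inverse")) {
  kind <- match.arg(kind)
  if (length(values) == 0) stopf("values must be non-empty")
  if (kind == "none") {
    spec <- structure(list(kind = "none", shift = 0), class = "devnorm_transform")
    return(list(values = values, spec = spec))
  }
  shift <- min(values)
  shifted <- values - shift + 1
  out <- switch(kind,
    log = log(shifted),
    sqrt = sqrt(shifted),
    inverse = 1 / shifted
  )
  spec <- structure(list(kind = kind, shift = shift), class = "devnorm_transform")
  list(values = out, spec = spec)
}

# Apply a recorded transform spec to new values (for scoring new
# individuals on a transformed model).
apply_transform_spec <- function(values, spec) {
  if (spec$kind == "none") return(values)
  shifted <- values - spec$shift + 1
  if (any(shifted <= 0)) {
    warnf("value(s) below the training minimum after shifting; transform may extrapolate poorly")
  }
  switch(spec$kind,
    log = log(shifted),
    sqrt = sqrt(shifted),
    inverse = 1 / shifted
  )
}

#' Invert a recorded transform
#'
#' Maps transformed values back to the original parameter units using the
#' shift recorded at transform time. Round-trips with [apply_transform()]
#' to within floating-point precision.
#'
#' @param y Transformed values.
#' @param spec A `devnorm_transform` from [apply_transform()].
#' @return Values on the original scale.
#' @export
invert_transform <- function(y, spec) {
  switch(spec$kind,
    none = y,
    log = exp(y) + spec$shift - 1,
    sqrt = y^2 + spec$shift - 1,
    inverse = 1 / y + spec$shift - 1,
    stopf("unknown transform kind '%s'", spec$kind)
  )
}
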