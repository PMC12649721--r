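#' Pipeline configuration
#'
#' Collects every tunable constant of the normative-modeling pipeline in one
#' validated object. The defaults are the pipeline's published operating
#' point: ten-fold cross-validation, three rounds of 3-SD outlier removal,
#' Shapiro-Wilk at alpha = 0.05 with the skew/kurtosis "normal enough"
#' relaxation (|skew| < 0.6, kurtosis in (2.4, 3.6)), a +/-2 z-score deficit
#' cutoff and a central 95% normative band.
#'
#' @param k_folds Number of cross-validation folds (default 10).
#' @param outlier_rounds Rounds of iterative outlier removal (default 3).
#' @param outlier_sd SD multiple beyond which a z-score is flagged (default 3).
#' @param shapiro_alpha Significance level for the Shapiro-Wilk test.
#' @param skew_limit Absolute-skew bound of the "normal enough" rule.
#' @param kurtosis_window Length-2 numeric, open kurtosis window of the
#'   "normal enough" rule (Pearson convention, normal = 3).
#' @param z_cutoff Deficit cutoff on |z| when scoring individuals.
#' @param coverage Central coverage of the normative interval.
#' @param seed Integer seed driving fold assignment and any subsampling.
#' @param eq4_root Where the bias factor n/(n - DOF) sits relative to the
#'   square root in the spread scaling: `"outside"` (default) gives
#'   s = sqrt(pi/2) * n/(n - DOF) * m(age); `"inside"` gives
#'   s = sqrt(pi/2 * n/(n - DOF)) * m(age). Switchable for sensitivity
#'   checks; the two agree as n grows.
#' @param dof_rule How many residual degrees of freedom the pipeline charges:
#'   `"curve_plus_residual"` (default) counts the mean-curve coefficients
#'   plus the 2 coefficients of the residual line; `"curve_only"` counts
#'   only the mean curve.
#' @param max_iterations Optimizer iteration cap for the exponential fit.
#' @param convergence_tolerance Relative SSE-change tolerance declaring
#'   convergence of the exponential fit.
#'
#' @return An object of class `devnorm_config` (a validated list).
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 42)
#' cfg$k_folds
pipeline_config <- function(k_folds = 10L,
                            outlier_rounds = 3L,
                            outlier_sd = 3.0,
                            shapiro_alpha = 0.05,
                            skew_limit = 0.6,
                            kurtosis_window = c(2.4, 3.6),
                            z_cutoff = 2.0,
                            coverage = 0.95,
                            seed = 1L,
                            eq4_root = c("outside", "inside"),
                            dof_rule = c("curve_plus_residual", "curve_only"),
                            max_iterations = 1000L,
                            convergence_tolerance = 1e-10) {
  eq4_root <- match.arg(eq4_root)
  dof_rule <- match.arg(dof_rule)
  stopifnot(
    k_folds >= 2, outlier_rounds >= 1, outlier_sd > 0,
    shapiro_alpha > 0, shapiro_alpha < 1,
    skew_limit > 0, length(kurtosis_window) == 2L,
    kurtosis_window[1] < kurtosis_window[2],
    z_cutoff > 0, coverage > 0, coverage < 1,
    max_iterations >= 1, convergence_tolerance > 0
  )
  structure(
    list(
      k_folds = as.integer(k_folds),
      outlier_rounds = as.integer(outlier_rounds),
      outlier_sd = outlier_sd,
      shapiro_alpha = shapiro_alpha,
      skew_limit = skew_limit,
      kurtosis_window = as.numeric(kurtosis_window),
      z_cutoff = z_cutoff,
      coverage = coverage,
      seed = as.integer(seed),
      eq4_root = eq4_root,
      dof_rule = dof_rule,
      max_iterations = as.integer(max_iterations),
      convergence_tolerance = convergence_tolerance
    ),
    class = "devnorm_config"
  )
}

#' @export
print.devnorm_config <- function(x, ...) {
  cat("devnorm pipeline configuration\n")
  cat(sprintf("  folds: %d   outlier rounds: %d (|z| > %g SD)\n",
              x$k_folds, x$outlier_rounds, x$outlier_sd))
  cat(sprintf("  gate: Shapiro alpha %g; |skew| < %g; kurtosis in (%g, %g)\n",
              x$shapiro_alpha, x$skew_limit,
              x$kurtosis_window[1], x$kurtosis_window[2]))
  cat(sprintf("  band coverage: %g   deficit cutoff: |z| > %g\n",
              x$coverage, x$z_cutoff))
  cat(sprintf("  spread scaling: n/(n-DOF) %s the root, DOF rule '%s'\n",
              x$eq4_root, x$dof_rule))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
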