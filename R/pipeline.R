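# Run one full modeling pass for a single transform variant:
# transform -> family selection -> CV curve fit -> absolute-residual line
# -> z-scores -> outlier rounds -> normality verdict.
fit_variant <- function(table, kind, includes_hand, config) {
  tr <- apply_transform(table$value, kind)
  wtab <- table
  wtab$value <- tr$values
  family <- select_family(wtab$value)
  curve <- kfold_cv_fit(wtab, config, family, includes_hand)
  res <- compute_residuals(curve, wtab)
  resmodel <- fit_residual_model(
    wtab$age, abs(res), config,
    mean_curve_params = curve$n_params,
    value_range = diff(range(wtab$value))
  )
  zset <- z_scores(res, resmodel, wtab$age)
  zset <- cbind(participant_id = table$participant_id,
                hand = table$hand, zset)
  outliers <- remove_outliers(zset$z, config$outlier_rounds, config$outlier_sd)
  gate <- normality_assess(zset$z[outliers$retained],
                           alpha = config$shapiro_alpha,
                           skew_limit = config$skew_limit,
                           kurtosis_window = config$kurtosis_window,
                           subsample_seed = config$seed)
  list(kind = kind, transform = tr$spec, family = family, curve = curve,
       residual = resmodel, zset = zset, outliers = outliers, gate = gate)
}

#' Transform selection by rerunning the pipeline per variant
#'
#' If the untransformed pipeline's z-scores pass the normality gate, no
#' transform is applied. Otherwise the log, square-root and inverse
#' variants are each run through the full pipeline (their own curve fit,
#' residual line, outlier rounds and normality verdict); among variants
#' that pass the gate, the one with the highest held-out R-squared of its
#' mean curve wins. If none pass, the untransformed models are kept for
#' simplicity.
#'
#' @param table Cohort table (single parameter) with columns `age`, `sex`,
#'   `hand`, `value`, `participant_id`.
#' @param config A [pipeline_config()].
#' @param includes_hand Include the hand dummy covariate?
#' @return List with `chosen` (the winning variant), `variants` (all
#'   fitted variants) and `decision` (a human-readable trail).
#' @export
select_transform <- function(table, config = pipeline_config(),
                             includes_hand = TRUE) {
  base <- fit_variant(table, "none", includes_hand, config)
  variants <- list(none = base)
  if (base$gate$final_pass) {
    return(list(chosen = base, variants = variants,
                decision = "untransformed z-scores passed the normality gate"))
  }
  log_lines <- "untransformed z-scores failed the normality gate"
  for (kind in c("log", "sqrt", "inverse")) {
    v <- tryCatch(fit_variant(table, kind, includes_hand, config),
                  error = function(e) e)
    if (inherits(v, "error")) {
      log_lines <- c(log_lines,
                     sprintf("%s transform disqualified: %s", kind,
                             conditionMessage(v)))
      next
    }
    variants[[kind]] <- v
    log_lines <- c(log_lines,
                   sprintf("%s transform: gate %s, held-out R^2 %.4f", kind,
                           if (v$gate$final_pass) "pass" else "fail",
                           v$curve$test_r2))
  }
  passing <- Filter(function(v) v$gate$final_pass, variants[names(variants) != "none"])
  if (length(passing) == 0) {
    log_lines <- c(log_lines, "all transforms failed; untransformed models kept")
    return(list(chosen = base, variants = variants,
                decision = paste(log_lines, collapse = "\n")))
  }
  r2 <- vapply(passing, function(v) v$curve$test_r2, numeric(1))
  winner <- passing[[which.max(r2)]]
  log_lines <- c(log_lines, sprintf("chose %s transform (held-out R^2 %.4f)",
                                    winner$kind, winner$curve$test_r2))
  list(chosen = winner, variants = variants,
       decision = paste(log_lines, collapse = "\n"))
}

#' Build a normative model for one performance parameter
#'
#' End-to-end driver: selects the curve family from the sign of the
#' values, fits the mean curve with ten-fold cross-validated selection,
#' fits the linear absolute-residual (variability) line with the same
#' scheme, standardizes into z-scores, runs three rounds of 3-SD outlier
#' removal, assesses normality, and — only if the gate fails — runs the
#' shift-then-transform ladder and keeps the best passing variant. Every
#' random step derives from `config$seed`, so the same inputs and seed
#' reproduce the same model bit for bit.
#'
#' @param cohort Long-format cohort table (see [read_cohort()]) or a path
#'   to such a CSV.
#' @param parameter Name of the parameter to model (matched against the
#'   `parameter` column); `NULL` if the table holds a single unnamed
#'   parameter.
#' @param config A [pipeline_config()].
#' @param includes_hand Include the hand dummy covariate? Use `FALSE` for
#'   bimanual-task parameters where both hands act at once.
#' @return A `devnorm_model`: curve, residual line, transform spec,
#'   outlier report, normality verdict, per-observation z-scores, coding
#'   dictionaries, config and decision trail.
#' @export
#' @examples
#' coh <- generate_cohort(demographics(60), seed = 1)
#' truth <- ground_truth("exponential", a0 = 0.45, a1 = -0.134, a4 = 0.12,
#'                       noise_intercept = 0.07, noise_slope = -0.003,
#'                       parameter = "reaction_time")
#' tab <- simulate_parameter(coh, truth, seed = 2)
#' nm <- run_pipeline(tab, "reaction_time", pipeline_config(seed = 3))
#' nm$gate$final_pass
run_pipeline <- function(cohort, parameter = NULL,
                         config = pipeline_config(),
                         includes_hand = TRUE) {
  if (is.character(cohort) && length(cohort) == 1L) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  if (!is.null(parameter)) {
    cohort <- cohort[cohort$parameter == parameter, , drop = FALSE]
    if (nrow(cohort) == 0) stopf("no rows for parameter '%s'", parameter)
  } else {
    parameter <- if ("parameter" %in% names(cohort)) unique(cohort$parameter)[1] else "param"
  }
  sel <- select_transform(cohort, config, includes_hand)
  v <- sel$chosen
  structure(
    list(
      parameter = parameter,
      curve = v$curve,
      residual = v$residual,
      transform = v$transform,
      gate = v$gate,
      outliers = v$outliers,
      zset = v$zset,
      coding = list(sex = c(female = 0L, male = 1L),
                    hand = c(non_dominant = 0L, dominant = 1L)),
      includes_hand = includes_hand,
      age_range = range(cohort$age),
      n = nrow(cohort),
      config = config,
      decision = sel$decision
    ),
    class = "devnorm_model"
  )
}

#' @export
print.devnorm_model <- function(x, ...) {
  cat(sprintf("normative model for '%s' (n = %d, ages %.1f-%.1f)\n",
              x$parameter, x$n, x$age_range[1], x$age_range[2]))
  cat(sprintf("transform: %s\n", x$transform$kind))
  print(x$curve)
  print(x$residual)
  cat(sprintf("outliers flagged: %d of %d\n",
              x$n - length(x$outliers$retained), x$n))
  print(x$gate)
  invisible(x)
}

# --- cohort and model I/O ---------------------------------------------------

cohort_columns <- c("participant_id", "age", "sex", "hand", "parameter", "value")

validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols)) {
    stopf("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(cohort), cohort_columns)
  if (length(extra)) stopf("unknown cohort column(s): %s", paste(extra, collapse = ", "))
  bad <- which(!is.finite(cohort$value) | !is.finite(cohort$age))
  if (length(bad)) stopf("non-numeric or missing value/age in row(s): %s",
                         paste(utils::head(bad, 10), collapse = ", "))
  bad_sex <- which(!cohort$sex %in% c(0, 1))
  if (length(bad_sex)) stopf("sex code must be 0 or 1; bad row(s): %s",
                             paste(utils::head(bad_sex, 10), collapse = ", "))
  bad_hand <- which(!cohort$hand %in% c(0, 1))
  if (length(bad_hand)) stopf("hand code must be 0 or 1; bad row(s): %s",
                              paste(utils::head(bad_hand, 10), collapse = ", "))
  key <- paste(cohort$participant_id, cohort$hand, cohort$parameter)
  if (anyDuplicated(key)) {
    stopf("duplicate (participant_id, hand, parameter) row(s), first at row %d",
          anyDuplicated(key))
  }
  invisible(cohort)
}

#' Read and validate a long-format cohort CSV
#'
#' Expects the exact header `participant_id,age,sex,hand,parameter,value`
#' (UTF-8, `.` decimal separator; CRLF tolerated). Validation rejects
#' unknown columns, non-binary sex/hand codes, missing or non-numeric
#' values and duplicate (participant, hand, parameter) rows, reporting row
#' numbers.
#'
#' @param path CSV path.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort$participant_id <- as.character(cohort$participant_id)
  validate_cohort(cohort)
  cohort
}

#' Write a cohort table as CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a normative model to JSON
#'
#' Full-precision, deterministic JSON (no timestamps): the same model
#' writes byte-identical files, and [read_model()] restores an equivalent
#' model whose scores agree exactly.
#'
#' @param nm A `devnorm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(nm, path) {
  stopifnot(inherits(nm, "devnorm_model"))
  curve_fields <- unclass(nm$curve)[c("family", "coefficients", "includes_hand",
                                      "n_params", "test_r2", "sse", "converged",
                                      "fold", "fold_r2", "seed")]
  curve_fields$coefficients <- as.list(curve_fields$coefficients)
  payload <- list(
    format = "devnorm-model-v1",
    parameter = nm$parameter,
    curve = curve_fields,
    residual = unclass(nm$residual),
    transform = unclass(nm$transform),
    gate = unclass(nm$gate),
    outliers = list(round_flagged = nm$outliers$round_flagged,
                    retained = nm$outliers$retained,
                    rounds = nm$outliers$rounds),
    zset = nm$zset,
    coding = nm$coding,
    includes_hand = nm$includes_hand,
    age_range = nm$age_range,
    n = nm$n,
    config = unclass(nm$config),
    decision = nm$decision
  )
  # I(17) significant digits: exact binary round-trip for doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a normative model written by [write_model()]
#'
#' @param path JSON path.
#' @return A `devnorm_model`.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "devnorm-model-v1")) {
    stopf("'%s' is not a devnorm model file", path)
  }
  curve <- new_curve_model(
    family = p$curve$family,
    coefficients = unlist(p$curve$coefficients),
    includes_hand = p$curve$includes_hand,
    test_r2 = p$curve$test_r2, sse = p$curve$sse,
    converged = p$curve$converged, fold = as.integer(p$curve$fold),
    fold_r2 = p$curve$fold_r2, seed = as.integer(p$curve$seed)
  )
  residual <- new_residual_model(
    intercept = p$residual$intercept, slope = p$residual$slope,
    n = p$residual$n, dof = p$residual$dof,
    test_r2 = if (is.null(p$residual$test_r2)) NA_real_ else p$residual$test_r2,
    floor = p$residual$floor, eq4_root = p$residual$eq4_root,
    fold_r2 = p$residual$fold_r2,
    seed = as.integer(p$residual$seed)
  )
  cfg <- do.call(pipeline_config, p$config[setdiff(names(p$config), character(0))])
  structure(
    list(
      parameter = p$parameter,
      curve = curve,
      residual = residual,
      transform = structure(p$transform, class = "devnorm_transform"),
      gate = structure(p$gate, class = "devnorm_verdict"),
      outliers = structure(
        list(round_flagged = lapply(p$outliers$round_flagged, as.integer),
             final_mask = seq_len(p$n) %in% p$outliers$retained,
             retained = as.integer(p$outliers$retained),
             rounds = as.integer(p$outliers$rounds)),
        class = "devnorm_outliers"),
      zset = p$zset,
      coding = p$coding,
      includes_hand = p$includes_hand,
      age_range = p$age_range,
      n = as.integer(p$n),
      config = cfg,
      decision = p$decision
    ),
    class = "devnorm_model"
  )
}
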