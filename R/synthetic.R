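#' Cohort demographics specification
#'
#' Describes the sampling frame for a synthetic cross-sectional cohort:
#' how many participants, the age range and the target age mean/SD, and the
#' sex mix. Defaults emulate a study-like cohort of 288 children aged 5-18
#' with mean age 13, SD 3.2 and roughly two males for every female, i.e. a
#' distribution skewed toward older ages.
#'
#' @param n_participants Number of participants.
#' @param age_min,age_max Age bounds in years.
#' @param age_mean,age_sd Target mean and SD of the sampled ages (years).
#' @param male_fraction Proportion of males in \[0, 1\] (sex coded male = 1,
#'   female = 0).
#' @param age_skew Shape parameter of the skew-normal age sampler; negative
#'   values put the long tail at young ages (default -3, matching a cohort
#'   recruited mostly at ages 11+).
#' @return A `devnorm_demographics` object.
#' @export
#' @examples
#' demographics(288)
demographics <- function(n_participants,
                         age_min = 5, age_max = 18,
                         age_mean = 13, age_sd = 3.2,
                         male_fraction = 2 / 3,
                         age_skew = -3) {
  if (!is.numeric(n_participants) || n_participants < 0) {
    stopf("n_participants must be a non-negative count")
  }
  if (age_min >= age_max) stopf("age_min (%g) must be below age_max (%g)", age_min, age_max)
  if (age_sd <= 0) stopf("age_sd must be positive, got %g", age_sd)
  if (age_mean < age_min || age_mean > age_max) {
    stopf("age_mean (%g) must lie within [%g, %g]", age_mean, age_min, age_max)
  }
  if (male_fraction < 0 || male_fraction > 1) {
    stopf("male_fraction must be in [0, 1], got %g", male_fraction)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      age_min = age_min, age_max = age_max,
      age_mean = age_mean, age_sd = age_sd,
      male_fraction = male_fraction,
      age_skew = age_skew
    ),
    class = "devnorm_demographics"
  )
}

#' Ground-truth specification for a simulated performance parameter
#'
#' Defines the data-generating process a synthetic parameter follows: an
#' exponential (`a0 * exp(a1 * age) + a2 * sex + a3 * hand + a4`) or
#' quadratic (`a0 * age^2 + a1 * age + a2 * sex + a3 * hand + a4`) mean
#' trend, plus additive noise whose expected absolute deviation varies
#' linearly with age, `E|eps| = noise_intercept + noise_slope * age`.
#' Because the analysis pipeline estimates exactly this structure, cohorts
#' drawn from a `ground_truth` support parameter-recovery and calibration
#' tests with known answers.
#'
#' @param family `"exponential"` or `"quadratic"`.
#' @param a0,a1,a2,a3,a4 Mean-curve coefficients. `a2` is the sex offset,
#'   `a3` the hand offset, `a4` the intercept/offset term.
#' @param noise_intercept,noise_slope Linear model of the expected absolute
#'   deviation of the noise versus age, in parameter units.
#' @param noise_shape `"normal"` (Gaussian noise) or `"skewed"` (centered
#'   gamma noise with skewness `noise_skew`, used to exercise the
#'   transform ladder).
#' @param noise_skew Target skewness of the noise when `noise_shape =
#'   "skewed"`; sign gives the tail direction.
#' @param per_hand If `TRUE`, two observations (hand 0 and hand 1) are
#'   emitted per participant, as for unimanual tasks performed with each
#'   hand.
#' @param parameter Name recorded in the `parameter` column.
#' @return A `devnorm_truth` object.
#' @export
ground_truth <- function(family = c("exponential", "quadratic"),
                         a0 = 0, a1 = 0, a2 = 0, a3 = 0, a4 = 0,
                         noise_intercept = 0, noise_slope = 0,
                         noise_shape = c("normal", "skewed"),
                         noise_skew = 2,
                         per_hand = TRUE,
                         parameter = "param") {
  family <- match.arg(family)
  noise_shape <- match.arg(noise_shape)
  if (noise_shape == "skewed" && noise_skew == 0) {
    stopf("noise_skew must be nonzero for the skewed noise shape")
  }
  structure(
    list(
      family = family,
      a0 = a0, a1 = a1, a2 = a2, a3 = a3, a4 = a4,
      noise_intercept = noise_intercept, noise_slope = noise_slope,
      noise_shape = noise_shape, noise_skew = noise_skew,
      per_hand = isTRUE(per_hand),
      parameter = parameter
    ),
    class = "devnorm_truth"
  )
}

# --- skew-normal age sampler ------------------------------------------------

# Density of the skew-normal SN(xi, omega, alpha).
dsn <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

# Mean and SD of SN(xi, omega, alpha) truncated to [lo, hi], by quadrature.
truncated_sn_moments <- function(xi, omega, alpha, lo, hi) {
  mass <- stats::integrate(dsn, lo, hi, xi = xi, omega = omega, alpha = alpha,
                           rel.tol = 1e-9)$value
  if (mass <= 0) return(c(mean = NA_real_, sd = NA_real_))
  m1 <- stats::integrate(function(x) x * dsn(x, xi, omega, alpha), lo, hi,
                         rel.tol = 1e-9)$value / mass
  m2 <- stats::integrate(function(x) (x - m1)^2 * dsn(x, xi, omega, alpha), lo, hi,
                         rel.tol = 1e-9)$value / mass
  c(mean = m1, sd = sqrt(m2))
}

# Location/scale of a truncated skew-normal whose truncated mean/SD match
# the targets, for a fixed shape alpha. Two-parameter root find via optim.
match_truncated_sn <- function(age_mean, age_sd, alpha, lo, hi) {
  obj <- function(p) {
    mo <- truncated_sn_moments(p[1], exp(p[2]), alpha, lo, hi)
    if (any(!is.finite(mo))) return(1e6)
    (mo["mean"] - age_mean)^2 + (mo["sd"] - age_sd)^2
  }
  fit <- stats::optim(c(age_mean, log(age_sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  list(xi = fit$par[1], omega = exp(fit$par[2]), alpha = alpha,
       achieved = truncated_sn_moments(fit$par[1], exp(fit$par[2]), alpha, lo, hi))
}

# Draw n skew-normal deviates via the |U0| construction.
rsn <- function(n, xi, omega, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- abs(stats::rnorm(n))
  u1 <- stats::rnorm(n)
  xi + omega * (delta * u0 + sqrt(1 - delta^2) * u1)
}

#' Generate a cohort skeleton (ids, ages, sexes)
#'
#' Samples participant ages from a truncated skew-normal moment-matched to
#' the target mean and SD on the declared age range, and sexes as Bernoulli
#' draws at `male_fraction`. Values are attached separately by
#' [simulate_parameter()]. Reproducible: the same demographics and seed give
#' a bit-identical table.
#'
#' @param demo A [demographics()] object.
#' @param seed Integer seed.
#' @return A data frame with columns `participant_id`, `age`, `sex`.
#' @export
#' @examples
#' head(generate_cohort(demographics(20), seed = 1))
generate_cohort <- function(demo, seed = 1L) {
  stopifnot(inherits(demo, "devnorm_demographics"))
  n <- demo$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  if (n == 0L) {
    return(data.frame(participant_id = character(), age = numeric(),
                      sex = integer()))
  }
  sn <- match_truncated_sn(demo$age_mean, demo$age_sd, demo$age_skew,
                           demo$age_min, demo$age_max)
  with_seed(seed, {
    ages <- numeric(0)
    # rejection sampling into the age window
    while (length(ages) < n) {
      draw <- rsn(2L * (n - length(ages)) + 16L, sn$xi, sn$omega, sn$alpha)
      ages <- c(ages, draw[draw >= demo$age_min & draw <= demo$age_max])
    }
    ages <- ages[seq_len(n)]
    sexes <- stats::rbinom(n, 1L, demo$male_fraction)
    data.frame(participant_id = ids, age = ages, sex = as.integer(sexes))
  })
}

# Evaluate a ground-truth mean curve at given covariates.
truth_mean <- function(truth, age, sex, hand) {
  if (truth$family == "exponential") {
    truth$a0 * exp(truth$a1 * age) + truth$a2 * sex + truth$a3 * hand + truth$a4
  } else {
    truth$a0 * age^2 + truth$a1 * age + truth$a2 * sex + truth$a3 * hand + truth$a4
  }
}

# Mean absolute deviation of a unit-scale centered gamma with skewness g.
centered_gamma_mad <- function(g) {
  shape <- (2 / abs(g))^2
  stats::integrate(function(x) abs(x - shape) * stats::dgamma(x, shape = shape),
                   0, Inf, rel.tol = 1e-9)$value
}

#' Simulate observed values for a cohort under a known ground truth
#'
#' Attaches values `mean(age, sex, hand) + eps` to a cohort skeleton, where
#' the noise `eps` has mean zero and expected absolute deviation
#' `noise_intercept + noise_slope * age` at every age — exactly the
#' variability structure the analysis pipeline assumes. For `"normal"` noise
#' the draw is `Normal(0, m(age) * sqrt(pi/2))` so that `E|eps| = m(age)`;
#' for `"skewed"` noise a centered gamma with the requested skewness is
#' rescaled to the same `E|eps|`.
#'
#' @param cohort Skeleton from [generate_cohort()] (or any data frame with
#'   `participant_id`, `age`, `sex` and optionally `hand`).
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed for the noise draw.
#' @return A long-format cohort table with columns `participant_id`, `age`,
#'   `sex`, `hand`, `parameter`, `value`.
#' @export
#' @examples
#' coh <- generate_cohort(demographics(50), seed = 1)
#' truth <- ground_truth("exponential", a0 = 0.45, a1 = -0.134, a4 = 0.12,
#'                       noise_intercept = 0.07, noise_slope = -0.003)
#' head(simulate_parameter(coh, truth, seed = 2))
simulate_parameter <- function(cohort, truth, seed = 1L) {
  stopifnot(inherits(truth, "devnorm_truth"))
  required <- c("participant_id", "age", "sex")
  if (!all(required %in% names(cohort))) {
    stopf("cohort must have columns %s", paste(required, collapse = ", "))
  }
  if (nrow(cohort) > 0) {
    ar <- range(cohort$age)
    m_at <- truth$noise_intercept + truth$noise_slope * ar
    if (any(m_at < 0)) {
      stopf("expected absolute deviation is negative within the age range [%g, %g]",
            ar[1], ar[2])
    }
  }
  if (!"hand" %in% names(cohort)) {
    cohort$hand <- 0L
    if (truth$per_hand) cohort <- duplicate_hands(cohort)
  }
  mu <- truth_mean(truth, cohort$age, cohort$sex, cohort$hand)
  m <- truth$noise_intercept + truth$noise_slope * cohort$age
  n <- nrow(cohort)
  eps <- with_seed(seed, {
    if (truth$noise_shape == "normal") {
      stats::rnorm(n, 0, m * sqrt(pi / 2))
    } else {
      g <- truth$noise_skew
      shape <- (2 / abs(g))^2
      unit <- (stats::rgamma(n, shape = shape) - shape) * sign(g)
      unit * m / centered_gamma_mad(g)
    }
  })
  out <- data.frame(
    participant_id = cohort$participant_id,
    age = cohort$age,
    sex = as.integer(cohort$sex),
    hand = as.integer(cohort$hand),
    parameter = truth$parameter,
    value = mu + eps
  )
  if (truth$family == "exponential" && any(out$value <= 0)) {
    warnf("%d simulated value(s) are non-positive; downstream family selection will fall back to a quadratic fit",
          sum(out$value <= 0))
  }
  rownames(out) <- NULL
  out
}

#' Duplicate each participant across both hands
#'
#' Expands a one-row-per-participant table into two rows per participant
#' (hand codes 0 and 1), the device used for unimanual tasks where both
#' hands are modeled jointly through a dummy-coded hand covariate — a
#' 288-participant cohort becomes 576 data points. All non-hand fields are
#' copied unchanged.
#'
#' @param cohort Data frame with one row per participant (per parameter).
#' @return The table with exactly twice as many rows, `hand` in `{0, 1}`.
#' @export
duplicate_hands <- function(cohort) {
  key <- cohort$participant_id
  if ("parameter" %in% names(cohort)) key <- paste(key, cohort$parameter)
  if (anyDuplicated(key)) {
    stopf("cohort already has multiple rows per participant; refusing to duplicate")
  }
  a <- cohort
  b <- cohort
  a$hand <- rep(0L, nrow(a))
  b$hand <- rep(1L, nrow(b))
  out <- rbind(a, b)
  cols <- names(cohort)
  if (!"hand" %in% cols) cols <- append(cols, "hand", after = match("sex", cols, nomatch = length(cols)))
  out <- out[order(match(out$participant_id, cohort$participant_id), out$hand), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Miss-count-weighted mean position
#'
#' Weighted mean of bin x-positions with miss counts as weights,
#' `sum(x_i * w_i) / sum(w_i)` — the lateral miss-bias summary of an
#' object-hitting task (centimetres; negative = misses biased left).
#'
#' @param bin_positions Numeric vector of bin x-positions (cm).
#' @param miss_counts Non-negative counts, same length.
#' @return The weighted mean position (cm).
#' @export
#' @examples
#' miss_bias_weighted_mean(c(-2, 0, 2), c(3, 1, 0))  # -1.5
miss_bias_weighted_mean <- function(bin_positions, miss_counts) {
  if (length(bin_positions) != length(miss_counts)) {
    stopf("bin_positions and miss_counts must have equal length")
  }
  if (any(miss_counts < 0)) stopf("miss_counts must be non-negative")
  total <- sum(miss_counts)
  if (total <= 0) stopf("all miss counts are zero; weighted mean is undefined")
  sum(bin_positions * miss_counts) / total
}
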