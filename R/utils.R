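#' Sample skewness (moment estimator)
#'
#' Third standardized moment, `m3 / m2^(3/2)`, computed with biased
#' (divide-by-n) central moments. This is the convention used for the
#' "normal enough" gate, where the reference value for a normal sample is 0.
#'
#' @param x Numeric vector, length >= 3.
#' @return Scalar skewness.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite values to compute skewness")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Sample kurtosis (Pearson convention, normal = 3)
#'
#' Fourth standardized moment `m4 / m2^2`. A normal distribution has
#' kurtosis 3 under this convention; the gate's acceptance window
#' (2.4, 3.6) is stated on this scale, not on excess kurtosis.
#'
#' @param x Numeric vector, length >= 4.
#' @return Scalar kurtosis.
#' @export
sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 finite values to compute kurtosis")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(3)
  mean((x - m)^4) / m2^2
}

#' Round half away from zero
#'
#' Commercial rounding used for report display of percentages (58.5 -> 59,
#' -47.5 -> -48), unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Scoped seeding: set the RNG seed without clobbering the caller's RNG
# stream. Used by every stochastic operation that takes a `seed` argument.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Internal assert helper with sprintf-style messages.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
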