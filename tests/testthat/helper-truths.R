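# Shared ground-truth worlds for simulation-based tests.

# High signal-to-noise increasing exponential: a hits-like parameter whose
# mean rises ~229% from ~95 units at age 5, with the expected absolute
# deviation of the noise shrinking 74% across the age range and an 8-unit
# sex offset. Rate and variability slope are well identified at n = 576.
hits_truth <- function(per_hand = TRUE) {
  a1 <- log(3.29) / 13          # +229% across ages 5..18
  ground_truth(
    family = "exponential",
    a0 = 95 / exp(5 * a1), a1 = a1, a2 = 8, a3 = 4, a4 = 0,
    noise_intercept = 21.45, noise_slope = -0.9508,  # E|eps|: 16.7 -> 4.3
    per_hand = per_hand, parameter = "hits"
  )
}

# Reaction-time-like decaying exponential with additive offset; low
# signal-to-noise mean trend but strongly shrinking variability.
rt_truth <- function() {
  ground_truth(
    family = "exponential",
    a0 = 0.45, a1 = -0.134, a2 = 0.01, a3 = 0.005, a4 = 0.12,
    noise_intercept = 0.0701, noise_slope = -0.00312,
    per_hand = TRUE, parameter = "RT"
  )
}

# Bias-like quadratic spanning zero, with strongly right-skewed noise —
# exercises the quadratic family and the transform ladder.
skewed_bias_truth <- function() {
  ground_truth(
    family = "quadratic",
    a0 = -0.02, a1 = 0.9, a4 = -3,
    noise_intercept = 2, noise_slope = 0,
    noise_shape = "skewed", noise_skew = 2,
    per_hand = FALSE, parameter = "bias"
  )
}

# Convenience: simulate a full table from demographics + truth.
sim_cohort <- function(n, truth, seed, demo = demographics(n)) {
  coh <- generate_cohort(demo, seed = seed)
  simulate_parameter(coh, truth, seed = seed + 10000L)
}
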