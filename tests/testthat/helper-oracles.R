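# Independent brute-force oracles, kept free of the package's code paths.

# U statistic by direct pairwise comparison with half-credit ties.
brute_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n_a + n_b, n_a) labelings of the pooled sample (tie-free inputs).
brute_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  picks <- utils::combn(n, na)
  u_all <- apply(picks, 2, function(idx) brute_u(pooled[idx], pooled[-idx]))
  u_obs <- brute_u(a, b)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Small hand-built patient table used across tests.
toy_cohort <- function(cohort = "A") {
  tibble::tibble(
    patient_id = paste0(cohort, 1:4),
    cohort = cohort,
    weight = c(70, 44, 95, 56),
    height = c(178.4, NA, 180, 165),
    gender = c("male", "female", "male", "female"),
    injected_activity = c(150, 150, 300, 250),
    dlp = c(420, 200, 600, 310))
}
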