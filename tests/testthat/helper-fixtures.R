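# Shared fixture builders and independent oracles.

# Tiny founder panel + cohort used across HMM / scan tests.
tiny_cohort <- function(n_snps = 100, n_chroms = 2, n_strains = 50,
                        bp = 3, err = 0, seed = 11) {
  panel <- simulate_founders(n_snps, n_chroms, seed = seed)
  coh <- simulate_cc_cohort(panel, n_strains,
                            expected_breakpoints_per_chrom = bp,
                            genotype_error_rate = err, seed = seed + 1)
  list(panel = panel, cohort = coh)
}

# Independent HMM oracle: brute-force enumeration over all 8^n state paths.
# Same model definition (haploid 8-state, symmetric emission error,
# exponential-distance transition kernel) computed by exhaustive summation.
brute_force_posterior <- function(calls, alleles, pos, eps, gamma,
                                  prior = rep(1 / 8, 8)) {
  n <- length(calls)
  stopifnot(n <= 6)  # 8^6 = 262144 paths
  paths <- as.matrix(expand.grid(rep(list(1:8), n)))
  logp <- log(prior[paths[, 1]])
  for (t in seq_len(n)) {
    if (!is.na(calls[t])) {
      match_t <- alleles[t, paths[, t]] == calls[t]
      logp <- logp + log(ifelse(match_t, 1 - eps, eps))
    }
    if (t > 1) {
      d <- pos[t] - pos[t - 1]
      stay <- exp(-gamma * d)
      same <- paths[, t] == paths[, t - 1]
      logp <- logp + log(ifelse(same, stay, (1 - stay) / 7))
    }
  }
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  post <- matrix(0, n, 8)
  for (t in seq_len(n)) for (k in 1:8)
    post[t, k] <- sum(w[paths[, t] == k])
  post
}

# Independent circular-statistics oracle: direct complex-exponential sum on
# doubled angles.
complex_sum_summary <- function(theta_deg, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(theta_deg))
  z <- sum(weights * exp(2i * theta_deg * pi / 180)) / sum(weights)
  list(MVL = Mod(z), theta_m = (Arg(z) * 180 / pi / 2) %% 180)
}

# Axial angular distance in degrees (on the 180-degree circle).
axial_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Sinusoidal stripe image: intensity constant along direction theta_deg.
stripe_image <- function(theta_deg, shape = c(128, 128), wavelength = 8) {
  th <- theta_deg * pi / 180
  x <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
  y <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
  0.5 + 0.5 * sin(2 * pi * (-x * sin(th) + y * cos(th)) / wavelength)
}
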