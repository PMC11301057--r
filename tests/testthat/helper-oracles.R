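# Independent oracles used to check the disproportionality statistics, kept
# deliberately separate from the package's own computation paths.

# random 2x2 suite with counts in the regime screening operates at
random_2x2_suite <- function(n, seed) {
  set.seed(seed)
  data.frame(a = sample(20:200, n, replace = TRUE),
             b = sample(100:5000, n, replace = TRUE),
             c = sample(50:2000, n, replace = TRUE),
             d = sample(5000:200000, n, replace = TRUE))
}

# ROR and Woolf CI, transcribed in a different factorization
ror_oracle <- function(a, b, c, d) {
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = or, low = exp(log(or) - 1.96 * se), high = exp(log(or) + 1.96 * se))
}

# PRR directly from the reporting proportions
prr_oracle <- function(a, b, c, d) (a * (c + d)) / (c * (a + b))

# Pearson chi-squared by brute-force observed-minus-expected over the 4 cells
chi2_oracle <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Monte-Carlo posterior of the information component: sample the drug and
# event marginal probabilities from their Beta posteriors, recompute the
# prior-balancing gamma per draw, sample the joint probability from its
# conditional Beta posterior, and average log2(p11 / (px * py)).
bcpnn_mc_oracle <- function(a, b, c, d, ndraws = 1e6, seed = 1) {
  set.seed(seed)
  N <- a + b + c + d
  n1 <- a + b
  n2 <- a + c
  px <- rbeta(ndraws, n1 + 1, N - n1 + 1)
  py <- rbeta(ndraws, n2 + 1, N - n2 + 1)
  g <- 1 / (px * py)
  p11 <- rbeta(ndraws, a + 1, N - a + g - 1)
  mean(log2(p11 / (px * py)))
}

# EBGM by numerical quadrature of E[log lambda] under the posterior gamma
# mixture (posterior weight recomputed from the marginal densities here)
ebgm_quadrature_oracle <- function(a, E, prior) {
  f1 <- prior$w * dnbinom(a, size = prior$alpha1,
                          prob = prior$beta1 / (prior$beta1 + E))
  f2 <- (1 - prior$w) * dnbinom(a, size = prior$alpha2,
                                prob = prior$beta2 / (prior$beta2 + E))
  q <- f1 / (f1 + f2)
  dens <- function(l) {
    q * dgamma(l, shape = prior$alpha1 + a, rate = prior$beta1 + E) +
      (1 - q) * dgamma(l, shape = prior$alpha2 + a, rate = prior$beta2 + E)
  }
  hi <- max(qgamma(1 - 1e-13, shape = prior$alpha1 + a, rate = prior$beta1 + E),
            qgamma(1 - 1e-13, shape = prior$alpha2 + a, rate = prior$beta2 + E))
  m <- integrate(function(l) log(l) * dens(l), 0, hi, rel.tol = 1e-11,
                 subdivisions = 400L)$value
  exp(m)
}

# convenience: run the full screening pipeline on a generated database
screen_synthetic <- function(g, level = "PT", criteria = signal_criteria()) {
  cases <- deduplicate(assemble_cases(g$tables))
  cohort <- extract_cohort(cases, synthetic_drug_terms())
  map <- as_pt_soc_map(synthetic_pt_soc_table(g$truth$config$n_events))
  ev <- code_events(cases, map)
  screen_signals(ev, cohort$cohort_ids, level, criteria)
}

recovery_config <- function(seed) {
  sim_config(n_reports = 20000L, target_drug_share = 0.06,
             implanted_signals = list(list(event = 25, rho = 10),
                                      list(event = 35, rho = 10),
                                      list(event = 45, rho = 10)),
             seed = seed)
}
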