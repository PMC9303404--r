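# Shared fixtures: the single-condition study rates (order of the 150 mM
# KAc condition at 34 C) and small synthetic traces built in code.

fixture_rates <- function() {
  rate_constants(k1 = 0.1, k_neg1 = 1.7, k2 = 0.16,
                 k3 = 0.0525, k_neg3 = 0.0389, k5 = 0.0385,
                 R_conc = 5)
}

# Deterministic two-level step series: CS level 900 nm, one OS visit.
step_series <- function(n = 1000, at = 500, jump = 73, level = 900,
                        noise = 0, seed = 1) {
  set.seed(seed)
  z <- rep(level, n)
  z[(at + 1):n] <- level - jump
  if (noise > 0) z <- z + rnorm(n, sd = noise)
  z
}

# Draw from a two-exponential mixture.
rexpmix <- function(n, k_plus, k_minus, p_minus, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slow <- runif(n) < p_minus
  ifelse(slow, rexp(n, k_minus), rexp(n, k_plus))
}

expmix_cdf <- function(q, k_plus, k_minus, p_minus) {
  1 - (1 - p_minus) * exp(-k_plus * q) - p_minus * exp(-k_minus * q)
}
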