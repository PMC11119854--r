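# Independent oracles used across the suite. These re-derive, by a different
# route, the quantities the package computes, and stay free of the code paths
# they check.

# Shunt forward model by closed-form algebra: the arterial-content fixed point
# Ca = (1 - q) Cc + q (Ca - avDO2) solves exactly to Ca = Cc - q avDO2/(1 - q);
# arterial saturation then comes from bisection (uniroot) on the monotone
# content curve, independent of the package's Newton inversion.
oracle_sao2 <- function(fio2, q, v, paco2, hb = 12, const = physio_constants()) {
  pc <- max(fio2 * (const$Pb - const$PH2O) - paco2 / const$RQ - v, 0)
  sev <- function(p) ifelse(p == 0, 0, 1 / (1 + 23400 / (p^3 + 150 * p)))
  cc <- const$hb_O2_capacity * hb * sev(pc) + const$dissolved_O2_coeff * pc
  ca <- cc - q * const$avDO2 / (1 - q)
  if (ca <= 0) return(0)
  g <- function(p) const$hb_O2_capacity * hb * sev(p) + const$dissolved_O2_coeff * p - ca
  if (g(1500) < 0) return(sev(1500))
  sev(stats::uniroot(g, c(1e-12, 1500), tol = 1e-14)$root)
}

# Pearson chi-squared by direct Sum (O - E)^2 / E
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# OLS slope/intercept by the closed-form normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# a full 8-zone ultrasound exam as a one-row data frame
lus_exam <- function(scores) {
  stopifnot(length(scores) == 8)
  stats::setNames(as.data.frame(as.list(scores)), lus_zones())
}
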