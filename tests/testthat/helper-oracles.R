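# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and lm) so that agreement is informative.

# Closed-form normal-equations OLS: coefficients, SEs, covariance, R^2.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (length(y) - 2)
  V <- sigma2 * XtX_inv
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       se_intercept = sqrt(V[1, 1]), se_slope = sqrt(V[2, 2]),
       cov_ab = V[1, 2], r_squared = 1 - sum(resid^2) / ss_tot)
}

# Invert the standard normal CDF by bisection (oracle for probit()).
qnorm_bisect <- function(p, tol = 1e-10) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Grid-scan oracle for the non-parallel additive bounds: walk a dense
# log-spaced grid of total doses along the fixed-ratio ray and locate the
# sign change of each isobole residual.
grid_scan_bounds <- function(fit_a, fit_b, a50, b50, fraction, n = 1e6) {
  totals <- 10^seq(log10(min(a50, b50) * 1e-4), log10(a50 + b50),
                   length.out = n)
  s <- fraction * a50 + (1 - fraction) * b50
  a <- totals * fraction * a50 / s
  b <- totals * (1 - fraction) * b50 / s
  beq <- 10^((fit_a$slope * log10(a) + fit_a$intercept - fit_b$intercept) /
               fit_b$slope)
  aeq <- 10^((fit_b$slope * log10(b) + fit_b$intercept - fit_a$intercept) /
               fit_a$slope)
  r1 <- b + beq - b50
  r2 <- a + aeq - a50
  cross <- function(r) {
    i <- which(diff(sign(r)) != 0)[1]
    # linear interpolation across the bracketing pair
    totals[i] + (totals[i + 1] - totals[i]) * abs(r[i]) /
      (abs(r[i]) + abs(r[i + 1]))
  }
  sort(c(cross(r1), cross(r2)))
}

# Random positive-slope probit line pair with distinct potencies.
random_line_pair <- function() {
  a50 <- 10^runif(1, -1, 2)
  b50 <- 10^runif(1, -3, 1)
  sa <- runif(1, 1, 5)
  sb <- runif(1, 1, 5)
  list(
    fit_a = probit_fit(sa, 5 - sa * log10(a50), n_items = 48),
    fit_b = probit_fit(sb, 5 - sb * log10(b50), n_items = 48),
    a50 = a50, b50 = b50
  )
}

# Simulated plate with viability noise plus its OLS fit, for SEM checks.
noisy_fit <- function(seed, ic50 = 50, slope = 2.3, noise_sd = 2) {
  plate <- simulate_drug(drug_truth("X", ic50, slope, noise_sd = noise_sd),
                         seed = seed)
  fit_probit_line(plate)
}
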