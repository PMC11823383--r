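test_that("viability normalisation returns the clamped fraction affected", {
  expect_equal(effect_from_viability(100, 100), 0)
  expect_equal(effect_from_viability(0, 100), 1)
  expect_equal(effect_from_viability(25, 100), 0.75)
  expect_equal(effect_from_viability(60, 80), 0.25)
  # over-100% viability (stimulation) clamps to zero effect
  expect_equal(effect_from_viability(130, 100), 0)
  expect_error(effect_from_viability(50, 0), "control_mean")
  expect_error(effect_from_viability(-1, 100), "non-negative")
})

test_that("probit is NED + 5 and matches a bisection inversion of pnorm", {
  expect_equal(probit(0.5), 5)
  expect_equal(probit(0.841345), 6, tolerance = 1e-5)
  # independent oracle: invert the normal CDF by bisection
  for (p in c(0.10, 0.025, 0.6, 0.9987)) {
    expect_equal(probit(p), qnorm_bisect(p) + 5, tolerance = 1e-8)
  }
  expect_equal(probit(0.10), 3.7184, tolerance = 1e-4)
  expect_error(probit(0), "strictly inside")
  expect_error(probit(1), "strictly inside")
})

test_that("probit is strictly increasing and inv_probit inverts it", {
  p <- seq(0.001, 0.999, length.out = 200)
  y <- probit(p)
  expect_true(all(diff(y) > 0))
  expect_equal(inv_probit(y), p, tolerance = 1e-12)
})

test_that("noise-free probit-linear data are recovered exactly", {
  doses <- c(1, 10, 100)
  eff <- inv_probit(2 * log10(doses) + 3)
  d <- tibble::tibble(dose_um = doses, effect = eff)
  fit <- suppressWarnings(fit_probit_line(d))
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_items, 3L)
  expect_equal(fit$n_doses, 3L)
  est <- ic50(fit)
  expect_equal(est$ic50, 10^((5 - 3) / 2), tolerance = 1e-9)
})

test_that("OLS coefficients match the normal-equations oracle on random data", {
  set.seed(42)
  for (i in 1:25) {
    n_dose <- sample(3:8, 1)
    doses <- 10^sort(runif(n_dose, -1, 2.5))
    reps <- sample(2:6, 1)
    slope <- runif(1, 0.8, 4)
    int <- runif(1, -2, 4)
    x <- rep(log10(doses), each = reps)
    y <- slope * x + int + rnorm(length(x), sd = 0.4)
    d <- tibble::tibble(dose_um = 10^x, effect = inv_probit(pmin(pmax(y, -3), 13)))
    fit <- fit_probit_line(d)
    o <- ols_oracle(log10(d$dose_um), probit(d$effect))
    expect_equal(fit$slope, o$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, o$intercept, tolerance = 1e-9)
    expect_equal(fit$se_slope, o$se_slope, tolerance = 1e-9)
    expect_equal(fit$se_intercept, o$se_intercept, tolerance = 1e-9)
    expect_equal(fit$cov_ab, o$cov_ab, tolerance = 1e-9)
    expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-9)
  }
})

test_that("dose rescaling leaves the slope unchanged and scales the IC50", {
  plate <- simulate_drug(drug_truth("X", 50, 2.3), seed = 7)
  fit1 <- fit_probit_line(plate)
  for (c_scale in c(0.1, 2, 37)) {
    scaled <- dplyr::mutate(plate, dose_um = dose_um * c_scale)
    fit2 <- fit_probit_line(scaled)
    expect_equal(fit2$slope, fit1$slope, tolerance = 1e-9)
    expect_equal(ic50(fit2)$ic50, ic50(fit1)$ic50 * c_scale, tolerance = 1e-9)
    expect_equal(ic50(fit2)$sem, ic50(fit1)$sem * c_scale, tolerance = 1e-9)
  }
})

test_that("IC50 extraction reproduces published log-probit equations", {
  expect_equal(ic50(probit_fit(4.3531, -3.4047, n_items = 10))$ic50, 85.26,
               tolerance = 0.005 / 85.26)
  expect_equal(ic50(probit_fit(2.2979, 1.0988, n_items = 10))$ic50, 49.86,
               tolerance = 0.005 / 49.86)
  expect_equal(ic50(probit_fit(2.0, 5.0, n_items = 10))$ic50, 1.0,
               tolerance = 1e-12)
})

test_that("degenerate and inverted fits are refused or flagged", {
  expect_error(ic50(probit_fit(0, 2, n_items = 5)), "slope is zero")
  inv <- probit_fit(-1.5, 8, n_items = 5)
  expect_true(inv$inverted)
  expect_warning(ic50(inv), "inverted")
  # single usable dose level is unfittable
  d <- tibble::tibble(dose_um = c(10, 10, 10), effect = c(0.4, 0.5, 0.6))
  expect_error(fit_probit_line(d), "distinct dose")
  # all-saturated data are unfittable
  d2 <- tibble::tibble(dose_um = c(1, 10), effect = c(0, 1))
  expect_error(fit_probit_line(d2), "unfittable")
})

test_that("saturation policies drop or clamp boundary effects", {
  d <- tibble::tibble(
    dose_um = rep(c(1, 10, 100), each = 4),
    effect = c(0, 0.1, 0.12, 0.08, 0.45, 0.5, 0.55, 0.6, 1, 1, 0.97, 0.99)
  )
  fit_drop <- fit_probit_line(d, saturation = "drop")
  expect_equal(fit_drop$n_items, 9L)
  fit_clamp <- fit_probit_line(d, saturation = "clamp")
  expect_equal(fit_clamp$n_items, 12L)
  # clamp bound is 1/(2m) with m = 4 wells per dose
  expect_true(all(abs(fit_clamp$slope - fit_drop$slope) < 1))
})

test_that("per-dose-mean aggregation fits dose-level means", {
  plate <- simulate_drug(drug_truth("X", 50, 2.3), seed = 11)
  fit <- fit_probit_line(plate, aggregation = "per_dose_mean")
  expect_equal(fit$n_items, 6L)
  means <- plate |>
    dplyr::group_by(dose_um) |>
    dplyr::summarise(effect = mean(effect))
  o <- ols_oracle(log10(means$dose_um), probit(means$effect))
  expect_equal(fit$slope, o$slope, tolerance = 1e-9)
})

test_that("delta-method SEM is exact for zero-variance fits and scales with dose", {
  f0 <- probit_fit(2.5, 1.0, se_slope = 0, se_intercept = 0, n_items = 10)
  expect_equal(ic50_sem(f0), 0)
  expect_equal(ic50(f0)$sem, 0)
})

test_that("delta-method SEM agrees with a parametric bootstrap oracle", {
  fit <- noisy_fit(101)
  # draw (intercept, slope) from the fitted bivariate normal by Cholesky
  Sigma <- matrix(c(fit$se_intercept^2, fit$cov_ab,
                    fit$cov_ab, fit$se_slope^2), 2, 2)
  L <- chol(Sigma)
  set.seed(2024)
  z <- matrix(rnorm(2 * 2000), ncol = 2) %*% L
  draws <- 10^((5 - (fit$intercept + z[, 1])) / (fit$slope + z[, 2]))
  boot_sem <- sd(draws)
  expect_equal(ic50_sem(fit), boot_sem, tolerance = 0.15)
})

test_that("fit summaries tidy and glance into the documented schema", {
  plate <- simulate_drug(drug_truth("EX527", 50, 2.3), seed = 5)
  fit <- fit_probit_line(plate)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(fit)
  expect_named(gl, c("treatment", "slope", "intercept", "r_squared",
                     "se_slope", "se_intercept", "cov_ab", "n_items",
                     "n_doses", "ic50_um", "sem_um"))
  expect_equal(gl$treatment, "EX527")
  expect_equal(gl$ic50_um, ic50(fit)$ic50)
})
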