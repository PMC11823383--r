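test_that("identical fits are parallel; clearly different slopes are not", {
  f <- probit_fit(2.3, 1.0, se_slope = 0.2, n_items = 48)
  res <- test_parallelism(f, f)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$is_parallel)

  a <- probit_fit(2.0, 1.0, se_slope = 0.01, n_items = 50)
  b <- probit_fit(4.0, -2.0, se_slope = 0.01, n_items = 50)
  res2 <- test_parallelism(a, b)
  expect_equal(res2$t_stat, 2 / sqrt(2 * 0.01^2), tolerance = 1e-9)
  expect_false(res2$is_parallel)
})

test_that("zero slope variance with unequal slopes is flagged degenerate", {
  a <- probit_fit(2.0, 1.0, se_slope = 0, n_items = 50)
  b <- probit_fit(3.0, 1.0, se_slope = 0, n_items = 50)
  res <- test_parallelism(a, b)
  expect_false(res$is_parallel)
  expect_equal(res$p_value, 0)
  expect_true(res$degenerate)
})

test_that("the parallelism test holds its size under the probit-linear model", {
  # same-slope truth, homoscedastic probit-scale noise: the statistic's own
  # model assumptions, under which its null distribution is (near) exact
  set.seed(77)
  doses <- 50 * 2^(-2:3)
  x <- rep(log10(doses), each = 8)
  one_fit <- function() {
    y <- 2.3 * (x - log10(50)) + 5 + rnorm(length(x), sd = 0.35)
    fit_probit_line(tibble::tibble(dose_um = 10^x, effect = inv_probit(y)))
  }
  rejections <- vapply(seq_len(2000), function(i) {
    !test_parallelism(one_fit(), one_fit())$is_parallel
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("parallel additivity follows the straight-line isobole formula", {
  eq <- additive_parallel(potency_estimate(10, 1, 50), potency_estimate(10, 1, 50))
  expect_equal(eq$lower, 10)
  expect_true(eq$parallel_case)
  expect_equal(eq$n_add, 100L)

  # a vastly more potent partner contributes almost nothing to the total
  bt <- additive_parallel(potency_estimate(49.86, 3.6, 92, "EX527"),
                          potency_estimate(0.005, 0.001, 48, "PAX"))
  expect_equal(bt$lower, 24.93, tolerance = 0.01 / 24.93)

  s <- additive_parallel(potency_estimate(10, 3, 50), potency_estimate(10, 4, 50))
  expect_equal(s$sem_lower, 2.5)
})

test_that("parallel additivity is exchange-symmetric", {
  set.seed(1)
  for (i in 1:20) {
    a <- potency_estimate(10^runif(1, -2, 2), runif(1, 0, 2), sample(10:200, 1))
    b <- potency_estimate(10^runif(1, -2, 2), runif(1, 0, 2), sample(10:200, 1))
    f <- runif(1, 0.05, 0.95)
    p1 <- additive_parallel(a, b, fraction = f)
    p2 <- additive_parallel(b, a, fraction = 1 - f)
    expect_equal(p1$lower, p2$lower, tolerance = 1e-12)
    expect_equal(p1$sem_lower, p2$sem_lower, tolerance = 1e-12)
    expect_equal(p1$n_add, p2$n_add)
  }
})

test_that("dose equivalence matches effect-matching through probit inversion", {
  set.seed(2)
  for (i in 1:20) {
    pr <- random_line_pair()
    dose_a <- 10^runif(1, log10(pr$a50) - 1, log10(pr$a50) + 1)
    got <- dose_equivalent(pr$fit_a, pr$fit_b, dose_a)
    # oracle: effect of dose_a through A's line, re-inverted through B's line
    eff <- inv_probit(pr$fit_a$slope * log10(dose_a) + pr$fit_a$intercept)
    oracle <- 10^((probit(eff) - pr$fit_b$intercept) / pr$fit_b$slope)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
  # at A's own IC50 the equivalent dose is exactly B's IC50
  pr <- random_line_pair()
  expect_equal(dose_equivalent(pr$fit_a, pr$fit_b, pr$a50), pr$b50,
               tolerance = 1e-9)
  # equal slopes reduce to a constant potency ratio
  fa <- probit_fit(2.0, 5 - 2 * log10(20), n_items = 10)
  fb <- probit_fit(2.0, 5 - 2 * log10(5), n_items = 10)
  expect_equal(dose_equivalent(fa, fb, 8), 8 * 5 / 20, tolerance = 1e-12)
})

test_that("non-parallel bounds collapse onto the parallel value at equal slopes", {
  set.seed(3)
  for (i in 1:10) {
    s <- runif(1, 1, 4)
    a50 <- 10^runif(1, 0, 2)
    b50 <- 10^runif(1, -3, 0)
    fa <- probit_fit(s, 5 - s * log10(a50), n_items = 48)
    fb <- probit_fit(s, 5 - s * log10(b50), n_items = 48)
    f <- runif(1, 0.1, 0.9)
    np <- additive_nonparallel(fa, fb, fraction = f)
    par <- additive_parallel(ic50(fa), ic50(fb), fraction = f)
    expect_equal(np$lower, par$lower, tolerance = 1e-6)
    expect_equal(np$upper, par$lower, tolerance = 1e-6)
    expect_lte((np$upper - np$lower) / np$lower, 1e-6)
  }
})

test_that("the bisection root-finder agrees with a dense grid-scan oracle", {
  set.seed(4)
  for (i in 1:6) {
    pr <- random_line_pair()
    np <- additive_nonparallel(pr$fit_a, pr$fit_b, fraction = 0.5)
    oracle <- grid_scan_bounds(pr$fit_a, pr$fit_b, pr$a50, pr$b50, 0.5)
    expect_equal(np$lower, oracle[1], tolerance = 1e-4)
    expect_equal(np$upper, oracle[2], tolerance = 1e-4)
  }
})

test_that("curved isoboles bracket the straight additive line", {
  fa <- probit_fit(4.35, 5 - 4.35 * log10(85), n_items = 48)
  fb <- probit_fit(1.5, 5 - 1.5 * log10(0.005), n_items = 48)
  np <- additive_nonparallel(fa, fb)
  straight <- 0.5 * 85 + 0.5 * 0.005
  expect_lt(np$lower, straight)
  expect_gt(np$upper, straight)
  expect_true(np$lower > 0)
  expect_true(np$upper < 2 * max(85, 0.005))
})

test_that("non-parallel bound SEMs are propagated and shrink with precision", {
  fa <- probit_fit(4.35, 5 - 4.35 * log10(85), se_slope = 0.2,
                   se_intercept = 0.3, cov_ab = -0.05, n_items = 48)
  fb <- probit_fit(1.5, 5 - 1.5 * log10(0.005), se_slope = 0.1,
                   se_intercept = 0.2, cov_ab = -0.01, n_items = 48)
  np <- additive_nonparallel(fa, fb)
  expect_gt(np$sem_lower, 0)
  expect_gt(np$sem_upper, 0)
  # exact coefficients propagate zero uncertainty
  fa0 <- probit_fit(4.35, 5 - 4.35 * log10(85), n_items = 48)
  fb0 <- probit_fit(1.5, 5 - 1.5 * log10(0.005), n_items = 48)
  np0 <- additive_nonparallel(fa0, fb0)
  expect_equal(np0$sem_lower, 0)
  expect_equal(np0$sem_upper, 0)
})

test_that("isobologram geometry is consistent with its construction", {
  est_a <- potency_estimate(50, 2, 48, "A")
  est_b <- potency_estimate(10, 1, 48, "B")
  pred <- additive_parallel(est_a, est_b)
  mix <- potency_estimate(28, 2, 48, "mix")
  coords <- isobologram_coordinates(pred, mix = mix, resolution = 50)
  lower <- dplyr::filter(coords, curve_id == "additive_lower")
  upper <- dplyr::filter(coords, curve_id == "additive_upper")
  # parallel case: the two isoboles coincide pointwise
  expect_equal(lower$dose_b_um, upper$dose_b_um, tolerance = 1e-12)
  # endpoints are the axis intercepts
  expect_equal(lower$dose_a_um[1], 50)
  expect_equal(lower$dose_b_um[1], 0)
  expect_equal(lower$dose_a_um[nrow(lower)], 0)
  expect_equal(lower$dose_b_um[nrow(lower)], 10)
  # M lies on the fixed-ratio ray
  m <- dplyr::filter(coords, curve_id == "experimental_mix")
  expect_equal(m$dose_a_um / m$dose_b_um, (0.5 * 50) / (0.5 * 10),
               tolerance = 1e-9)
  expect_equal(m$dose_a_um + m$dose_b_um, 28, tolerance = 1e-9)
})

test_that("non-parallel isobologram curves end at the axis intercepts", {
  fa <- probit_fit(4.35, 5 - 4.35 * log10(85), n_items = 48)
  fb <- probit_fit(1.5, 5 - 1.5 * log10(0.005), n_items = 48)
  np <- additive_nonparallel(fa, fb)
  coords <- isobologram_coordinates(np, resolution = 40)
  for (cid in c("additive_lower", "additive_upper")) {
    cur <- dplyr::filter(coords, curve_id == cid)
    expect_equal(cur$dose_a_um[1], 85, tolerance = 1e-9)
    expect_equal(cur$dose_b_um[1], 0, tolerance = 1e-9)
    expect_equal(cur$dose_a_um[nrow(cur)], 0, tolerance = 1e-9)
    expect_equal(cur$dose_b_um[nrow(cur)], 0.005, tolerance = 1e-6)
  }
  p <- autoplot(coords)
  expect_s3_class(p, "ggplot")
})

test_that("inverted fits are refused by isobolographic routines", {
  inv <- probit_fit(-2, 8, n_items = 10, label = "inv")
  ok <- probit_fit(2, 1, n_items = 10)
  expect_error(test_parallelism(inv, ok), "negative slope")
  expect_error(dose_equivalent(ok, inv, 1), "negative slope")
})
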