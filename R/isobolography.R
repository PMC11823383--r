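#' Test parallelism of two log-probit lines
#'
#' Compares the fitted slopes of two concentration-response lines with a
#' Welch-type statistic, `t = (b_A - b_B) / sqrt(se_A^2 + se_B^2)`, and
#' Welch-Satterthwaite degrees of freedom computed from the two slope
#' variances with denominators `n_items - 2` (residual df of each line).
#' Parallel curves share a common slope, so the additive isobole is the
#' straight line joining the two IC50 axis intercepts; non-parallel curves
#' call for the pair of bounding dose-equivalence isoboles
#' ([additive_nonparallel()]).
#'
#' @param fit_a,fit_b `probit_fit` objects for the two single agents.
#' @param alpha Significance level (default 0.05); slopes are declared
#'   parallel when `p > alpha`.
#' @return An object of class `parallelism_test` with `t_stat`, `df`,
#'   `p_value`, `is_parallel`, `alpha`, and a `degenerate` flag set when
#'   both slope variances are zero.
#' @examples
#' a <- probit_fit(2.3, 1.2, se_slope = 0.2, n_items = 48)
#' b <- probit_fit(2.4, 8.0, se_slope = 0.25, n_items = 48)
#' test_parallelism(a, b)
#' @export
test_parallelism <- function(fit_a, fit_b, alpha = 0.05) {
  stopifnot(inherits(fit_a, "probit_fit"), inherits(fit_b, "probit_fit"))
  check_alpha(alpha)
  refuse_inverted(fit_a, fit_b)
  va <- fit_a$se_slope^2
  vb <- fit_b$se_slope^2
  pooled <- va + vb
  degenerate <- FALSE
  if (pooled == 0) {
    if (fit_a$slope == fit_b$slope) {
      t_stat <- 0; df <- Inf; p <- 1
    } else {
      t_stat <- Inf; df <- Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t_stat <- (fit_a$slope - fit_b$slope) / sqrt(pooled)
    df_a <- fit_a$n_items - 2L
    df_b <- fit_b$n_items - 2L
    if (va == 0) {
      df <- df_b
    } else if (vb == 0) {
      df <- df_a
    } else {
      df <- pooled^2 / (va^2 / df_a + vb^2 / df_b)
    }
    p <- p_two_sided(t_stat, df)
  }
  structure(
    list(t_stat = abs(t_stat), df = df, p_value = p,
         is_parallel = p > alpha, alpha = alpha,
         slope_a = fit_a$slope, slope_b = fit_b$slope,
         degenerate = degenerate),
    class = "parallelism_test"
  )
}

#' @export
print.parallelism_test <- function(x, ...) {
  cat("Parallelism test of log-probit slopes\n")
  cat(sprintf("  slopes: %.4f vs %.4f\n", x$slope_a, x$slope_b))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3f -> %s (alpha = %g)\n",
              x$t_stat, x$df, x$p_value,
              if (x$is_parallel) "parallel" else "non-parallel", x$alpha))
  invisible(x)
}

#' @method tidy parallelism_test
#' @export
tidy.parallelism_test <- function(x, ...) {
  tibble::tibble(t_stat = x$t_stat, df = x$df, p_value = x$p_value,
                 is_parallel = x$is_parallel, alpha = x$alpha)
}

#' Construct an additive prediction from published bounds
#'
#' Builds the additive-IC50 object that [additive_parallel()] /
#' [additive_nonparallel()] return, directly from summary numbers — the
#' entry point for re-analysing a published interaction table. Supply equal
#' `lower` and `upper` (the default) for a parallel-curve single additive
#' value.
#'
#' @param lower,upper Lower and upper additive total-concentration IC50,
#'   uM (`upper` defaults to `lower`).
#' @param sem_lower,sem_upper Their standard errors, uM.
#' @param n_add Total item count behind the additive estimate.
#' @param fraction Fixed-ratio fraction f (default 0.5).
#' @return An `additive_prediction`.
#' @examples
#' additive_prediction(lower = 25.38, sem_lower = 5.67, n_add = 188)
#' @export
additive_prediction <- function(lower, upper = lower, sem_lower = 0,
                                sem_upper = sem_lower, n_add, fraction = 0.5) {
  check_fraction(fraction)
  new_additive_prediction(
    lower = lower, upper = upper, sem_lower = sem_lower,
    sem_upper = sem_upper, n_add = n_add,
    parallel_case = isTRUE(all.equal(lower, upper)), fraction = fraction,
    est_a = NULL, est_b = NULL
  )
}

new_additive_prediction <- function(lower, upper, sem_lower, sem_upper, n_add,
                                    parallel_case, fraction, est_a, est_b,
                                    fit_a = NULL, fit_b = NULL) {
  stopifnot(lower > 0, upper >= lower, sem_lower >= 0, sem_upper >= 0)
  structure(
    list(lower = lower, upper = upper, sem_lower = sem_lower,
         sem_upper = sem_upper, n_add = as.integer(n_add),
         parallel_case = parallel_case, fraction = fraction,
         est_a = est_a, est_b = est_b, fit_a = fit_a, fit_b = fit_b),
    class = "additive_prediction"
  )
}

#' @export
print.additive_prediction <- function(x, ...) {
  cat("Theoretical additive IC50 (fixed-ratio mixture, total concentration)\n")
  if (x$parallel_case) {
    cat(sprintf("  IC50_add = %.4g +/- %.4g uM (parallel curves, n_add = %d)\n",
                x$lower, x$sem_lower, x$n_add))
  } else {
    cat(sprintf("  lower IC50_add = %.4g +/- %.4g uM\n", x$lower, x$sem_lower))
    cat(sprintf("  upper IC50_add = %.4g +/- %.4g uM (non-parallel curves, n_add = %d)\n",
                x$upper, x$sem_upper, x$n_add))
  }
  invisible(x)
}

#' @method tidy additive_prediction
#' @export
tidy.additive_prediction <- function(x, ...) {
  tibble::tibble(
    l_ic50_add = x$lower, sem_l = x$sem_lower,
    u_ic50_add = x$upper, sem_u = x$sem_upper,
    n_add = x$n_add, parallel_case = x$parallel_case, fraction = x$fraction
  )
}

#' Additive IC50 for parallel concentration-response curves
#'
#' For a fixed-ratio mixture whose additive reference point contributes drug
#' A at fraction `f` of its IC50 (f = 0.5 for a 1:1 ratio), the additive
#' total-concentration IC50 is the point on the straight-line isobole,
#' `IC50_add = f * IC50_A + (1 - f) * IC50_B`, with SEM
#' `sqrt((f sem_A)^2 + ((1-f) sem_B)^2)` and `n_add = n_A + n_B`.
#'
#' @param est_a,est_b `potency_estimate` objects for the two single agents.
#' @param fraction Fraction `f` in (0, 1) of drug A's IC50 contributed at
#'   the additive point; 0.5 encodes the 1:1 fixed ratio.
#' @return An `additive_prediction` with equal lower and upper values.
#' @examples
#' a <- potency_estimate(49.86, sem = 3.6, n_items = 92, label = "EX527")
#' b <- potency_estimate(0.005, sem = 0.001, n_items = 48, label = "PAX")
#' additive_parallel(a, b)
#' @export
additive_parallel <- function(est_a, est_b, fraction = 0.5) {
  stopifnot(inherits(est_a, "potency_estimate"), inherits(est_b, "potency_estimate"))
  check_fraction(fraction)
  add <- fraction * est_a$ic50 + (1 - fraction) * est_b$ic50
  sem <- sqrt((fraction * est_a$sem)^2 + ((1 - fraction) * est_b$sem)^2)
  new_additive_prediction(
    lower = add, upper = add, sem_lower = sem, sem_upper = sem,
    n_add = est_a$n_items + est_b$n_items, parallel_case = TRUE,
    fraction = fraction, est_a = est_a, est_b = est_b
  )
}

#' Dose of drug B equivalent to a dose of drug A
#'
#' Converts a dose of drug A into the dose of drug B producing the same
#' probit effect through the two fitted lines (relative-potency / dose-
#' equivalence construction): the probit effect of `dose_a` on A's line is
#' re-inverted through B's line,
#' `10^((b_A log10(dose_a) + a_A - a_B) / b_B)`.
#'
#' @param fit_a,fit_b `probit_fit` objects; both slopes must be positive.
#' @param dose_a Dose(s) of drug A, uM (> 0).
#' @return Equivalent dose(s) of drug B, uM.
#' @export
dose_equivalent <- function(fit_a, fit_b, dose_a) {
  stopifnot(inherits(fit_a, "probit_fit"), inherits(fit_b, "probit_fit"))
  refuse_inverted(fit_a, fit_b)
  if (fit_b$slope == 0) stop("degenerate fit: slope of B is zero.", call. = FALSE)
  if (any(dose_a <= 0)) stop("`dose_a` must be positive.", call. = FALSE)
  10^((fit_a$slope * log10(dose_a) + fit_a$intercept - fit_b$intercept) /
        fit_b$slope)
}

# Fixed-ratio ray: component doses (a, b) at total dose T, where the ray
# passes through the additive reference point (f*A50, (1-f)*B50).
ray_components <- function(total, a50, b50, fraction) {
  s <- fraction * a50 + (1 - fraction) * b50
  list(a = total * fraction * a50 / s, b = total * (1 - fraction) * b50 / s)
}

# Signed residual of the two 50%-effect dose-equivalence isoboles at total
# dose T along the ray. which = "b_axis": b + b_eq(a) - B50 (isobole through
# B's axis); which = "a_axis": a + a_eq(b) - A50.
isobole_residual <- function(total, fit_a, fit_b, a50, b50, fraction, which) {
  cmp <- ray_components(total, a50, b50, fraction)
  if (which == "b_axis") {
    cmp$b + dose_equivalent(fit_a, fit_b, cmp$a) - b50
  } else {
    cmp$a + dose_equivalent(fit_b, fit_a, cmp$b) - a50
  }
}

# Bisection on log10(total dose); deterministic and bracket-safe.
bisect_log10 <- function(f, lo, hi, tol = 1e-10, max_iter = 200L) {
  llo <- log10(lo); lhi <- log10(hi)
  flo <- f(10^llo); fhi <- f(10^lhi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop(sprintf(paste0(
      "isobole construction failed: no sign change of the isobole residual ",
      "on total dose [%.4g, %.4g] (f(lo) = %.4g, f(hi) = %.4g)."),
      lo, hi, flo, fhi), call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (llo + lhi) / 2
    fm <- f(10^mid)
    if (fm == 0 || (lhi - llo) / 2 < tol) return(10^mid)
    if (flo * fm < 0) { lhi <- mid } else { llo <- mid; flo <- fm }
  }
  10^((llo + lhi) / 2)
}

solve_nonparallel_bounds <- function(fit_a, fit_b, a50, b50, fraction) {
  lo <- min(a50, b50) * 1e-4
  hi <- a50 + b50
  t1 <- bisect_log10(function(T) {
    isobole_residual(T, fit_a, fit_b, a50, b50, fraction, "b_axis")
  }, lo, hi)
  t2 <- bisect_log10(function(T) {
    isobole_residual(T, fit_a, fit_b, a50, b50, fraction, "a_axis")
  }, lo, hi)
  c(lower = min(t1, t2), upper = max(t1, t2))
}

#' Additive IC50 bounds for non-parallel concentration-response curves
#'
#' When the two log-probit slopes differ, Loewe dose equivalence no longer
#' yields a single straight isobole: converting B into A-equivalents and
#' converting A into B-equivalents trace two different curved isoboles
#' through the 50% effect level. This routine constructs both —
#' (i) `b + b_eq(a) = IC50_B` and (ii) `a + a_eq(b) = IC50_A` — and
#' intersects each with the fixed-ratio ray through the additive reference
#' point by bisection on log10(total dose). The smaller and larger
#' intersection totals are the lower and upper additive IC50 bounds.
#' SEMs are propagated by the delta method (numerical differentiation of
#' each bound with respect to the four line coefficients, using each fit's
#' coefficient covariance).
#'
#' @param fit_a,fit_b `probit_fit` objects for the two single agents (both
#'   slopes positive).
#' @param est_a,est_b Optional `potency_estimate`s; default derived from
#'   the fits via [ic50()].
#' @param fraction Fixed-ratio fraction f in (0, 1); see
#'   [additive_parallel()].
#' @return An `additive_prediction` with `lower < upper` in general;
#'   at equal slopes both bounds collapse onto the parallel value.
#' @export
additive_nonparallel <- function(fit_a, fit_b,
                                 est_a = ic50(fit_a), est_b = ic50(fit_b),
                                 fraction = 0.5) {
  stopifnot(inherits(fit_a, "probit_fit"), inherits(fit_b, "probit_fit"),
            inherits(est_a, "potency_estimate"), inherits(est_b, "potency_estimate"))
  check_fraction(fraction)
  refuse_inverted(fit_a, fit_b)
  bounds <- solve_nonparallel_bounds(fit_a, fit_b, est_a$ic50, est_b$ic50,
                                     fraction)
  sems <- nonparallel_bound_sems(fit_a, fit_b, fraction)
  new_additive_prediction(
    lower = bounds[["lower"]], upper = bounds[["upper"]],
    sem_lower = sems[["lower"]], sem_upper = sems[["upper"]],
    n_add = est_a$n_items + est_b$n_items, parallel_case = FALSE,
    fraction = fraction, est_a = est_a, est_b = est_b,
    fit_a = fit_a, fit_b = fit_b
  )
}

# Delta-method SEMs of the non-parallel bounds: numerical gradient of each
# bound w.r.t. theta = (a_A, b_A, a_B, b_B), block-diagonal covariance from
# the two fits.
nonparallel_bound_sems <- function(fit_a, fit_b, fraction) {
  theta <- c(fit_a$intercept, fit_a$slope, fit_b$intercept, fit_b$slope)
  bounds_of <- function(th) {
    fa <- probit_fit(slope = th[2], intercept = th[1], n_items = fit_a$n_items)
    fb <- probit_fit(slope = th[4], intercept = th[3], n_items = fit_b$n_items)
    a50 <- 10^((5 - th[1]) / th[2])
    b50 <- 10^((5 - th[3]) / th[4])
    solve_nonparallel_bounds(fa, fb, a50, b50, fraction)
  }
  Sigma <- matrix(0, 4, 4)
  Sigma[1:2, 1:2] <- matrix(c(fit_a$se_intercept^2, fit_a$cov_ab,
                              fit_a$cov_ab, fit_a$se_slope^2), 2, 2)
  Sigma[3:4, 3:4] <- matrix(c(fit_b$se_intercept^2, fit_b$cov_ab,
                              fit_b$cov_ab, fit_b$se_slope^2), 2, 2)
  if (all(Sigma == 0)) return(c(lower = 0, upper = 0))
  grad <- matrix(0, nrow = 2, ncol = 4)
  for (j in 1:4) {
    h <- max(1e-6, abs(theta[j]) * 1e-6)
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    grad[, j] <- (bounds_of(up) - bounds_of(dn)) / (2 * h)
  }
  v <- diag(grad %*% Sigma %*% t(grad))
  v[v < 0 & v > -1e-12] <- 0
  if (any(v < 0)) {
    stop("negative propagated variance for additive bounds.", call. = FALSE)
  }
  c(lower = sqrt(v[1]), upper = sqrt(v[2]))
}

#' Additive prediction with automatic parallel/non-parallel branching
#'
#' Runs [test_parallelism()] and dispatches to [additive_parallel()] or
#' [additive_nonparallel()] accordingly.
#'
#' @inheritParams additive_nonparallel
#' @param alpha Significance level for the parallelism test.
#' @return A list with elements `parallelism` (a `parallelism_test`) and
#'   `prediction` (an `additive_prediction`).
#' @export
additive_ic50 <- function(fit_a, fit_b, est_a = ic50(fit_a), est_b = ic50(fit_b),
                          fraction = 0.5, alpha = 0.05) {
  par_test <- test_parallelism(fit_a, fit_b, alpha = alpha)
  pred <- if (par_test$is_parallel) {
    additive_parallel(est_a, est_b, fraction = fraction)
  } else {
    additive_nonparallel(fit_a, fit_b, est_a, est_b, fraction = fraction)
  }
  list(parallelism = par_test, prediction = pred)
}

#' Isobologram coordinates
#'
#' Emits the geometry of a 50%-effect isobologram as a tibble of
#' `(dose_a, dose_b)` points: the additive isobole(s) sampled from axis
#' intercept `(IC50_A, 0)` to `(0, IC50_B)` (the straight line when
#' parallel, the lower/upper dose-equivalence curves when not), the
#' fixed-ratio ray from the origin, and — when an experimental mixture
#' estimate is supplied — the point M, the mixture total-concentration IC50
#' decomposed into component doses along the ray.
#'
#' @param prediction An `additive_prediction` (it carries the single-agent
#'   estimates, the ratio, and — in the non-parallel case — the fits).
#' @param mix Optional `potency_estimate` for the experimental mixture
#'   (total concentration).
#' @param resolution Number of points per curve (>= 2, default 100).
#' @return A tibble with columns `curve_id` (one of `additive_lower`,
#'   `additive_upper`, `fixed_ratio_ray`, `experimental_mix`), `dose_a_um`,
#'   `dose_b_um`.
#' @export
isobologram_coordinates <- function(prediction, mix = NULL, resolution = 100) {
  stopifnot(inherits(prediction, "additive_prediction"), resolution >= 2)
  if (is.null(prediction$est_a) || is.null(prediction$est_b)) {
    stop("this prediction carries no single-agent estimates (it was built ",
         "from published bounds); isobologram geometry needs the axis ",
         "intercepts IC50_A and IC50_B.", call. = FALSE)
  }
  a50 <- prediction$est_a$ic50
  b50 <- prediction$est_b$ic50
  f <- prediction$fraction
  a_grid <- seq(a50, 0, length.out = resolution)
  if (prediction$parallel_case) {
    lower_b <- b50 * (1 - a_grid / a50)
    upper_b <- lower_b
  } else {
    fit_a <- prediction$fit_a; fit_b <- prediction$fit_b
    interior <- a_grid > 0 & a_grid < a50
    # isobole through B's axis: b = B50 - b_eq(a)
    b_i <- pmax(b50 - dose_equivalent(fit_a, fit_b, pmax(a_grid, a50 * 1e-12)), 0)
    b_i[a_grid == a50] <- 0; b_i[a_grid == 0] <- b50
    # isobole through A's axis: a = A50 - a_eq(b), inverted numerically onto
    # the a-grid by solving for b at each a
    b_ii <- vapply(a_grid, function(a) {
      if (a >= a50) return(0)
      if (a <= 0) return(b50)
      resid <- function(b) a + dose_equivalent(fit_b, fit_a, b) - a50
      tryCatch(
        stats::uniroot(resid, lower = b50 * 1e-12, upper = b50,
                       tol = b50 * 1e-10)$root,
        error = function(e) NA_real_
      )
    }, numeric(1))
    iso <- cbind(b_i, b_ii)
    totals_at_mid <- solve_nonparallel_bounds(fit_a, fit_b, a50, b50, f)
    # identify which isobole crosses the ray lower vs upper
    mid <- ray_components(totals_at_mid[["lower"]], a50, b50, f)
    pick_lower <- which.min(abs(iso[which.min(abs(a_grid - mid$a)), ] - mid$b))
    lower_b <- iso[, pick_lower]
    upper_b <- iso[, -pick_lower]
  }
  ray_total <- seq(0, max(a50 + b50, if (is.null(mix)) 0 else mix$ic50),
                   length.out = resolution)
  ray <- ray_components(ray_total, a50, b50, f)
  out <- dplyr::bind_rows(
    tibble::tibble(curve_id = "additive_lower", dose_a_um = a_grid,
                   dose_b_um = lower_b),
    tibble::tibble(curve_id = "additive_upper", dose_a_um = a_grid,
                   dose_b_um = upper_b),
    tibble::tibble(curve_id = "fixed_ratio_ray", dose_a_um = ray$a,
                   dose_b_um = ray$b)
  )
  if (!is.null(mix)) {
    stopifnot(inherits(mix, "potency_estimate"))
    m <- ray_components(mix$ic50, a50, b50, f)
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(curve_id = "experimental_mix", dose_a_um = m$a,
                     dose_b_um = m$b)
    )
  }
  class(out) <- c("isobologram_coords", class(out))
  out
}

#' Plot an isobologram
#'
#' @param object A tibble from [isobologram_coordinates()].
#' @param ... Unused.
#' @return A ggplot object: additive isobole(s), fixed-ratio ray (dotted),
#'   and the experimental mixture point M if present.
#' @method autoplot isobologram_coords
#' @export
autoplot.isobologram_coords <- function(object, ...) {
  curves <- dplyr::filter(object, .data$curve_id %in%
                            c("additive_lower", "additive_upper"))
  ray <- dplyr::filter(object, .data$curve_id == "fixed_ratio_ray")
  mixp <- dplyr::filter(object, .data$curve_id == "experimental_mix")
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$dose_a_um, y = .data$dose_b_um)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$curve_id,
                                    linetype = .data$curve_id)) +
    ggplot2::geom_line(data = ray, linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "Drug A dose (uM)", y = "Drug B dose (uM)",
                  linetype = "additive isobole") +
    ggplot2::theme_minimal()
  if (nrow(mixp) > 0) {
    p <- p + ggplot2::geom_point(data = mixp, shape = 21, size = 3,
                                 fill = "white")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

check_fraction <- function(fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be a single number strictly inside (0, 1).",
         call. = FALSE)
  }
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number strictly inside (0, 1).",
         call. = FALSE)
  }
}

refuse_inverted <- function(...) {
  for (f in list(...)) {
    if (isTRUE(f$inverted)) {
      stop("fit `", f$label %||% "<unnamed>",
           "` has a negative slope (inverted response); isobolographic ",
           "analysis requires increasing concentration-response lines.",
           call. = FALSE)
    }
  }
}
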