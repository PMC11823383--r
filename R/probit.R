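#' Convert viability to fraction affected
#'
#' Normalises a raw viability reading (e.g. MTT absorbance expressed as a
#' percentage) against the mean of untreated control wells and returns the
#' fraction of the population affected, `1 - viability / control`, clamped
#' to `[0, 1]`.
#'
#' @param viability_pct Numeric vector of viability readings, in percent of
#'   control (or any units consistent with `control_mean`).
#' @param control_mean Mean viability of the untreated control wells, in the
#'   same units. Defaults to 100 (readings already expressed as % of control).
#' @return Numeric vector of effect fractions in `[0, 1]`.
#' @examples
#' effect_from_viability(c(100, 25, 0))
#' @export
effect_from_viability <- function(viability_pct, control_mean = 100) {
  if (!is.numeric(viability_pct) || !is.numeric(control_mean)) {
    stop("`viability_pct` and `control_mean` must be numeric.", call. = FALSE)
  }
  if (any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    stop("`control_mean` must be positive and finite.", call. = FALSE)
  }
  if (any(viability_pct < 0, na.rm = TRUE)) {
    stop("`viability_pct` must be non-negative.", call. = FALSE)
  }
  pmin(pmax(1 - viability_pct / control_mean, 0), 1)
}

#' Probit transform
#'
#' Classical probit of an effect fraction: the normal equivalent deviate plus
#' 5, i.e. `qnorm(p) + 5`. On this scale the median effect (p = 0.5) sits at
#' probit 5, so the IC50 of a fitted probit-vs-log10(dose) line is the dose
#' at which the line crosses y = 5.
#'
#' @param p Effect fraction(s), strictly inside (0, 1).
#' @return Probit value(s).
#' @seealso [inv_probit()]
#' @examples
#' probit(0.5)      # 5
#' probit(0.841345) # ~6
#' @export
probit <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric.", call. = FALSE)
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    stop("`p` must lie strictly inside (0, 1); filter or clamp saturated effects first.",
         call. = FALSE)
  }
  stats::qnorm(p) + 5
}

#' @rdname probit
#' @param y Probit value(s).
#' @export
inv_probit <- function(y) {
  if (!is.numeric(y)) stop("`y` must be numeric.", call. = FALSE)
  stats::pnorm(y - 5)
}

#' Construct a probit line fit from published coefficients
#'
#' Builds the fitted-line object that [fit_probit_line()] returns, directly
#' from summary statistics. This is the entry point for re-analysing
#' published log-probit equations (`y = b x + a` with x = log10 dose in uM,
#' y = probit of effect) when raw plates are unavailable.
#'
#' @param slope Slope `b`, probit units per log10(uM).
#' @param intercept Intercept `a`, probit units.
#' @param se_slope,se_intercept Standard errors of the coefficients
#'   (default 0, i.e. treated as exact).
#' @param cov_ab Covariance of intercept and slope estimates (default 0).
#' @param n_items Number of wells (items) behind the fit.
#' @param n_doses Number of distinct dose levels (default `NA`).
#' @param r_squared Coefficient of determination (default `NA`).
#' @param label Treatment label.
#' @return An object of class `probit_fit`.
#' @examples
#' probit_fit(slope = 4.3531, intercept = -3.4047, n_items = 48, label = "EX527")
#' @export
probit_fit <- function(slope, intercept, se_slope = 0, se_intercept = 0,
                       cov_ab = 0, n_items = NA_integer_, n_doses = NA_integer_,
                       r_squared = NA_real_, label = NULL) {
  stopifnot(is.numeric(slope), length(slope) == 1L,
            is.numeric(intercept), length(intercept) == 1L)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("`r_squared` must lie in [0, 1].", call. = FALSE)
  }
  if (se_slope < 0 || se_intercept < 0) {
    stop("standard errors must be non-negative.", call. = FALSE)
  }
  structure(
    list(
      slope = as.numeric(slope),
      intercept = as.numeric(intercept),
      r_squared = as.numeric(r_squared),
      se_slope = as.numeric(se_slope),
      se_intercept = as.numeric(se_intercept),
      cov_ab = as.numeric(cov_ab),
      n_items = as.integer(n_items),
      n_doses = as.integer(n_doses),
      label = label %||% NA_character_,
      inverted = is.finite(slope) && slope < 0
    ),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  lbl <- if (is.na(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf("Log-probit line fit%s\n", lbl))
  cat(sprintf("  y = %.4f x %+.4f   (x = log10 dose [uM], y = probit effect)\n",
              x$slope, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  cat(sprintf("  se(slope) = %.4g, se(intercept) = %.4g, n = %s wells\n",
              x$se_slope, x$se_intercept, x$n_items))
  if (isTRUE(x$inverted)) cat("  WARNING: negative slope (inverted response)\n")
  invisible(x)
}

prepare_probit_points <- function(data, aggregation = c("per_well", "per_dose_mean"),
                                  saturation = c("drop", "clamp")) {
  aggregation <- match.arg(aggregation)
  saturation <- match.arg(saturation)
  stopifnot(is.data.frame(data))
  if (!all(c("dose_um", "effect") %in% names(data))) {
    stop("`data` must contain columns `dose_um` and `effect`.", call. = FALSE)
  }
  pts <- dplyr::filter(data, .data$dose_um > 0)
  if (any(pts$effect < 0 | pts$effect > 1, na.rm = TRUE)) {
    stop("`effect` must lie in [0, 1].", call. = FALSE)
  }
  # aggregation happens before the saturation policy, so a dose whose mean
  # lies inside (0, 1) is retained even if individual wells saturate
  pts <- pts |>
    dplyr::group_by(.data$dose_um) |>
    (\(g) if (aggregation == "per_dose_mean") {
      dplyr::summarise(g, effect = mean(.data$effect), m = dplyr::n(),
                       .groups = "drop")
    } else {
      dplyr::ungroup(dplyr::mutate(g, m = dplyr::n()))
    })()
  if (saturation == "clamp") {
    # clamp saturated effects to (1/(2m), 1 - 1/(2m)), m = wells at that dose
    pts$effect <- pmin(pmax(pts$effect, 1 / (2 * pts$m)), 1 - 1 / (2 * pts$m))
  } else {
    pts <- dplyr::filter(pts, .data$effect > 0, .data$effect < 1)
  }
  pts
}

#' Fit a log-probit concentration-response line
#'
#' Ordinary least-squares fit of `probit(effect)` on `log10(dose)` for one
#' treatment arm, the linear form behind printed log-probit equations
#' `y = b x + a`. Control wells (`dose_um == 0`) never enter the fit;
#' saturated wells (effect exactly 0 or 1) are excluded by default or
#' clamped to `(1/(2m), 1 - 1/(2m))` (m = wells at that dose) when
#' `saturation = "clamp"`.
#'
#' @param data A data frame with columns `dose_um` (uM; for a mixture the
#'   total combined concentration) and `effect` (fraction affected in
#'   `[0, 1]`), one row per well — e.g. the output of [read_plate_csv()] or
#'   [simulate_drug()]. A `treatment` column, if present, must hold a single
#'   value.
#' @param aggregation `"per_well"` (default) fits one point per well so that
#'   `n_items` equals the well count; `"per_dose_mean"` first averages the
#'   effect at each dose.
#' @param saturation Policy for effects exactly 0 or 1: `"drop"` (default)
#'   or `"clamp"`.
#' @return A `probit_fit` object (see [probit_fit()]) carrying slope,
#'   intercept, their standard errors and covariance, R^2, and well counts.
#' @examples
#' plate <- simulate_drug(drug_truth("EX527", ic50 = 50, slope = 2.3), seed = 1)
#' fit_probit_line(plate)
#' @export
fit_probit_line <- function(data, aggregation = c("per_well", "per_dose_mean"),
                            saturation = c("drop", "clamp")) {
  aggregation <- match.arg(aggregation)
  label <- NULL
  if ("treatment" %in% names(data)) {
    trts <- unique(data$treatment)
    if (length(trts) > 1L) {
      stop("`data` holds ", length(trts),
           " treatments; fit one arm at a time (e.g. split with dplyr::group_split()).",
           call. = FALSE)
    }
    label <- as.character(trts)
  }
  pts <- prepare_probit_points(data, aggregation, saturation)
  n_doses <- dplyr::n_distinct(pts$dose_um)
  if (nrow(pts) == 0L || all(pts$effect <= 0 | pts$effect >= 1)) {
    stop("unfittable dataset: no wells with effect strictly inside (0, 1).",
         call. = FALSE)
  }
  if (n_doses < 2L) {
    stop("unfittable dataset: need >= 2 distinct dose levels with usable effects.",
         call. = FALSE)
  }
  x <- log10(pts$dose_um)
  y <- probit(pts$effect)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  vc <- stats::vcov(fit)
  out <- probit_fit(
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    se_slope = sm$coefficients["x", "Std. Error"],
    se_intercept = sm$coefficients["(Intercept)", "Std. Error"],
    cov_ab = vc["(Intercept)", "x"],
    n_items = nrow(pts),
    n_doses = n_doses,
    r_squared = sm$r.squared,
    label = label
  )
  if (out$inverted) {
    warning("fitted slope is negative (inverted concentration-response); ",
            "downstream isobolography will refuse this fit.", call. = FALSE)
  }
  out
}

#' IC50 and its standard error from a probit line fit
#'
#' The median inhibitory concentration solves `b * log10(IC50) + a = 5`,
#' i.e. `IC50 = 10^((5 - a) / b)`. Its standard error is propagated from the
#' coefficient covariance by the delta method:
#' `var(log10 IC50) = (var(a) + 2 g cov(a,b) + g^2 var(b)) / b^2` with
#' `g = (5 - a) / b`, and `SEM(IC50) = ln(10) * IC50 * sd(log10 IC50)`.
#'
#' @param fit A `probit_fit`.
#' @param label Optional label override for the estimate.
#' @return A `potency_estimate` with fields `ic50` (uM), `sem` (uM),
#'   `n_items` and `label`.
#' @examples
#' ic50(probit_fit(slope = 4.3531, intercept = -3.4047, n_items = 48))
#' @export
ic50 <- function(fit, label = NULL) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!is.finite(fit$slope) || fit$slope == 0) {
    stop("degenerate fit: slope is zero; IC50 undefined.", call. = FALSE)
  }
  if (isTRUE(fit$inverted)) {
    warning("IC50 derived from an inverted (negative-slope) fit.", call. = FALSE)
  }
  est <- 10^((5 - fit$intercept) / fit$slope)
  potency_estimate(
    ic50 = est,
    sem = ic50_sem(fit),
    n_items = fit$n_items,
    label = label %||% fit$label
  )
}

#' @rdname ic50
#' @export
ic50_sem <- function(fit) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!is.finite(fit$slope) || fit$slope == 0) {
    stop("degenerate fit: slope is zero.", call. = FALSE)
  }
  g <- (5 - fit$intercept) / fit$slope
  v <- (fit$se_intercept^2 + 2 * g * fit$cov_ab + g^2 * fit$se_slope^2) /
    fit$slope^2
  if (v < 0) {
    stop(sprintf(paste0(
      "negative delta-method variance (%.4g) for log10 IC50; the coefficient ",
      "covariance (se_a = %.4g, se_b = %.4g, cov_ab = %.4g) is not positive ",
      "semi-definite at this fit."), v, fit$se_intercept, fit$se_slope,
      fit$cov_ab), call. = FALSE)
  }
  log(10) * 10^g * sqrt(v)
}

#' Construct a potency estimate
#'
#' Container for an IC50 (single agent or fixed-ratio mixture total
#' concentration) with its standard error and the number of wells behind it.
#'
#' @param ic50 Median inhibitory concentration, uM (> 0).
#' @param sem Standard error of the IC50, uM (>= 0).
#' @param n_items Number of wells (items).
#' @param label Treatment label.
#' @return An object of class `potency_estimate`.
#' @export
potency_estimate <- function(ic50, sem = 0, n_items = NA_integer_, label = NULL) {
  stopifnot(is.numeric(ic50), length(ic50) == 1L, is.numeric(sem))
  if (!is.finite(ic50) || ic50 <= 0) stop("`ic50` must be positive.", call. = FALSE)
  if (sem < 0) stop("`sem` must be non-negative.", call. = FALSE)
  structure(
    list(ic50 = as.numeric(ic50), sem = as.numeric(sem),
         n_items = as.integer(n_items), label = label %||% NA_character_),
    class = "potency_estimate"
  )
}

#' @export
print.potency_estimate <- function(x, ...) {
  lbl <- if (is.na(x$label)) "" else paste0(x$label, ": ")
  cat(sprintf("%sIC50 = %.4g +/- %.4g uM (n = %s)\n", lbl, x$ic50, x$sem,
              x$n_items))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a probit line fit
#'
#' @param x A `probit_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`intercept`, `slope`):
#'   `term`, `estimate`, `std.error`.
#' @method tidy probit_fit
#' @export
tidy.probit_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' Glance at a probit line fit
#'
#' @param x A `probit_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `treatment`, `slope`, `intercept`, `r_squared`,
#'   `se_slope`, `se_intercept`, `cov_ab`, `n_items`, `n_doses`, `ic50_um`,
#'   `sem_um` — the fit-summary schema used for CSV/JSON export.
#' @method glance probit_fit
#' @export
glance.probit_fit <- function(x, ...) {
  est <- tryCatch(suppressWarnings(ic50(x)), error = function(e) NULL)
  tibble::tibble(
    treatment = x$label,
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    se_slope = x$se_slope,
    se_intercept = x$se_intercept,
    cov_ab = x$cov_ab,
    n_items = x$n_items,
    n_doses = x$n_doses,
    ic50_um = if (is.null(est)) NA_real_ else est$ic50,
    sem_um = if (is.null(est)) NA_real_ else est$sem
  )
}

#' @method tidy potency_estimate
#' @export
tidy.potency_estimate <- function(x, ...) {
  tibble::tibble(label = x$label, ic50_um = x$ic50, sem_um = x$sem,
                 n_items = x$n_items)
}
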