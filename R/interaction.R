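#' Two-sided tail probability of the t distribution
#'
#' `2 * P(T > |t|)` for a t-distributed statistic with (possibly
#' fractional) degrees of freedom.
#'
#' @param t Test statistic(s).
#' @param df Degrees of freedom (> 0), fractional values allowed
#'   (Welch-Satterthwaite).
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
p_two_sided <- function(t, df) {
  if (any(!is.finite(df) & !is.infinite(df)) || any(df <= 0)) {
    stop("`df` must be positive.", call. = FALSE)
  }
  2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
}

#' Welch comparison of an experimental mixture IC50 with a reference IC50
#'
#' Unpaired Student's t-test with Welch's correction on two IC50 estimates
#' summarised as (estimate, SEM, n):
#' `t = |IC50_mix - IC50_ref| / sqrt(sem_mix^2 + sem_ref^2)` with
#' Satterthwaite degrees of freedom
#' `df = (sem_mix^2 + sem_ref^2)^2 / (sem_mix^4/(n_mix-1) + sem_ref^4/(n_ref-1))`.
#'
#' @param mix A `potency_estimate` for the experimental mixture.
#' @param reference_ic50,reference_sem,reference_n Reference IC50 (uM), its
#'   SEM (uM) and item count — typically an additive prediction (or one of
#'   its bounds).
#' @param reference_bound Which bound the reference is
#'   (`"single"`, `"lower"`, `"upper"`); recorded in the result.
#' @return An object of class `welch_comparison` with `t_stat` (>= 0),
#'   `df`, `p_value`, `difference` (mix - reference, signed, uM),
#'   `reference_bound` and a `degenerate` flag (both SEMs zero with unequal
#'   means).
#' @examples
#' mix <- potency_estimate(29.52, sem = 3.29, n_items = 120, label = "mix")
#' welch_compare(mix, reference_ic50 = 25.38, reference_sem = 5.67,
#'               reference_n = 188)
#' @export
welch_compare <- function(mix, reference_ic50, reference_sem, reference_n,
                          reference_bound = c("single", "lower", "upper")) {
  stopifnot(inherits(mix, "potency_estimate"))
  reference_bound <- match.arg(reference_bound)
  if (reference_sem < 0 || mix$sem < 0) {
    stop("SEMs must be non-negative.", call. = FALSE)
  }
  if (is.na(mix$n_items) || mix$n_items < 2L || reference_n < 2L) {
    stop("both item counts must be >= 2.", call. = FALSE)
  }
  diff <- mix$ic50 - reference_ic50
  v <- mix$sem^2 + reference_sem^2
  degenerate <- FALSE
  # variances at floating-point noise level are zero in substance: compare
  # the means at the same numerical tolerance instead of forming t = 0/0
  num_tol <- .Machine$double.eps^0.5 * max(abs(mix$ic50), abs(reference_ic50), 1)
  if (sqrt(v) < num_tol && abs(diff) < num_tol) {
    diff <- 0
    v <- 0
  }
  if (v == 0) {
    if (diff == 0) {
      t_stat <- 0; df <- mix$n_items + reference_n - 2; p <- 1
    } else {
      t_stat <- Inf; df <- mix$n_items + reference_n - 2; p <- 0
      degenerate <- TRUE
    }
  } else {
    t_stat <- abs(diff) / sqrt(v)
    num <- v^2
    den <- mix$sem^4 / (mix$n_items - 1) + reference_sem^4 / (reference_n - 1)
    df <- if (den == 0) mix$n_items + reference_n - 2 else num / den
    p <- p_two_sided(t_stat, df)
  }
  structure(
    list(t_stat = t_stat, df = df, p_value = p, difference = diff,
         reference_bound = reference_bound, reference_ic50 = reference_ic50,
         degenerate = degenerate),
    class = "welch_comparison"
  )
}

#' @export
print.welch_comparison <- function(x, ...) {
  cat("Welch comparison of IC50 estimates\n")
  cat(sprintf("  reference: %s additive value (%.4g uM); difference = %+.4g uM\n",
              x$reference_bound, x$reference_ic50, x$difference))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.3f\n", x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' @method tidy welch_comparison
#' @export
tidy.welch_comparison <- function(x, ...) {
  tibble::tibble(t = x$t_stat, df = x$df, p = x$p_value,
                 difference = x$difference, reference_bound = x$reference_bound)
}

#' Select the additive reference bound for an interaction test
#'
#' For a parallel-curve prediction the reference is the single additive
#' value. For a non-parallel prediction the mixture is tested against the
#' bound nearer to its own IC50 (ties resolved to the lower bound) — the
#' conservative choice, since the nearer bound gives the smaller test
#' statistic.
#'
#' @param mix A `potency_estimate` for the experimental mixture.
#' @param prediction An `additive_prediction`.
#' @return A list: `bound` (`"single"`, `"lower"` or `"upper"`), `ic50`,
#'   `sem`, `n`.
#' @export
choose_reference <- function(mix, prediction) {
  stopifnot(inherits(mix, "potency_estimate"),
            inherits(prediction, "additive_prediction"))
  if (prediction$parallel_case) {
    return(list(bound = "single", ic50 = prediction$lower,
                sem = prediction$sem_lower, n = prediction$n_add))
  }
  d_lower <- abs(mix$ic50 - prediction$lower)
  d_upper <- abs(mix$ic50 - prediction$upper)
  if (d_lower <= d_upper) {
    list(bound = "lower", ic50 = prediction$lower, sem = prediction$sem_lower,
         n = prediction$n_add)
  } else {
    list(bound = "upper", ic50 = prediction$upper, sem = prediction$sem_upper,
         n = prediction$n_add)
  }
}

#' Classify a drug-drug interaction
#'
#' Compares the experimental mixture IC50 with the theoretical additive
#' IC50 ([choose_reference()] then [welch_compare()]) and classifies:
#' no significant difference (`p > alpha`) is additivity; a significantly
#' smaller mixture IC50 (for non-parallel curves, below the lower bound) is
#' synergy; a significantly larger one (above the upper bound) is
#' antagonism.
#'
#' @param mix A `potency_estimate` for the experimental mixture (total
#'   concentration).
#' @param prediction An `additive_prediction`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `interaction_call` with `classification`
#'   (`"synergistic"`, `"additive"` or `"antagonistic"`), `alpha` and the
#'   underlying `welch_comparison`.
#' @export
classify_interaction <- function(mix, prediction, alpha = 0.05) {
  check_alpha(alpha)
  ref <- choose_reference(mix, prediction)
  cmp <- welch_compare(mix, reference_ic50 = ref$ic50, reference_sem = ref$sem,
                       reference_n = ref$n, reference_bound = ref$bound)
  classification <- if (cmp$p_value > alpha) {
    "additive"
  } else if (cmp$difference < 0) {
    "synergistic"
  } else {
    "antagonistic"
  }
  structure(
    list(classification = classification, alpha = alpha, comparison = cmp,
         mix = mix, prediction = prediction),
    class = "interaction_call"
  )
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("Interaction: %s (alpha = %g)\n", toupper(x$classification),
              x$alpha))
  print(x$comparison)
  invisible(x)
}

#' @method tidy interaction_call
#' @export
tidy.interaction_call <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(classification = x$classification, alpha = x$alpha),
    tidy(x$comparison)
  )
}

#' Table-style interaction report
#'
#' Assembles one report row per analysed combination in the layout of a
#' published isobolography table: experimental mixture IC50 (+/- SEM, n),
#' lower/upper additive IC50 (+/- SEM, n_add), Welch t, df, p, and the
#' interaction call.
#'
#' @param calls A named list of `interaction_call` objects (names become the
#'   `cell_line` column), or a single `interaction_call`.
#' @return A tibble with columns `cell_line, ic50_mix, sem_mix, n_mix,
#'   l_ic50_add, sem_l, u_ic50_add, sem_u, n_add, t, df, p, interaction`.
#' @export
interaction_report <- function(calls) {
  if (inherits(calls, "interaction_call")) calls <- list(calls)
  purrr::imap_dfr(calls, function(call, name) {
    stopifnot(inherits(call, "interaction_call"))
    pred <- call$prediction
    tibble::tibble(
      cell_line = if (is.character(name) && nzchar(name)) name else
        call$mix$label,
      ic50_mix = call$mix$ic50, sem_mix = call$mix$sem,
      n_mix = call$mix$n_items,
      l_ic50_add = pred$lower, sem_l = pred$sem_lower,
      u_ic50_add = if (pred$parallel_case) NA_real_ else pred$upper,
      sem_u = if (pred$parallel_case) NA_real_ else pred$sem_upper,
      n_add = pred$n_add,
      t = call$comparison$t_stat, df = call$comparison$df,
      p = call$comparison$p_value,
      interaction = call$classification
    )
  })
}
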