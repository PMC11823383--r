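PLATE_KEY_COLS <- c("treatment", "dose_um", "replicate")

#' Read a long-format viability plate CSV
#'
#' Expected columns: `treatment`, `dose_um`, `replicate`, and exactly one
#' of `viability_pct` (raw viability, % scale) or `effect` (fraction
#' affected in `[0, 1]`). Rows with `dose_um == 0` are untreated controls:
#' they are averaged per treatment into a control mean used to normalise
#' `viability_pct` (treatments without control rows are assumed already
#' normalised to a 100% control) and are then removed from the returned
#' table.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `treatment`, `dose_um`, `replicate`,
#'   `effect` and `control_mean` (the per-treatment normaliser, recorded
#'   for provenance), one row per treated well, sorted by treatment, dose,
#'   replicate.
#' @export
read_plate_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(PLATE_KEY_COLS, names(raw))
  if (length(missing) > 0) {
    stop("plate schema error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "), " in ", path, call. = FALSE)
  }
  has_v <- "viability_pct" %in% names(raw)
  has_e <- "effect" %in% names(raw)
  if (has_v && has_e) {
    stop("plate schema error: `viability_pct` and `effect` are mutually ",
         "exclusive; provide exactly one.", call. = FALSE)
  }
  if (!has_v && !has_e) {
    stop("plate schema error: need a `viability_pct` or `effect` column.",
         call. = FALSE)
  }
  if (!is.numeric(raw$dose_um)) {
    stop("plate schema error: `dose_um` must be numeric.", call. = FALSE)
  }
  bad <- which(!is.finite(raw$dose_um) | raw$dose_um < 0)
  if (length(bad) > 0) {
    stop("plate row error: negative or non-finite `dose_um` at file line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  if (has_e && any(raw$effect < 0 | raw$effect > 1, na.rm = TRUE)) {
    bad <- which(raw$effect < 0 | raw$effect > 1)
    stop("plate row error: `effect` outside [0, 1] at file line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  if (has_v) {
    controls <- raw |>
      dplyr::filter(.data$dose_um == 0) |>
      dplyr::group_by(.data$treatment) |>
      dplyr::summarise(control_mean = mean(.data$viability_pct),
                       .groups = "drop")
    out <- raw |>
      dplyr::filter(.data$dose_um > 0) |>
      dplyr::left_join(controls, by = "treatment") |>
      dplyr::mutate(
        control_mean = dplyr::coalesce(.data$control_mean, 100),
        effect = effect_from_viability(.data$viability_pct,
                                       .data$control_mean)
      ) |>
      dplyr::select(dplyr::all_of(c(PLATE_KEY_COLS, "effect", "control_mean")))
  } else {
    out <- raw |>
      dplyr::filter(.data$dose_um > 0) |>
      dplyr::mutate(control_mean = NA_real_) |>
      dplyr::select(dplyr::all_of(c(PLATE_KEY_COLS, "effect", "control_mean")))
  }
  dplyr::arrange(out, .data$treatment, .data$dose_um, .data$replicate)
}

#' Write a plate table to CSV (with optional ground-truth sidecar)
#'
#' Writes the long plate format consumed by [read_plate_csv()]
#' (`treatment,dose_um,replicate,viability_pct` or `...,effect`). If
#' `truth` is supplied (any list, e.g. simulator parameters) it is written
#' alongside as `<path>.truth.json`.
#'
#' @param data A plate tibble (e.g. from [simulate_drug()]).
#' @param path Output CSV path.
#' @param truth Optional list of ground-truth parameters.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(data, path, truth = NULL) {
  stopifnot(is.data.frame(data))
  value_col <- if ("viability_pct" %in% names(data)) "viability_pct" else "effect"
  readr::write_csv(data[, c(PLATE_KEY_COLS, value_col)], path)
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read published fit summaries
#'
#' Reads a CSV of already-fitted log-probit line summaries — the
#' re-analysis entry point when raw plates are unavailable. Required
#' columns: `treatment`, `slope`, `intercept`; optional: `r_squared`,
#' `se_slope`, `se_intercept`, `cov_ab`, `n_items`.
#'
#' @param path Path to the CSV file.
#' @return A named list of [probit_fit()] objects keyed by treatment.
#' @export
read_fit_summaries <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("treatment", "slope", "intercept")
  missing <- setdiff(needed, names(tb))
  if (length(missing) > 0) {
    stop("fit-summary schema error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  opt <- function(col, default) if (col %in% names(tb)) tb[[col]] else
    rep(default, nrow(tb))
  fits <- purrr::pmap(
    list(tb$treatment, tb$slope, tb$intercept, opt("se_slope", 0),
         opt("se_intercept", 0), opt("cov_ab", 0),
         opt("n_items", NA_integer_), opt("r_squared", NA_real_)),
    function(trt, b, a, seb, sea, cab, n, r2) {
      probit_fit(slope = b, intercept = a, se_slope = seb, se_intercept = sea,
                 cov_ab = cab, n_items = n, r_squared = r2, label = trt)
    }
  )
  stats::setNames(fits, tb$treatment)
}

#' Run the end-to-end fixed-ratio interaction analysis
#'
#' Fits log-probit lines to the two single-drug arms and the fixed-ratio
#' mixture arm of a plate table, tests parallelism, computes the additive
#' IC50 (single value or lower/upper bounds), compares the experimental
#' mixture IC50 against the additive reference with the Welch t-test, and
#' classifies the interaction.
#'
#' @param plates A plate tibble (wells of all three arms; e.g.
#'   `dplyr::bind_rows()` of [simulate_drug()] /
#'   [simulate_fixed_ratio_mixture()] outputs, or [read_plate_csv()]).
#' @param drug_a,drug_b,mixture Treatment labels of the two single agents
#'   and the mixture arm.
#' @param fraction Fixed-ratio fraction f (default 0.5).
#' @param alpha Significance level for both the parallelism test and the
#'   interaction call (default 0.05).
#' @param aggregation,saturation Passed to [fit_probit_line()].
#' @param isobole_resolution Points per isobole curve (default 100).
#' @return An object of class `run_report`: a list with `fits` (named list
#'   of `probit_fit`), `fit_summaries` (tibble), `estimates` (named list of
#'   `potency_estimate`), `parallelism`, `prediction`, `call`, `report`
#'   (one Table-style row) and `isobologram` (coordinate tibble), plus the
#'   `config` used.
#' @export
run_interaction_analysis <- function(plates, drug_a, drug_b, mixture,
                                     fraction = 0.5, alpha = 0.05,
                                     aggregation = "per_well",
                                     saturation = "drop",
                                     isobole_resolution = 100) {
  stopifnot(is.data.frame(plates), "treatment" %in% names(plates))
  arms <- c(a = drug_a, b = drug_b, mix = mixture)
  absent <- arms[!arms %in% plates$treatment]
  if (length(absent) > 0) {
    stop("treatment arm(s) not present in `plates`: ",
         paste(sQuote(absent), collapse = ", "), call. = FALSE)
  }
  fit_arm <- function(lbl) {
    tryCatch(
      fit_probit_line(dplyr::filter(plates, .data$treatment == lbl),
                      aggregation = aggregation, saturation = saturation),
      error = function(e) {
        stop("stage fit[", lbl, "]: ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  fits <- lapply(arms, fit_arm)
  est_a <- ic50(fits$a)
  est_b <- ic50(fits$b)
  est_mix <- ic50(fits$mix)
  branch <- additive_ic50(fits$a, fits$b, est_a, est_b, fraction = fraction,
                          alpha = alpha)
  call <- classify_interaction(est_mix, branch$prediction, alpha = alpha)
  coords <- isobologram_coordinates(branch$prediction, mix = est_mix,
                                    resolution = isobole_resolution)
  structure(
    list(
      fits = fits,
      fit_summaries = purrr::map_dfr(fits, glance),
      estimates = list(a = est_a, b = est_b, mix = est_mix),
      parallelism = branch$parallelism,
      prediction = branch$prediction,
      call = call,
      report = interaction_report(stats::setNames(list(call), mixture)),
      isobologram = coords,
      config = list(drug_a = drug_a, drug_b = drug_b, mixture = mixture,
                    fraction = fraction, alpha = alpha,
                    aggregation = aggregation, saturation = saturation,
                    isobole_resolution = isobole_resolution)
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("Fixed-ratio isobolographic interaction analysis\n")
  cat(sprintf("  arms: A = %s, B = %s, mixture = %s (f = %g)\n",
              x$config$drug_a, x$config$drug_b, x$config$mixture,
              x$config$fraction))
  print(x$parallelism)
  print(x$prediction)
  print(x$call)
  invisible(x)
}

#' @method tidy run_report
#' @export
tidy.run_report <- function(x, ...) x$report
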