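#' Ground-truth description of a single-drug viability series
#'
#' Encodes the probit-linear truth the simulator draws from: a drug with a
#' true IC50 and probit slope, assayed at a dose grid with replicate wells
#' and Gaussian plate-reader noise on viability. The default grid is six
#' two-fold dilutions spanning 0.25x-8x the true IC50, loosely emulating a
#' 96-well MTT screen.
#'
#' @param label Treatment label.
#' @param ic50 True IC50, uM (> 0).
#' @param slope True probit slope, probit units per log10(uM) (> 0).
#' @param doses Dose grid in uM; default `ic50 * 2^(-2:3)`.
#' @param replicates Wells per dose (default 8).
#' @param noise_sd Gaussian noise SD on viability, in % units (default 2).
#' @return An object of class `drug_truth`.
#' @export
drug_truth <- function(label, ic50, slope, doses = ic50 * 2^(-2:3),
                       replicates = 8, noise_sd = 2) {
  stopifnot(is.numeric(ic50), ic50 > 0, is.numeric(slope), slope > 0,
            all(doses > 0), replicates >= 1, noise_sd >= 0)
  structure(
    list(label = as.character(label), ic50 = ic50, slope = slope,
         doses = sort(as.numeric(doses)), replicates = as.integer(replicates),
         noise_sd = noise_sd),
    class = "drug_truth"
  )
}

#' Ground-truth description of a fixed-ratio mixture series
#'
#' The mixture truth is a Loewe interaction index: at every generated dose
#' the effect E solves `a / A(E) + b / B(E) = lambda`, where `A(E)` and
#' `B(E)` invert each single drug's probit line at effect E. `lambda = 1`
#' is exact Loewe additivity, `lambda < 1` synergy, `lambda > 1`
#' antagonism.
#'
#' @param lambda Loewe interaction index (> 0, default 1).
#' @param fraction Fixed-ratio fraction f in (0, 1) (default 0.5, the 1:1
#'   ratio).
#' @param dilution_steps Multiples of the additive reference total dose
#'   `f * IC50_A + (1 - f) * IC50_B` at which mixture wells are laid out
#'   (default `2^(-2:3)`).
#' @param replicates Wells per dose (default 8).
#' @param noise_sd Gaussian viability noise SD in % units (default 2).
#' @return An object of class `mixture_truth`.
#' @export
mixture_truth <- function(lambda = 1, fraction = 0.5,
                          dilution_steps = 2^(-2:3), replicates = 8,
                          noise_sd = 2) {
  stopifnot(is.numeric(lambda), lambda > 0, all(dilution_steps > 0),
            replicates >= 1, noise_sd >= 0)
  check_fraction(fraction)
  structure(
    list(lambda = lambda, fraction = fraction,
         dilution_steps = sort(as.numeric(dilution_steps)),
         replicates = as.integer(replicates), noise_sd = noise_sd),
    class = "mixture_truth"
  )
}

# Deterministic 32-bit stream seed from (seed, stream label): identical
# pairs give identical streams, distinct labels decorrelated streams.
stream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

noisy_viability <- function(mean_viability, noise_sd) {
  v <- mean_viability + stats::rnorm(length(mean_viability), sd = noise_sd)
  pmin(pmax(v, 0), 100)
}

plate_tibble <- function(label, doses, replicates, mean_viability, noise_sd) {
  n <- length(doses) * replicates
  tb <- tibble::tibble(
    treatment = label,
    dose_um = rep(doses, each = replicates),
    replicate = rep(seq_len(replicates), times = length(doses)),
    viability_pct = noisy_viability(rep(mean_viability, each = replicates),
                                    noise_sd)
  )
  tb$effect <- effect_from_viability(tb$viability_pct, control_mean = 100)
  tb
}

#' Simulate a single-drug viability plate
#'
#' Draws one long-format plate for a probit-linear drug: the mean viability
#' at dose d is `100 * (1 - pnorm(slope * (log10 d - log10 IC50)))`, to
#' which Gaussian noise of SD `noise_sd` is added and the result truncated
#' to `[0, 100]`. Effects are derived against a noiseless 100% control.
#'
#' @param truth A [drug_truth()].
#' @param seed Integer seed.
#' @param stream Stream label; identical `(seed, stream)` pairs reproduce
#'   the dataset exactly (defaults to the drug label).
#' @return A tibble with columns `treatment`, `dose_um`, `replicate`,
#'   `viability_pct`, `effect`, sorted by dose then replicate.
#' @examples
#' simulate_drug(drug_truth("EX527", ic50 = 50, slope = 2.3), seed = 1)
#' @export
simulate_drug <- function(truth, seed, stream = truth$label) {
  stopifnot(inherits(truth, "drug_truth"))
  mean_v <- 100 * (1 - stats::pnorm(truth$slope *
                                      (log10(truth$doses) - log10(truth$ic50))))
  with_stream_seed(seed, stream, {
    plate_tibble(truth$label, truth$doses, truth$replicates, mean_v,
                 truth$noise_sd)
  })
}

# Invert the Loewe equation a/A(E) + b/B(E) = lambda for the effect E at
# component doses (a, b); probit lines give A(E) = 10^((qnorm(E)+5-a0)/b0).
loewe_effect <- function(a, b, truth_a, truth_b, lambda) {
  int_a <- 5 - truth_a$slope * log10(truth_a$ic50)
  int_b <- 5 - truth_b$slope * log10(truth_b$ic50)
  g <- function(z) {
    a / 10^((z + 5 - int_a) / truth_a$slope) +
      b / 10^((z + 5 - int_b) / truth_b$slope) - lambda
  }
  lo <- -12; hi <- 12
  if (g(lo) < 0 || g(hi) > 0) return(NA_real_)
  stats::pnorm(stats::uniroot(g, c(lo, hi), tol = 1e-12)$root)
}

#' Simulate a fixed-ratio mixture viability plate
#'
#' Lays mixture wells along the fixed-ratio ray: at total dose T the
#' component doses are `(a, b) = T * (f A50, (1-f) B50) / (f A50 + (1-f) B50)`,
#' and the noise-free effect solves the Loewe equation
#' `a / A(E) + b / B(E) = lambda` by monotone root-finding through the two
#' single-drug probit truths. Viability noise is added exactly as in
#' [simulate_drug()]. Doses at which no effect in (0, 1) solves the
#' equation are skipped with a warning.
#'
#' @param truth_a,truth_b [drug_truth()] objects for the two components.
#' @param mix A [mixture_truth()].
#' @param seed Integer seed.
#' @param stream Stream label (default `"<A>:<B>"`).
#' @param label Treatment label for the mixture arm (defaults to the stream
#'   label).
#' @return A tibble in the same long plate format as [simulate_drug()],
#'   with `dose_um` holding the total combined concentration.
#' @export
simulate_fixed_ratio_mixture <- function(truth_a, truth_b, mix = mixture_truth(),
                                         seed,
                                         stream = paste0(truth_a$label, ":",
                                                         truth_b$label),
                                         label = stream) {
  stopifnot(inherits(truth_a, "drug_truth"), inherits(truth_b, "drug_truth"),
            inherits(mix, "mixture_truth"))
  f <- mix$fraction
  ref_total <- f * truth_a$ic50 + (1 - f) * truth_b$ic50
  totals <- mix$dilution_steps * ref_total
  effects <- vapply(totals, function(T) {
    cmp <- ray_components(T, truth_a$ic50, truth_b$ic50, f)
    loewe_effect(cmp$a, cmp$b, truth_a, truth_b, mix$lambda)
  }, numeric(1))
  if (anyNA(effects)) {
    warning(sum(is.na(effects)),
            " mixture dose(s) had no Loewe-consistent effect in (0, 1) and ",
            "were skipped.", call. = FALSE)
    totals <- totals[!is.na(effects)]
    effects <- effects[!is.na(effects)]
  }
  mean_v <- 100 * (1 - effects)
  with_stream_seed(seed, stream, {
    plate_tibble(label, totals, mix$replicates, mean_v, mix$noise_sd)
  })
}
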