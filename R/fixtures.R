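#' Published EX527 / paclitaxel isobolography summaries
#'
#' Convenience loaders for the summary statistics shipped with the package:
#' the printed log-probit equations (`ex527_pax_fits()`) and the published
#' isobolographic interaction table (`ex527_pax_summary()`) for the
#' combination of the SIRT1 inhibitor EX527 (selisistat) with paclitaxel in
#' five breast cancer cell lines, plus the signed SIGNOR-style causal graph
#' connecting the two drugs' molecular targets
#' (`sirt_tubulin_graph()`). These are the published-summary inputs used
#' for re-analysis when raw plates are unavailable.
#'
#' @return `ex527_pax_fits()`: a tibble of log-probit equations
#'   (`treatment`, `cell_line`, `arm`, `slope`, `intercept`, `r_squared`).
#'   `ex527_pax_summary()`: a tibble with one row per cell line
#'   (`ic50_mix`, `sem_mix`, `n_mix`, `l_ic50_add`, `sem_l`, `u_ic50_add`,
#'   `sem_u`, `n_add`, `parallel`); the `+/-` values are standard errors of
#'   the IC50 estimates. `sirt_tubulin_graph()`: a [causal_graph()].
#' @name published-summaries
NULL

#' @rdname published-summaries
#' @export
ex527_pax_fits <- function() {
  readr::read_csv(system.file("extdata", "ex527_pax_fits.csv",
                              package = "isobolr"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published-summaries
#' @export
ex527_pax_summary <- function() {
  readr::read_csv(system.file("extdata", "ex527_pax_summary.csv",
                              package = "isobolr"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published-summaries
#' @export
sirt_tubulin_graph <- function() {
  read_edge_list(system.file("extdata", "sirt_tubulin_edges.tsv",
                             package = "isobolr"))
}
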