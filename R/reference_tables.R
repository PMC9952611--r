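# Bundled reference counts: the contingency-table cells and risk-factor
# marginals from a published FAERS screen of electrolyte disorders for
# piperacillin/tazobactam (reports 2004-2018; pair-level counts). They
# let the full statistical layer run without any report-level data.

#' Bundled reference contingency tables
#'
#' Three published signal-screen tables ship with the package as plain
#' TSV cell counts (drug-event pair level, FAERS 2004-2018):
#'
#' * `"tzp_vs_all"`: piperacillin/tazobactam against all other drugs,
#'   across the ten electrolyte disorders.
#' * `"within_pcn"`: hypokalemia for each of twelve penicillin-class
#'   drugs against the other penicillins.
#' * `"pcn_vs_all"`: hypokalemia for the same twelve penicillins against
#'   all other drugs.
#'
#' @param which one of `"tzp_vs_all"`, `"within_pcn"`, `"pcn_vs_all"`.
#' @return data frame of labels and cells `a`, `b`, `c`, `d`, suitable
#'   for [dispro_screen_cells()].
#' @examples
#' dispro_screen_cells(reference_screen("tzp_vs_all"))
#' @export
reference_screen <- function(which = c("tzp_vs_all", "within_pcn",
                                       "pcn_vs_all")) {
  which <- match.arg(which)
  file <- switch(which,
    tzp_vs_all = "screen_tzp_electrolyte_vs_all.tsv",
    within_pcn = "screen_hypokalemia_within_pcn.tsv",
    pcn_vs_all = "screen_hypokalemia_pcn_vs_all.tsv")
  read_tsv(system.file("extdata", file, package = "pvsignal"))
}

#' Bundled risk-factor marginal counts
#'
#' Marginal case/control counts by sex and age group for
#' piperacillin/tazobactam-associated hypokalemia (reports with both sex
#' and age known), used by the closed-form odds-ratio examples.
#'
#' @return data frame with columns `variable`, `level`, `cases`,
#'   `controls`.
#' @export
reference_risk_marginals <- function() {
  read_tsv(system.file("extdata", "hypokalemia_risk_marginals.tsv",
                       package = "pvsignal"))
}
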