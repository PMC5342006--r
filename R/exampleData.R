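#' Bundled synergy records from a 131-patient lung adenocarcinoma IHC study
#'
#' The reported (pair, clinical-feature) synergy-screen records of a
#' 131-patient Asian lung adenocarcinoma cohort: single-marker and pair
#' Fisher p-values, the pair q-value within its clinical-feature family, and
#' the pair log-rank p-value, grouped by the five dichotomized features.
#' Several pairs recur under more than one feature; deduplicating yields the
#' 24 distinct predicted synthetic-lethal pairs of that study.
#'
#' @return data.frame with columns `feature`, `marker1`, `marker2`,
#'   `pSingle1`, `pSingle2`, `pPair`, `qPair`, `logrankPair`.
#' @examples
#' rec <- exampleSynergyRecords()
#' nrow(unique(rec[, c("marker1", "marker2")]))  # 24
#' @export
exampleSynergyRecords <- function() {
  read.delim(system.file("extdata", "ladc131_synergy_records.tsv",
                         package = "slpairs", mustWork = TRUE),
             fileEncoding = "UTF-8")
}
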