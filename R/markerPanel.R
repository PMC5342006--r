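#' The default 23-marker IHC panel
#'
#' Twenty proteins stained in lung adenocarcinoma tissue, three of them
#' (BRCA2, FEN1, MSH2) at two cellular locations, giving 23 markers. Each
#' marker carries its abnormality criterion on the ordinal intensity scale
#' (or percent membrane staining for CDH1) and the observed marginal
#' abnormality rate in the 131-patient cohort, which the synthetic generator
#' uses as its default marginal rate.
#'
#' @return a [MarkerPanel] with 23 markers.
#' @examples
#' nrow(markerInfo(defaultMarkerPanel()))
#' @export
defaultMarkerPanel <- function() {
  m <- data.frame(
    protein   = c("ABL1", "AURKB", "BCR", "BRCA1", "BRCA2", "BRCA2", "CDH1",
                  "CSNK1E", "CTNNB1", "EGFR", "FEN1", "FEN1", "MSH2", "MSH2",
                  "MYC", "PARP1", "POLB", "RAD54B", "RB1", "SGK2", "SKP2",
                  "TP53", "WNT5A"),
    location  = c("C", "C", "C", "C", "C", "N", "M", "C", "N", "C", "C", "N",
                  "C", "N", "N", "N", "N", "N", "N", "C", "C", "N", "C"),
    kind      = c(rep("intensity", 6), "percent", rep("intensity", 16)),
    direction = c(">=", ">=", ">=", "<", "<", "<", ">=", "<", ">=", ">=",
                  ">=", ">=", "<", "<", ">=", ">=", ">=", ">=", "<", "<",
                  ">=", ">=", ">="),
    threshold = c("2+", "1+", "2+", "1+", "2+", "2+", "70", "2+", "1+", "1+",
                  "2+", "2+", "1+", "1+", "2+", "1+", "1+", "1+", "1+", "2+",
                  "2+", "1+", "1+"),
    abnormalRate = c(0.24, 0.91, 0.27, 0.77, 0.67, 0.19, 0.62, 0.94, 0.06,
                     0.19, 0.58, 0.50, 0.31, 0.20, 0.42, 0.87, 0.91, 0.33,
                     0.55, 0.96, 0.10, 0.51, 0.60),
    stringsAsFactors = FALSE
  )
  m$marker <- paste0(m$protein, "(", m$location, ")")
  MarkerPanel(m[, c("marker", "protein", "location", "kind", "direction",
                    "threshold", "abnormalRate")])
}

#' Dichotomize an IHC observation against a marker's abnormality criterion
#'
#' Intensity observations are compared on the ordinal scale
#' 0 < ± < 1+ < 2+ < 3+; percent observations numerically. Both comparisons
#' are boundary-inclusive for `">="` criteria.
#'
#' @param observation character vector of grade symbols, or numeric/character
#'   percents for percent-kind markers. `NA` propagates.
#' @param marker one row of [markerInfo()] (a list or single-row data.frame),
#'   or a `MarkerPanel` together with `name`.
#' @param name marker identifier when `marker` is a `MarkerPanel`.
#' @return logical vector: `TRUE` = abnormal.
#' @examples
#' p <- defaultMarkerPanel()
#' dichotomizeMarker("1+", p, "RAD54B(N)")  # TRUE  (criterion >= 1+)
#' dichotomizeMarker("1+", p, "BRCA1(C)")   # FALSE (criterion <  1+)
#' @export
dichotomizeMarker <- function(observation, marker, name = NULL) {
  if (is(marker, "MarkerPanel")) {
    stopifnot(!is.null(name))
    info <- marker@markers
    marker <- as.list(info[match(name, info$marker), ])
    if (is.na(marker$marker)) stop("unknown marker: ", name)
  }
  if (marker$kind == "intensity") {
    r <- gradeRank(as.character(observation))
    thr <- gradeRank(marker$threshold)
  } else {
    r <- as.numeric(observation)
    if (any(is.na(r) & !is.na(observation)))
      stop("non-numeric percent observation for ", marker$marker)
    thr <- as.numeric(marker$threshold)
  }
  if (marker$direction == ">=") r >= thr else r < thr
}

#' Abnormality matrix of a cohort
#'
#' Applies every marker's criterion to its column of observations.
#'
#' @param ihc an [IHCCohort].
#' @return logical matrix (patients x markers).
#' @export
abnormalityMatrix <- function(ihc) {
  obs <- ihcObservations(ihc)
  info <- markerInfo(ihc)
  out <- matrix(NA, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  for (mk in colnames(obs)) {
    def <- as.list(info[info$marker == mk, ])
    out[, mk] <- dichotomizeMarker(obs[, mk], def)
  }
  out
}
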