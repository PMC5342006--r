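#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' PairedExpression: per-patient tumor/normal log2-ratios
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single assay
#' `"logRatio"` holding log2(tumor/matched normal) values, genes in rows and
#' patients in columns. This is the substrate of the co-differential-expression
#' pattern screen.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("PairedExpression", contains = "SummarizedExperiment")

setValidity("PairedExpression", function(object) {
  msg <- character()
  if (!"logRatio" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'logRatio' is required")
  else {
    lr <- SummarizedExperiment::assay(object, "logRatio")
    if (any(!is.finite(lr) & !is.na(lr)))
      msg <- c(msg, "log-ratios must be finite (NA allowed for missing)")
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate patient identifiers")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "gene (row) and patient (column) names are required")
  if (length(msg)) msg else TRUE
})

#' Construct a PairedExpression object
#'
#' @param logRatio numeric matrix of log2(tumor/normal) ratios, genes in rows,
#'   patients in columns; dimnames required.
#' @return a `PairedExpression` object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("FEN1", "RAD54B"), c("P1", "P2", "P3")))
#' PairedExpression(m)
#' @export
PairedExpression <- function(logRatio) {
  logRatio <- as.matrix(logRatio)
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(logRatio = logRatio))
  new("PairedExpression", se)
}

#' Extract the log2-ratio matrix (genes x patients)
#' @param x a `PairedExpression` object.
#' @return numeric matrix.
#' @export
logRatios <- function(x) {
  if (is(x, "PairedExpression")) SummarizedExperiment::assay(x, "logRatio") else as.matrix(x)
}

setMethod("show", "PairedExpression", function(object) {
  cat("PairedExpression:", nrow(object), "genes x", ncol(object), "patients\n")
  cat("  fold range: ", paste(signif(2^range(logRatios(object), na.rm = TRUE), 3),
                              collapse = " .. "), "\n", sep = "")
})

#' MarkerPanel: IHC marker definitions with abnormality criteria
#'
#' Each marker is one protein stained at one cellular location, with a
#' directional abnormality criterion on either the ordinal staining-intensity
#' scale 0 < ± < 1+ < 2+ < 3+ or a percent-stained scale.
#'
#' @slot markers data.frame with columns `marker` (e.g. `"RAD54B(N)"`),
#'   `protein`, `location` (C/N/M), `kind` (`"intensity"` or `"percent"`),
#'   `direction` (`">="` or `"<"`), `threshold` (grade symbol or percent),
#'   `abnormalRate` (cohort marginal abnormality fraction, used by the
#'   synthetic generator).
#' @export
setClass("MarkerPanel", representation(markers = "data.frame"))

setValidity("MarkerPanel", function(object) {
  m <- object@markers
  need <- c("marker", "protein", "location", "kind", "direction", "threshold", "abnormalRate")
  if (!all(need %in% names(m))) return(paste("missing columns:",
      paste(setdiff(need, names(m)), collapse = ", ")))
  msg <- character()
  if (anyDuplicated(m$marker)) msg <- c(msg, "duplicate marker identifiers")
  if (!all(m$location %in% c("C", "N", "M"))) msg <- c(msg, "location must be C, N or M")
  if (!all(m$kind %in% c("intensity", "percent"))) msg <- c(msg, "kind must be intensity or percent")
  if (!all(m$direction %in% c(">=", "<"))) msg <- c(msg, "direction must be >= or <")
  ints <- m$kind == "intensity"
  if (any(ints) && !all(m$threshold[ints] %in% GRADE_LEVELS))
    msg <- c(msg, "intensity thresholds must be grades 0, ±, 1+, 2+, 3+")
  if (any(!ints)) {
    pc <- suppressWarnings(as.numeric(m$threshold[!ints]))
    if (anyNA(pc) || any(pc < 0 | pc > 100))
      msg <- c(msg, "percent thresholds must be numbers in [0,100]")
  }
  if (any(m$abnormalRate < 0 | m$abnormalRate > 1)) msg <- c(msg, "abnormalRate must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerPanel
#' @param markers data.frame, see the class description.
#' @return a `MarkerPanel`.
#' @export
MarkerPanel <- function(markers) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  markers$threshold <- as.character(markers$threshold)
  new("MarkerPanel", markers = markers)
}

#' Marker definition table of a panel
#' @param x a `MarkerPanel` or `IHCCohort`.
#' @return data.frame of marker definitions.
#' @export
markerInfo <- function(x) {
  if (is(x, "IHCCohort")) x@panel@markers else x@markers
}

#' Marker identifiers of a panel
#' @param x a `MarkerPanel` or `IHCCohort`.
#' @return character vector.
#' @export
markerNames <- function(x) markerInfo(x)$marker

setMethod("show", "MarkerPanel", function(object) {
  m <- object@markers
  cat("MarkerPanel:", nrow(m), "markers on", length(unique(m$protein)), "proteins\n")
  cat("  criteria: ", paste(head(paste0(m$marker, " ", m$direction, " ", m$threshold), 4),
                            collapse = "; "), if (nrow(m) > 4) "; ..." else "", "\n", sep = "")
})

#' IHCCohort: per-patient ordinal IHC observations for a marker panel
#'
#' @slot observations character matrix, patients in rows, markers in columns;
#'   entries are grade symbols for intensity markers or numbers (as character)
#'   for percent markers.
#' @slot panel the `MarkerPanel` the columns refer to.
#' @export
setClass("IHCCohort", representation(observations = "matrix", panel = "MarkerPanel"))

setValidity("IHCCohort", function(object) {
  obs <- object@observations
  info <- object@panel@markers
  msg <- character()
  if (is.null(rownames(obs))) msg <- c(msg, "patient ids (rownames) required")
  if (!all(colnames(obs) %in% info$marker))
    msg <- c(msg, "observation columns must be panel markers")
  for (mk in colnames(obs)) {
    kind <- info$kind[info$marker == mk]
    v <- obs[, mk]
    v <- v[!is.na(v)]
    if (kind == "intensity" && !all(v %in% GRADE_LEVELS))
      msg <- c(msg, paste0("invalid grade for ", mk))
    if (kind == "percent") {
      nv <- suppressWarnings(as.numeric(v))
      if (anyNA(nv) || any(nv < 0 | nv > 100))
        msg <- c(msg, paste0("invalid percent for ", mk))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IHCCohort
#' @param observations character matrix (patients x markers).
#' @param panel a `MarkerPanel`.
#' @return an `IHCCohort`.
#' @export
IHCCohort <- function(observations, panel) {
  new("IHCCohort", observations = as.matrix(observations), panel = panel)
}

#' IHC observation matrix (patients x markers)
#' @param x an `IHCCohort`.
#' @return character matrix.
#' @export
ihcObservations <- function(x) x@observations

setMethod("show", "IHCCohort", function(object) {
  cat("IHCCohort:", nrow(object@observations), "patients x",
      ncol(object@observations), "markers\n")
})

#' SyntheticStudy: one simulated cohort (expression + IHC + clinical)
#'
#' @slot expression a `PairedExpression`.
#' @slot ihc an `IHCCohort`.
#' @slot clinical data.frame of clinical records (one row per patient).
#' @slot spec list echo of the generating `cohortSpec`.
#' @export
setClass("SyntheticStudy", representation(expression = "PairedExpression",
                                          ihc = "IHCCohort",
                                          clinical = "data.frame",
                                          spec = "list"))

setValidity("SyntheticStudy", function(object) {
  pe <- colnames(object@expression)
  pi_ <- rownames(object@ihc@observations)
  pc <- object@clinical$patient
  if (!identical(pe, pi_) || !identical(pe, pc))
    return("expression, IHC and clinical must share identical patient ids")
  TRUE
})

#' @describeIn SyntheticStudy accessor for the expression component.
#' @param x a `SyntheticStudy`.
#' @export
studyExpression <- function(x) x@expression

#' @describeIn SyntheticStudy accessor for the IHC component.
#' @export
studyIHC <- function(x) x@ihc

#' @describeIn SyntheticStudy accessor for the clinical table.
#' @export
studyClinical <- function(x) x@clinical

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", ncol(object@expression), "patients,",
      nrow(object@expression), "genes,",
      ncol(object@ihc@observations), "IHC markers\n")
})

#' RiskModel: fitted proportional-hazards marker risk model
#'
#' @slot coefficients named numeric vector of log hazard ratios.
#' @slot design character vector of design variable names (markers, covariates).
#' @slot withCovariates logical, whether age/stage covariates are in the design.
#' @slot training identifier of the training cohort.
#' @slot fit the underlying `coxph` fit.
#' @export
setClass("RiskModel", representation(coefficients = "numeric", design = "character",
                                     withCovariates = "logical", training = "character",
                                     fit = "ANY"))

setValidity("RiskModel", function(object) {
  if (any(!is.finite(object@coefficients))) return("coefficients must be finite")
  if (!identical(names(object@coefficients), object@design))
    return("coefficient names must match the recorded design")
  TRUE
})

#' @describeIn RiskModel fitted log-hazard-ratio coefficients.
#' @param x a `RiskModel`.
#' @export
riskCoefficients <- function(x) x@coefficients

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel trained on '", object@training, "':\n", sep = "")
  print(round(exp(object@coefficients), 3))
})
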