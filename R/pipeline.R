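#' Pipeline configuration
#'
#' Validates and normalizes a configuration list (or a YAML/JSON file) for
#' [runPipeline()]. Unknown keys are rejected; parameters must lie in their
#' documented ranges.
#'
#' @param config named list, or path to a `.yaml`/`.yml`/`.json` file. Keys:
#'   `pairList`, `expression`, `panel`, `ihc`, `clinical`, `survival` (file
#'   paths; `panel`, `survival` optional), `outDir`, and parameters
#'   `foldCutoff` (default 1.5), `nPerm` (10000), `alpha` (0.05),
#'   `minFraction` (0.01), `fdrMethod` (`"storey"`/`"bh"`), `fdrFamily`
#'   (`"feature"`/`"global"`), `seed`.
#' @return normalized config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(pairList = NULL, expression = NULL, panel = NULL,
                   ihc = NULL, clinical = NULL, survival = NULL,
                   outDir = NULL, foldCutoff = 1.5, nPerm = 10000,
                   alpha = 0.05, minFraction = 0.01, fdrMethod = "storey",
                   fdrFamily = "feature", seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$foldCutoff > 1, cfg$nPerm >= 1, cfg$alpha > 0, cfg$alpha < 1,
            cfg$minFraction >= 0, cfg$minFraction < 1,
            cfg$fdrMethod %in% c("storey", "bh"),
            cfg$fdrFamily %in% c("feature", "global"))
  structure(cfg, class = "pipelineConfig")
}

#' Read a log-ratio TSV (patients in rows, genes in columns)
#' @param path TSV file with a `patient` column followed by gene columns.
#' @return a [PairedExpression].
#' @export
readLogRatioTSV <- function(path) {
  d <- read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  stopifnot("patient" %in% names(d))
  m <- as.matrix(d[setdiff(names(d), "patient")])
  rownames(m) <- d$patient
  PairedExpression(t(m))
}

#' Read a candidate gene-pair list TSV (columns gene1, gene2, optionally source)
#' @param path TSV file.
#' @return data.frame.
#' @export
readPairListTSV <- function(path) {
  d <- read.delim(path, fileEncoding = "UTF-8")
  stopifnot(all(c("gene1", "gene2") %in% names(d)))
  d
}

#' Read a marker-panel TSV (columns of [markerInfo()])
#' @param path TSV file.
#' @return a [MarkerPanel].
#' @export
readMarkerPanelTSV <- function(path) {
  MarkerPanel(read.delim(path, fileEncoding = "UTF-8",
                         colClasses = c(threshold = "character")))
}

#' Read an IHC cohort TSV (patient column + one column per marker)
#' @param path TSV file; the literal `±` grade is allowed.
#' @param panel a [MarkerPanel].
#' @return an [IHCCohort].
#' @export
readIHCTSV <- function(path, panel) {
  d <- read.delim(path, check.names = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  stopifnot("patient" %in% names(d))
  m <- as.matrix(d[setdiff(names(d), "patient")])
  rownames(m) <- d$patient
  IHCCohort(m, panel)
}

#' Read a clinical TSV
#' @param path TSV with columns `patient`, `survivalMonths`, `event`, `grade`,
#'   `metastasis`, `nodal`, `stage`, `age`, `sex`.
#' @return data.frame.
#' @export
readClinicalTSV <- function(path) {
  read.delim(path, fileEncoding = "UTF-8")
}

#' Validate pipeline input files
#'
#' Checks column schemas, value vocabularies (including the ordinal grade
#' symbols 0, ±, 1+, 2+, 3+), numeric ranges, and patient-id joinability
#' across tables. Violations are reported, not thrown.
#'
#' @param paths named list of file paths (any of `expression`, `pairList`,
#'   `panel`, `ihc`, `clinical`).
#' @return data.frame with columns `file`, `where`, `issue`; zero rows when
#'   everything is well-formed.
#' @export
validateInputs <- function(paths) {
  v <- list()
  note <- function(file, where, issue)
    v[[length(v) + 1]] <<- data.frame(file = file, where = where, issue = issue)
  ids <- list()

  panel <- NULL
  if (!is.null(paths$panel)) {
    panel <- tryCatch(readMarkerPanelTSV(paths$panel), error = function(e) {
      note(paths$panel, "panel", conditionMessage(e)); NULL })
  } else panel <- defaultMarkerPanel()

  if (!is.null(paths$expression)) {
    d <- tryCatch(read.delim(paths$expression, check.names = FALSE,
                             fileEncoding = "UTF-8"),
                  error = function(e) { note(paths$expression, "file", conditionMessage(e)); NULL })
    if (!is.null(d)) {
      if (!"patient" %in% names(d)) note(paths$expression, "columns", "missing 'patient' column")
      else {
        ids$expression <- as.character(d$patient)
        num <- d[setdiff(names(d), "patient")]
        bad <- !vapply(num, is.numeric, logical(1))
        if (any(bad)) note(paths$expression, paste(names(num)[bad], collapse = ","),
                           "non-numeric log-ratio column")
      }
    }
  }
  if (!is.null(paths$pairList)) {
    d <- tryCatch(read.delim(paths$pairList, fileEncoding = "UTF-8"),
                  error = function(e) { note(paths$pairList, "file", conditionMessage(e)); NULL })
    if (!is.null(d) && !all(c("gene1", "gene2") %in% names(d)))
      note(paths$pairList, "columns", "need columns gene1, gene2")
  }
  if (!is.null(paths$ihc) && !is.null(panel)) {
    d <- tryCatch(read.delim(paths$ihc, check.names = FALSE, colClasses = "character",
                             fileEncoding = "UTF-8"),
                  error = function(e) { note(paths$ihc, "file", conditionMessage(e)); NULL })
    if (!is.null(d)) {
      if (!"patient" %in% names(d)) note(paths$ihc, "columns", "missing 'patient' column")
      else {
        ids$ihc <- as.character(d$patient)
        info <- markerInfo(panel)
        for (mk in setdiff(names(d), "patient")) {
          if (!mk %in% info$marker) { note(paths$ihc, mk, "not a panel marker"); next }
          kind <- info$kind[info$marker == mk]
          vv <- d[[mk]][!is.na(d[[mk]])]
          if (kind == "intensity") {
            bad <- which(!vv %in% GRADE_LEVELS)
            if (length(bad)) note(paths$ihc, paste0(mk, " row ", bad[1]),
                                  paste0("invalid grade '", vv[bad[1]], "'"))
          } else {
            nv <- suppressWarnings(as.numeric(vv))
            bad <- which(is.na(nv) | nv < 0 | nv > 100)
            if (length(bad)) note(paths$ihc, paste0(mk, " row ", bad[1]),
                                  "percent outside [0,100]")
          }
        }
      }
    }
  }
  if (!is.null(paths$clinical)) {
    d <- tryCatch(read.delim(paths$clinical, fileEncoding = "UTF-8"),
                  error = function(e) { note(paths$clinical, "file", conditionMessage(e)); NULL })
    if (!is.null(d)) {
      need <- c("patient", "survivalMonths", "event", "grade", "metastasis",
                "nodal", "stage")
      miss <- setdiff(need, names(d))
      if (length(miss)) note(paths$clinical, "columns",
                             paste("missing:", paste(miss, collapse = ", ")))
      if ("patient" %in% names(d)) ids$clinical <- as.character(d$patient)
      if ("survivalMonths" %in% names(d) && any(d$survivalMonths < 0, na.rm = TRUE))
        note(paths$clinical, paste0("row ", which(d$survivalMonths < 0)[1]),
             "negative survival time")
      if ("event" %in% names(d) && !all(d$event %in% c(0, 1, NA)))
        note(paths$clinical, "event", "event must be 0/1")
      vocab <- list(grade = c("well", "moderate", "poor"),
                    metastasis = c("yes", "no"), nodal = c("N0", "N1", "N2"),
                    stage = c("I", "II", "III", "IV"))
      for (col in intersect(names(vocab), names(d))) {
        bad <- which(!d[[col]] %in% c(vocab[[col]], NA))
        if (length(bad)) note(paths$clinical, paste0(col, " row ", bad[1]),
                              paste0("invalid value '", d[[col]][bad[1]], "'"))
      }
    }
  }
  if (length(ids) >= 2) {
    ref <- ids[[1]]
    for (k in names(ids)[-1]) {
      extra <- setdiff(ids[[k]], ref)
      lost <- setdiff(ref, ids[[k]])
      if (length(extra)) note(paths[[k]], "patient ids",
        paste0("ids absent from ", names(ids)[1], ": ", paste(head(extra, 3), collapse = ", ")))
      if (length(lost)) note(paths[[k]], "patient ids",
        paste0("ids of ", names(ids)[1], " missing here: ", paste(head(lost, 3), collapse = ", ")))
    }
  }
  if (!length(v)) data.frame(file = character(), where = character(),
                             issue = character())
  else do.call(rbind, v)
}

#' Run the full screening pipeline
#'
#' Executes the configured stages in order: expression pattern screen with
#' permutation p and q-values; IHC pair synergy screen with the 2-hop
#' expansion; and survival-marker analysis (per-pair log-rank, univariate Cox
#' for each predicted pair plus age/sex/stage, and a stepwise-AIC multivariate
#' model per predicted pair). All randomness flows from the single config
#' seed. Stage outputs are returned and, when `outDir` is set, written as TSV.
#'
#' @param config a [pipelineConfig()] (or list / file path coercible to one).
#' @return a `RunReport` list: `screen`, `candidates`, `synergyRecords`,
#'   `predictedPairs`, `twoHop`, `survivalUnivariate`, `survivalStepwise`,
#'   `log` (stage row counts), `provenance` (config echo and seed).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "pipelineConfig")) config <- pipelineConfig(config)
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))
  report <- list()

  expr <- NULL
  if (!is.null(config$expression) && !is.null(config$pairList)) {
    viol <- validateInputs(config[c("expression", "pairList")])
    if (nrow(viol)) stop("input validation failed: ", viol$file[1], " [",
                         viol$where[1], "] ", viol$issue[1])
    expr <- readLogRatioTSV(config$expression)
    pairs <- readPairListTSV(config$pairList)
    scr <- screenExpression(expr, pairs, foldCutoff = config$foldCutoff,
                            nPerm = config$nPerm, seed = config$seed,
                            fdrMethod = config$fdrMethod,
                            minFraction = config$minFraction)
    report$screen <- scr
    report$candidates <- selectCandidates(scr, minFraction = config$minFraction)
    say("expression screen: ", nrow(scr), " (pair, pattern) records, ",
        nrow(report$candidates), " candidate pairs")
  } else say("expression stage skipped (no expression/pairList configured)")

  if (!is.null(config$ihc) && !is.null(config$clinical)) {
    viol <- validateInputs(config[c("panel", "ihc", "clinical")])
    if (nrow(viol)) stop("input validation failed: ", viol$file[1], " [",
                         viol$where[1], "] ", viol$issue[1])
    panel <- if (is.null(config$panel)) defaultMarkerPanel()
             else readMarkerPanelTSV(config$panel)
    ihc <- readIHCTSV(config$ihc, panel)
    clinical <- readClinicalTSV(config$clinical)
    clinical <- clinical[match(rownames(ihcObservations(ihc)), clinical$patient), ]
    syn <- synergyScreen(ihc, clinical, alpha = config$alpha,
                         fdrFamily = config$fdrFamily,
                         fdrMethod = config$fdrMethod)
    report$synergyRecords <- syn$records
    report$predictedPairs <- syn$predictedPairs
    info <- markerInfo(panel)
    prot <- function(mk) info$protein[match(mk, info$marker)]
    report$twoHop <- twoHopCandidates(
      data.frame(gene1 = prot(syn$predictedPairs$marker1),
                 gene2 = prot(syn$predictedPairs$marker2)))
    say("synergy screen: ", nrow(syn$records), " records, ",
        nrow(syn$predictedPairs), " predicted pairs, ",
        nrow(report$twoHop), " 2-hop candidates")

    if (all(c("survivalMonths", "event") %in% names(clinical))) {
      abn <- abnormalityMatrix(ihc)
      sd_ <- data.frame(time = clinical$survivalMonths, event = clinical$event,
                        age65 = as.integer(clinical$age > 65),
                        male = as.integer(clinical$sex == "male"),
                        stageHigh = as.integer(clinical$stage %in% c("III", "IV")))
      uni <- list()
      for (v in c("stageHigh", "age65", "male"))
        uni[[v]] <- cbind(marker = v, coxUnivariate(sd_, v))
      for (i in seq_len(nrow(syn$predictedPairs))) {
        m1 <- syn$predictedPairs$marker1[i]; m2 <- syn$predictedPairs$marker2[i]
        nm <- paste0(m1, "-", m2)
        sd_$pairInd <- as.integer(abn[, m1] & abn[, m2])
        if (length(unique(sd_$pairInd)) < 2) next
        uni[[nm]] <- cbind(marker = nm, coxUnivariate(sd_, "pairInd"))
      }
      report$survivalUnivariate <- do.call(rbind, uni)
      rownames(report$survivalUnivariate) <- NULL
      steps <- list()
      for (i in seq_len(nrow(syn$predictedPairs))) {
        m1 <- syn$predictedPairs$marker1[i]; m2 <- syn$predictedPairs$marker2[i]
        nm <- paste0(m1, "-", m2)
        sd_$pairInd <- as.integer(abn[, m1] & abn[, m2])
        if (length(unique(sd_$pairInd)) < 2) next
        st <- coxStepwise(sd_, c("pairInd", "age65", "male", "stageHigh"))
        if (nrow(st$table))
          steps[[nm]] <- cbind(marker = nm, st$table, aic = st$aic)
      }
      report$survivalStepwise <- do.call(rbind, steps)
      rownames(report$survivalStepwise) <- NULL
      say("survival stage: ", length(uni), " univariate fits, ",
          length(steps), " stepwise models")
    } else say("survival stage skipped (no survival columns in clinical table)")
  } else say("synergy/survival stages skipped (no ihc/clinical configured)")

  report$log <- log
  report$provenance <- list(config = unclass(config), seed = config$seed,
                            packageVersion = as.character(utils::packageVersion("slpairs")))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("screen", "candidates", "synergyRecords", "predictedPairs",
                 "twoHop", "survivalUnivariate", "survivalStepwise")) {
      if (!is.null(report[[nm]]))
        write.table(report[[nm]], file.path(config$outDir, paste0(nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    fileEncoding = "UTF-8")
    }
    writeLines(log, file.path(config$outDir, "pipeline.log"))
  }
  report
}
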