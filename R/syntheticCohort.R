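#' Define a planted co-expression pattern for a gene pair
#'
#' @param gene1,gene2 gene symbols (distinct).
#' @param pattern one of `"uu"`, `"ud"`, `"du"`, `"dd"`: the signs of the two
#'   planted log-ratios (u = up-regulated in tumor, d = down-regulated).
#' @param penetrance fraction in \[0, 1\] of patients carrying the pattern.
#' @param foldMagnitude fold change applied to carriers (must exceed 1; planted
#'   log2-ratios are `+/- log2(foldMagnitude)`).
#' @return a `plantedPair` list.
#' @export
plantedPair <- function(gene1, gene2, pattern = c("uu", "ud", "du", "dd"),
                        penetrance, foldMagnitude = 2.0) {
  pattern <- match.arg(pattern)
  stopifnot(gene1 != gene2, penetrance >= 0, penetrance <= 1, foldMagnitude > 1)
  structure(list(gene1 = gene1, gene2 = gene2, pattern = pattern,
                 penetrance = penetrance, foldMagnitude = foldMagnitude),
            class = "plantedPair")
}

#' Specify a synthetic study design
#'
#' Collects every tunable of the generator: cohort size, gene panel, planted
#' co-expression pairs, expression noise, IHC marker panel with marginal
#' abnormality rates, interaction-only marker-pair/feature synergy effects,
#' marker-dependent hazards, censoring, and the study seed.
#'
#' @param nPatients cohort size (default 83, the size of the paired
#'   tumor/normal expression cohort; the IHC cohort in the source study had
#'   131 patients — pass `nPatients = 131` to emulate it).
#' @param genes gene symbols of the expression panel.
#' @param plantedPairs list of [plantedPair()] objects.
#' @param noiseSd standard deviation of the baseline log2-ratio noise (> 0).
#' @param panel a [MarkerPanel]; defaults to [defaultMarkerPanel()].
#' @param markerRates named marginal abnormality rates overriding the panel's
#'   `abnormalRate` column.
#' @param featureRates named baseline adverse-probability per clinical feature
#'   (`survival3y`, `grade`, `metastasis`, `nodal`, `stage`).
#' @param synergyEffects list of lists with fields `marker1`, `marker2`,
#'   `feature`, `oddsRatio` (> 0): the adverse odds are multiplied by
#'   `oddsRatio` ONLY for patients with both markers abnormal; single-marker
#'   abnormality leaves the baseline untouched (interaction-only planting).
#' @param hazardEffects named log hazard ratios over indicator names, used by
#'   [generateSurvival()].
#' @param baselineHazard events per month at indicator zero (default 0.02,
#'   i.e. median survival of roughly 35 months).
#' @param censorWindow months of uniform administrative censoring (default 120).
#' @param earlyCensorRate fraction of patients censored alive before 36 months
#'   (not evaluable for the 3-year survival feature; default 0.1).
#' @param seed study RNG seed; split internally into fixed per-component
#'   streams so e.g. adding markers never perturbs the expression draws.
#' @return a `cohortSpec` list.
#' @export
cohortSpec <- function(nPatients = 83, genes = NULL, plantedPairs = list(),
                       noiseSd = 1.0, panel = defaultMarkerPanel(),
                       markerRates = NULL, featureRates = NULL,
                       synergyEffects = list(), hazardEffects = numeric(),
                       baselineHazard = 0.02, censorWindow = 120,
                       earlyCensorRate = 0.1, seed = 1L) {
  stopifnot(nPatients >= 2, noiseSd > 0, baselineHazard > 0, censorWindow >= 0,
            earlyCensorRate >= 0, earlyCensorRate < 1)
  if (is.null(genes)) genes <- unique(unlist(lapply(plantedPairs, function(p)
    c(p$gene1, p$gene2))))
  for (p in plantedPairs) {
    stopifnot(inherits(p, "plantedPair"))
    if (!all(c(p$gene1, p$gene2) %in% genes))
      stop("planted gene not in the gene panel: ",
           paste(setdiff(c(p$gene1, p$gene2), genes), collapse = ", "))
  }
  rates <- setNames(markerInfo(panel)$abnormalRate, markerNames(panel))
  if (!is.null(markerRates)) {
    bad <- setdiff(names(markerRates), names(rates))
    if (length(bad)) stop("markerRates for unknown markers: ", paste(bad, collapse = ", "))
    rates[names(markerRates)] <- markerRates
  }
  ## Baseline adverse rates for the five dichotomized features; values chosen
  ## to emulate a stage-mixed adenocarcinoma cohort.
  fr <- c(survival3y = 0.45, grade = 0.35, metastasis = 0.20,
          nodal = 0.45, stage = 0.40)
  if (!is.null(featureRates)) {
    bad <- setdiff(names(featureRates), FEATURES)
    if (length(bad)) stop("unknown clinical feature(s): ", paste(bad, collapse = ", "))
    fr[names(featureRates)] <- featureRates
  }
  for (s in synergyEffects) {
    stopifnot(all(c("marker1", "marker2", "feature", "oddsRatio") %in% names(s)))
    if (!s$feature %in% FEATURES) stop("unknown clinical feature: ", s$feature)
    if (s$oddsRatio <= 0) stop("synergy odds ratios must be > 0")
    if (!all(c(s$marker1, s$marker2) %in% names(rates)))
      stop("synergy effect references markers outside the panel")
  }
  if (length(hazardEffects)) stopifnot(!is.null(names(hazardEffects)),
                                       all(is.finite(hazardEffects)))
  structure(list(nPatients = as.integer(nPatients), genes = genes,
                 plantedPairs = plantedPairs, noiseSd = noiseSd, panel = panel,
                 markerRates = rates, featureRates = fr,
                 synergyEffects = synergyEffects, hazardEffects = hazardEffects,
                 baselineHazard = baselineHazard, censorWindow = censorWindow,
                 earlyCensorRate = earlyCensorRate, seed = as.integer(seed)),
            class = "cohortSpec")
}

.patternSigns <- function(pattern) {
  switch(pattern, uu = c(1, 1), ud = c(1, -1), du = c(-1, 1), dd = c(-1, -1))
}

#' Generate a paired tumor/normal log-ratio matrix with planted patterns
#'
#' Baseline entries are Normal(0, `noiseSd`) log2-ratios. For each planted
#' pair, a Bernoulli(`penetrance`) subset of patients has both genes set to
#' `+/- log2(foldMagnitude)` with pattern-determined signs (later planted
#' pairs overwrite earlier ones on shared genes). Deterministic given the
#' spec's seed.
#'
#' @param spec a [cohortSpec()].
#' @return a [PairedExpression] (genes x patients).
#' @export
generateExpression <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  if (length(spec$genes) == 0) stop("spec has no genes in the expression panel")
  set.seed(componentSeeds(spec$seed)[["expression"]])
  n <- spec$nPatients
  m <- matrix(rnorm(length(spec$genes) * n, 0, spec$noiseSd),
              nrow = length(spec$genes), ncol = n,
              dimnames = list(spec$genes, patientIds(n)))
  for (p in spec$plantedPairs) {
    carriers <- runif(n) < p$penetrance
    s <- .patternSigns(p$pattern) * log2(p$foldMagnitude)
    m[p$gene1, carriers] <- s[1]
    m[p$gene2, carriers] <- s[2]
  }
  PairedExpression(m)
}

.sampleGrades <- function(abnormal, def, n) {
  if (def$kind == "intensity") {
    ok <- dichotomizeMarker(GRADE_LEVELS, def)
    out <- character(n)
    out[abnormal]  <- sample(GRADE_LEVELS[ok],  sum(abnormal),  replace = TRUE)
    out[!abnormal] <- sample(GRADE_LEVELS[!ok], sum(!abnormal), replace = TRUE)
  } else {
    thr <- as.numeric(def$threshold)
    out <- character(n)
    ## boundary-inclusive ">=": satisfying percents are [thr, 100], the
    ## complement [0, thr-1] (integer-valued observations)
    hi <- def$direction == ">="
    above <- function(k) round(runif(k, thr, 100))
    below <- function(k) pmin(round(runif(k, 0, thr - 1)), thr - 1)
    out[abnormal]  <- as.character(if (hi) above(sum(abnormal)) else below(sum(abnormal)))
    out[!abnormal] <- as.character(if (hi) below(sum(!abnormal)) else above(sum(!abnormal)))
  }
  out
}

#' Generate an IHC cohort and clinical records with interaction-only synergy
#'
#' Per-marker abnormality is drawn at its marginal rate and mapped back to an
#' ordinal grade (or percent) consistent with that marker's criterion:
#' abnormal patients receive a grade sampled uniformly from the grades
#' satisfying the criterion, normal patients from the complement. For each
#' synergy effect, the adverse odds of the target clinical feature are
#' multiplied by the effect's odds ratio only in patients with both markers
#' abnormal; single-marker abnormality leaves the baseline untouched.
#' Survival months are constructed consistently with the 3-year feature:
#' adverse patients die uniformly within 36 months, an `earlyCensorRate`
#' fraction is censored alive before 36 months (not evaluable), and the rest
#' survive past 36 months.
#'
#' @param spec a [cohortSpec()].
#' @return list with components `ihc` (an [IHCCohort]) and `clinical`
#'   (data.frame: patient, survivalMonths, event, grade, metastasis, nodal,
#'   stage, age, sex).
#' @export
generateIHCClinical <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  seeds <- componentSeeds(spec$seed)
  n <- spec$nPatients
  info <- markerInfo(spec$panel)

  set.seed(seeds[["ihc"]])
  abn <- sapply(info$marker, function(mk) runif(n) < spec$markerRates[[mk]])
  rownames(abn) <- patientIds(n)
  obs <- abn
  storage.mode(obs) <- "character"
  for (mk in info$marker) {
    def <- as.list(info[info$marker == mk, ])
    obs[, mk] <- .sampleGrades(abn[, mk], def, n)
  }
  ihc <- IHCCohort(obs, spec$panel)

  set.seed(seeds[["clinical"]])
  adverse <- sapply(FEATURES, function(f) {
    eta <- rep(qlogis(spec$featureRates[[f]]), n)
    for (s in spec$synergyEffects) {
      if (s$feature == f) {
        both <- abn[, s$marker1] & abn[, s$marker2]
        eta[both] <- eta[both] + log(s$oddsRatio)
      }
    }
    runif(n) < plogis(eta)
  })

  pickIf <- function(cond, yes, no) ifelse(cond, sample(yes, n, TRUE), sample(no, n, TRUE))
  clin <- data.frame(
    patient = patientIds(n),
    grade = ifelse(adverse[, "grade"], "poor", sample(c("well", "moderate"), n, TRUE)),
    metastasis = ifelse(adverse[, "metastasis"], "yes", "no"),
    nodal = pickIf(adverse[, "nodal"], c("N1", "N2"), "N0"),
    stage = pickIf(adverse[, "stage"], c("III", "IV"), c("I", "II")),
    age = pmin(pmax(round(rnorm(n, 65, 10)), 30), 90),
    sex = sample(c("male", "female"), n, TRUE),
    stringsAsFactors = FALSE
  )
  earlyCensor <- runif(n) < spec$earlyCensorRate
  died3y <- adverse[, "survival3y"] & !earlyCensor
  time <- numeric(n); event <- integer(n)
  time[earlyCensor] <- runif(sum(earlyCensor), 0, 36); event[earlyCensor] <- 0L
  time[died3y] <- runif(sum(died3y), 0.5, 36); event[died3y] <- 1L
  late <- !earlyCensor & !died3y
  time[late] <- 36 + rexp(sum(late), 1 / 24)
  event[late] <- rbinom(sum(late), 1, 0.5)
  clin$survivalMonths <- time
  clin$event <- event
  clin <- clin[, c("patient", "survivalMonths", "event", "grade", "metastasis",
                   "nodal", "stage", "age", "sex")]
  list(ihc = ihc, clinical = clin)
}

#' Generate exponential survival times with marker-dependent hazards
#'
#' Event times are exponential with hazard
#' `baselineHazard * exp(sum(beta * indicator))`; censoring is independent
#' Uniform(0, `censorWindow`). The event flag is 1 iff the event time does not
#' exceed the censoring time.
#'
#' @param spec a [cohortSpec()]; its `hazardEffects` names must be columns of
#'   `indicators`.
#' @param indicators data.frame or matrix of binary indicators (one row per
#'   subject).
#' @return data.frame with columns `time` (months) and `event` (0/1).
#' @export
generateSurvival <- function(spec, indicators) {
  stopifnot(inherits(spec, "cohortSpec"))
  indicators <- as.data.frame(indicators)
  beta <- spec$hazardEffects
  miss <- setdiff(names(beta), names(indicators))
  if (length(miss)) stop("hazardEffects refer to unknown indicator(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(indicators)
  lp <- if (length(beta)) as.matrix(indicators[names(beta)]) %*% beta else rep(0, n)
  set.seed(componentSeeds(spec$seed)[["survival"]])
  tEvent <- rexp(n, rate = spec$baselineHazard * exp(as.numeric(lp)))
  tCens <- runif(n, 0, spec$censorWindow)
  data.frame(time = pmin(tEvent, tCens), event = as.integer(tEvent <= tCens))
}

#' Generate a complete synthetic study
#'
#' Composes [generateExpression()] and [generateIHCClinical()] over a shared
#' patient index. Bit-identical for identical specs (including the seed).
#'
#' @param spec a [cohortSpec()].
#' @return a [SyntheticStudy].
#' @export
generateStudy <- function(spec) {
  expr <- generateExpression(spec)
  ic <- generateIHCClinical(spec)
  new("SyntheticStudy", expression = expr, ihc = ic$ihc, clinical = ic$clinical,
      spec = unclass(spec)[setdiff(names(spec), "panel")])
}

#' Write a synthetic study to disk as TSV tables plus a JSON sidecar
#'
#' Writes `expression.tsv` (patients in rows, genes in columns),
#' `ihc.tsv`, `clinical.tsv`, `panel.tsv` and `spec.json` into `dir`,
#' in the formats [runPipeline()] reads.
#'
#' @param study a [SyntheticStudy].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    file.path(dir, f)
  }
  lr <- t(logRatios(studyExpression(study)))
  p1 <- wt(data.frame(patient = rownames(lr), lr, check.names = FALSE), "expression.tsv")
  obs <- ihcObservations(studyIHC(study))
  p2 <- wt(data.frame(patient = rownames(obs), obs, check.names = FALSE), "ihc.tsv")
  p3 <- wt(studyClinical(study), "clinical.tsv")
  p4 <- wt(markerInfo(studyIHC(study)), "panel.tsv")
  sp <- study@spec
  sp$plantedPairs <- lapply(sp$plantedPairs, unclass)
  p5 <- file.path(dir, "spec.json")
  jsonlite::write_json(sp, p5, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3, p4, p5))
}
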