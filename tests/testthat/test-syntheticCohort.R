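test_that("identical specs give bit-identical studies", {
  spec <- cohortSpec(nPatients = 40, genes = c("A", "B"),
                     plantedPairs = list(plantedPair("A", "B", "ud", 0.3)),
                     synergyEffects = list(list(marker1 = "TP53(N)",
                                                marker2 = "RB1(N)",
                                                feature = "metastasis",
                                                oddsRatio = 4)),
                     seed = 99)
  s1 <- generateStudy(spec)
  s2 <- generateStudy(spec)
  expect_identical(logRatios(studyExpression(s1)), logRatios(studyExpression(s2)))
  expect_identical(ihcObservations(studyIHC(s1)), ihcObservations(studyIHC(s2)))
  expect_identical(studyClinical(s1), studyClinical(s2))
})

test_that("component seed splitting isolates expression from the marker panel", {
  base <- list(nPatients = 30, genes = c("A", "B"),
               plantedPairs = list(plantedPair("A", "B", "uu", 0.5)), seed = 3)
  s1 <- generateExpression(do.call(cohortSpec, base))
  s2 <- generateExpression(do.call(cohortSpec,
          c(base, list(markerRates = c("TP53(N)" = 0.9)))))
  expect_identical(logRatios(s1), logRatios(s2))
})

test_that("planted pattern fractions land in the exact binomial interval", {
  n <- 83
  lo <- qbinom(0.005, n, 0.31)
  hi <- qbinom(0.995, n, 0.31)
  inside <- 0
  for (seed in 1:40) {
    spec <- cohortSpec(nPatients = n, genes = c("FEN1", "RAD54B"),
                       plantedPairs = list(plantedPair("FEN1", "RAD54B", "uu",
                                                       0.31, 2.0)),
                       noiseSd = 0.1, seed = seed)
    f <- patternFractions(generateExpression(spec), c("FEN1", "RAD54B"))
    k <- round(f[["uu"]] * n)
    if (k >= lo && k <= hi) inside <- inside + 1
  }
  expect_gte(inside, 36)  # 99% interval: expect ~all of 40 seeds inside
})

test_that("zero penetrance leaves pure noise at the expected pattern rate", {
  spec <- cohortSpec(nPatients = 2000, genes = c("A", "B"), noiseSd = 1,
                     plantedPairs = list(plantedPair("A", "B", "uu", 0)),
                     seed = 8)
  f <- patternFractions(generateExpression(spec), c("A", "B"))
  pUp <- pnorm(log2(1.5), sd = 1, lower.tail = FALSE)
  expect_equal(f[["uu"]], pUp^2, tolerance = 0.35)  # binomial noise at n=2000
  expect_lt(abs(f[["uu"]] - pUp^2), 3 * sqrt(pUp^2 * (1 - pUp^2) / 2000))
})

test_that("planting a gene outside the panel is a configuration error", {
  expect_error(cohortSpec(genes = c("A"), nPatients = 10,
                          plantedPairs = list(plantedPair("A", "B", "uu", 0.5))),
               "not in the gene panel")
})

test_that("marker marginal abnormality rates are calibrated", {
  spec <- cohortSpec(nPatients = 500, genes = "A", seed = 21)
  ihc <- generateIHCClinical(spec)$ihc
  ab <- abnormalityMatrix(ihc)
  info <- markerInfo(ihc)
  for (mk in c("RAD54B(N)", "BRCA1(C)", "CDH1(M)", "CTNNB1(N)")) {
    rate <- info$abnormalRate[info$marker == mk]
    k <- sum(ab[, mk])
    expect_gte(k, qbinom(0.005, 500, rate))
    expect_lte(k, qbinom(0.995, 500, rate))
  }
})

test_that("grades are consistent with each marker's criterion after back-mapping", {
  spec <- cohortSpec(nPatients = 200, genes = "A", seed = 5)
  ihc <- generateIHCClinical(spec)$ihc
  obs <- ihcObservations(ihc)
  ab <- abnormalityMatrix(ihc)
  # re-dichotomizing the sampled grades must reproduce the latent flags
  expect_true(all(!is.na(ab)))
  p <- defaultMarkerPanel()
  expect_identical(unname(ab[, "RAD54B(N)"]),
                   dichotomizeMarker(obs[, "RAD54B(N)"], p, "RAD54B(N)"))
})

test_that("zero marginal abnormality empties the exposed margin downstream", {
  spec <- cohortSpec(nPatients = 50, genes = "A", seed = 2,
                     markerRates = setNames(rep(0, 23), markerNames(defaultMarkerPanel())))
  st <- generateIHCClinical(spec)
  ab <- abnormalityMatrix(st$ihc)
  expect_equal(sum(ab), 0)
  adv <- dichotomizeFeature(st$clinical, "metastasis")
  tab <- table(factor(ab[, 1] & ab[, 2], c(FALSE, TRUE)),
               factor(adv, c(FALSE, TRUE)))
  expect_equal(fisherExact2x2(tab), 1.0)  # empty margin convention
})

test_that("interaction-only planting leaves single-marker tests null", {
  ## With an OR planted only on the joint-abnormal state, each single
  ## marker's Fisher p against the feature stays uniform over seeds.
  ps <- numeric(200)
  for (seed in 1:200) {
    spec <- cohortSpec(nPatients = 131, genes = "A", seed = seed,
                       markerRates = c("FEN1(N)" = 0.5, "RAD54B(N)" = 0.5),
                       synergyEffects = list(list(marker1 = "FEN1(N)",
                                                  marker2 = "RAD54B(N)",
                                                  feature = "metastasis",
                                                  oddsRatio = 6)))
    st <- generateIHCClinical(spec)
    ab <- abnormalityMatrix(st$ihc)
    adv <- dichotomizeFeature(st$clinical, "metastasis")
    ## condition on the partner being normal: the single-marker margin is
    ## contaminated by the interaction otherwise; the generator's claim is
    ## that single abnormality alone never moves the feature
    sub <- !ab[, "RAD54B(N)"]
    ps[seed] <- fisherExact2x2(table(factor(ab[sub, "FEN1(N)"], c(FALSE, TRUE)),
                                     factor(adv[sub], c(FALSE, TRUE))))
  }
  ## exact conditional tests are discrete and conservative, so the null
  ## p-values are super-uniform: P(p <= a) must not exceed its binomial bound
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(sum(ps <= a), qbinom(0.995, length(ps), a))
})

test_that("hazard generator recovers a planted hazard ratio", {
  set.seed(10)
  ind <- data.frame(RAD54B = rbinom(800, 1, 0.5))
  spec <- cohortSpec(nPatients = 800, genes = "A",
                     hazardEffects = c(RAD54B = log(2.39)), seed = 31)
  sv <- generateSurvival(spec, ind)
  fit <- coxUnivariate(cbind(sv, ind), "RAD54B")
  expect_gt(fit$hr, 1.8)
  expect_lt(fit$hr, 3.1)
})

test_that("a zero censor window censors everything at time zero", {
  spec <- cohortSpec(nPatients = 20, genes = "A", censorWindow = 0, seed = 1)
  sv <- generateSurvival(spec, data.frame(x = rep(0, 20)))
  expect_true(all(sv$event == 0))
  expect_true(all(sv$time == 0))
  expect_error(coxUnivariate(cbind(sv, x = rbinom(20, 1, 0.5)), "x"), "no events")
})

test_that("written studies round-trip through the pipeline readers", {
  spec <- cohortSpec(nPatients = 25, genes = c("A", "B"),
                     plantedPairs = list(plantedPair("A", "B", "dd", 0.4)),
                     seed = 44)
  st <- generateStudy(spec)
  dir <- withr::local_tempdir()
  writeStudy(st, dir)
  x <- readLogRatioTSV(file.path(dir, "expression.tsv"))
  expect_equal(logRatios(x), logRatios(studyExpression(st)), tolerance = 1e-9)
  panel <- readMarkerPanelTSV(file.path(dir, "panel.tsv"))
  ihc <- readIHCTSV(file.path(dir, "ihc.tsv"), panel)
  expect_identical(ihcObservations(ihc), ihcObservations(studyIHC(st)))
  clin <- readClinicalTSV(file.path(dir, "clinical.tsv"))
  expect_equal(clin$event, studyClinical(st)$event)
})
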