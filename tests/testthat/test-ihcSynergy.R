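test_that("clinical feature dichotomization follows the five rules", {
  clin <- data.frame(
    patient = paste0("P", 1:5),
    survivalMonths = c(20, 20, 40, 36, 10),
    event = c(1, 0, 0, 0, 1),
    grade = c("poor", "well", "moderate", "poor", "well"),
    metastasis = c("yes", "no", "no", "yes", "no"),
    nodal = c("N0", "N1", "N2", "N0", "N1"),
    stage = c("I", "II", "III", "IV", "I"))
  expect_identical(dichotomizeFeature(clin, "survival3y"),
                   c(TRUE, NA, FALSE, FALSE, TRUE))
  expect_identical(dichotomizeFeature(clin, "survival3y",
                                      censoredAsNonAdverse = TRUE),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(dichotomizeFeature(clin, "grade"),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(dichotomizeFeature(clin, "metastasis"),
                   c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(dichotomizeFeature(clin, "nodal"),
                   c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(dichotomizeFeature(clin, "stage"),
                   c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_error(dichotomizeFeature(clin, "smoking"))
})

test_that("pair enumeration excludes same-protein multi-location pairs", {
  panel <- MarkerPanel(data.frame(
    marker = c("A(C)", "A(N)", "B(C)", "C(N)"),
    protein = c("A", "A", "B", "C"),
    location = c("C", "N", "C", "N"),
    kind = "intensity", direction = ">=", threshold = "1+",
    abnormalRate = 0.5))
  pr <- enumeratePairs(panel)
  expect_equal(nrow(pr), 5)  # C(4,2) minus the A(C)-A(N) pair
  expect_false(any(pr$marker1 == "A(C)" & pr$marker2 == "A(N)"))
})

test_that("pair count matches the combinatorial formula on random panels", {
  set.seed(3)
  for (rep in 1:5) {
    nprot <- sample(4:8, 1)
    prots <- LETTERS[1:nprot]
    locs <- lapply(prots, function(p) sample(c("C", "N", "M"),
                                             sample(1:3, 1)))
    df <- do.call(rbind, lapply(seq_along(prots), function(i)
      data.frame(protein = prots[i], location = locs[[i]])))
    df$marker <- paste0(df$protein, "(", df$location, ")")
    df$kind <- "intensity"; df$direction <- ">="; df$threshold <- "1+"
    df$abnormalRate <- 0.5
    panel <- MarkerPanel(df)
    m <- nrow(df)
    k <- table(df$protein)
    expected <- choose(m, 2) - sum(choose(k[k > 1], 2))
    expect_equal(nrow(enumeratePairs(panel)), unname(expected))
    # brute force double check
    brute <- 0
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      if (df$protein[i] != df$protein[j]) brute <- brute + 1
    expect_equal(nrow(enumeratePairs(panel)), brute)
  }
})

test_that("Fisher p matches hand-enumerated values and conventions", {
  expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisherExact2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-10)
  expect_equal(fisherExact2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-10)
  expect_equal(fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1.0)
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)))
})

test_that("Fisher p is invariant under row/column swaps and transpose", {
  set.seed(8)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 6), 2)
    p <- fisherExact2x2(tab)
    expect_equal(fisherExact2x2(tab[2:1, ]), p, tolerance = 1e-9)
    expect_equal(fisherExact2x2(tab[, 2:1]), p, tolerance = 1e-9)
    expect_equal(fisherExact2x2(t(tab)), p, tolerance = 1e-9)
  }
})

test_that("synergy classification partitions the printed example triples", {
  expect_equal(classifySynergy(0.016, 0.442, 0.357), "synergistic")
  expect_equal(classifySynergy(0.003, 0.682, 0.012), "putative")
  expect_equal(classifySynergy(0.2, 0.5, 0.5), "none")
  expect_equal(classifySynergy(0.01, 0.005, 0.5), "none")
  # every triple receives exactly one label
  set.seed(1)
  p <- matrix(runif(300), ncol = 3)
  lab <- classifySynergy(p[, 1], p[, 2], p[, 3])
  expect_true(all(lab %in% c("synergistic", "putative", "none")))
  syn <- p[, 1] < 0.05 & p[, 2] >= 0.05 & p[, 3] >= 0.05
  expect_identical(lab == "synergistic", syn)
})

test_that("a planted interaction-only pair enters the predicted list", {
  found <- 0
  for (seed in 1:10) {
    spec <- cohortSpec(nPatients = 131, genes = "A", seed = seed,
                       markerRates = c("FEN1(N)" = 0.5, "RAD54B(N)" = 0.5),
                       synergyEffects = list(list(marker1 = "FEN1(N)",
                                                  marker2 = "RAD54B(N)",
                                                  feature = "metastasis",
                                                  oddsRatio = 6)))
    st <- generateIHCClinical(spec)
    syn <- synergyScreen(st$ihc, st$clinical)
    hit <- any(syn$predictedPairs$marker1 == "FEN1(N)" &
               syn$predictedPairs$marker2 == "RAD54B(N)")
    found <- found + hit
  }
  expect_gte(found, 8)
})

test_that("null cohorts yield few synergy discoveries", {
  spec <- cohortSpec(nPatients = 131, genes = "A", seed = 12)
  st <- generateIHCClinical(spec)
  syn <- synergyScreen(st$ihc, st$clinical)
  expect_equal(nrow(syn$records), 1250)
  # with no planted effects the flagged fraction is far below the family size
  expect_lt(sum(syn$records$label != "none"), 0.1 * 1250)
  # predicted pairs are deduplicated across features
  expect_false(any(duplicated(syn$predictedPairs)))
  # q-values computed within each feature family
  expect_false(anyNA(syn$records$qPair))
})

test_that("degenerate features warn and record p = 1", {
  spec <- cohortSpec(nPatients = 40, genes = "A", seed = 2,
                     featureRates = c(metastasis = 0))
  st <- generateIHCClinical(spec)
  expect_warning(syn <- synergyScreen(st$ihc, st$clinical), "metastasis")
  met <- syn$records[syn$records$feature == "metastasis", ]
  expect_true(all(met$pPair == 1))
  expect_true(all(met$label == "none"))
})

test_that("2-hop expansion proposes exactly the bridge-completing pairs", {
  expect_equal(twoHopCandidates(data.frame(a = c("PARP1", "BRCA1"),
                                           b = c("BRCA1", "TP53"))),
               data.frame(gene1 = "PARP1", gene2 = "TP53"))
  expect_equal(twoHopCandidates(data.frame(a = c("CSNK1E", "TP53"),
                                           b = c("TP53", "RB1"))),
               data.frame(gene1 = "CSNK1E", gene2 = "RB1"))
  empty <- data.frame(gene1 = character(), gene2 = character())
  expect_equal(twoHopCandidates(empty), empty)
  expect_equal(twoHopCandidates(data.frame(a = "X", b = "Y")), empty)
  # known pairs are never re-proposed; triangles close nothing new
  tri <- data.frame(a = c("A", "B", "A"), b = c("B", "C", "C"))
  expect_equal(nrow(twoHopCandidates(tri)), 0)
  # brute-force cross-check on a random graph
  set.seed(5)
  g <- unique(t(apply(matrix(sample(LETTERS[1:8], 24, TRUE), ncol = 2), 1, sort)))
  g <- g[g[, 1] != g[, 2], , drop = FALSE]
  got <- twoHopCandidates(g)
  known <- paste(g[, 1], g[, 2])
  brute <- character()
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    shared <- intersect(g[i, ], g[j, ])
    if (i != j && length(shared) == 1) {
      ends <- sort(c(setdiff(g[i, ], shared), setdiff(g[j, ], shared)))
      key <- paste(ends[1], ends[2])
      if (!key %in% known && ends[1] != ends[2]) brute <- c(brute, key)
    }
  }
  expect_setequal(paste(got$gene1, got$gene2), unique(brute))
})
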