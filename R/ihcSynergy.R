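#' Dichotomize a clinical feature into adverse / not adverse
#'
#' The five dichotomies are: overall survival shorter than 3 years versus at
#' least 3 years; tumor grade poorly differentiated versus well or moderately
#' differentiated; metastasis yes versus no; lymph-node status N1-N2 versus
#' N0; and stage III-IV versus I-II. For the survival feature, patients
#' censored alive before 36 months are not evaluable and return `NA`
#' (set `censoredAsNonAdverse = TRUE` to count them as not adverse instead).
#'
#' @param clinical data.frame of clinical records (columns `survivalMonths`,
#'   `event`, `grade`, `metastasis`, `nodal`, `stage`).
#' @param feature one of `"survival3y"`, `"grade"`, `"metastasis"`, `"nodal"`,
#'   `"stage"`.
#' @param censoredAsNonAdverse see above.
#' @return logical vector (`TRUE` = adverse, `NA` = not evaluable).
#' @export
dichotomizeFeature <- function(clinical, feature = FEATURES,
                               censoredAsNonAdverse = FALSE) {
  feature <- match.arg(feature)
  clinical <- as.data.frame(clinical)
  out <- switch(feature,
    survival3y = {
      t <- clinical$survivalMonths; e <- clinical$event
      adv <- ifelse(t >= 36, FALSE, ifelse(e == 1, TRUE, NA))
      if (censoredAsNonAdverse) adv[is.na(adv) & !is.na(t)] <- FALSE
      adv
    },
    grade = clinical$grade == "poor",
    metastasis = clinical$metastasis == "yes",
    nodal = clinical$nodal %in% c("N1", "N2"),
    stage = clinical$stage %in% c("III", "IV"))
  as.logical(out)
}

#' Enumerate testable marker pairs of a panel
#'
#' All unordered pairs of distinct markers whose underlying proteins differ
#' (pairs of the same protein stained at different cellular locations are
#' excluded).
#'
#' @param panel a [MarkerPanel].
#' @return data.frame with columns `marker1`, `marker2`.
#' @examples
#' nrow(enumeratePairs(defaultMarkerPanel()))  # 250
#' @export
enumeratePairs <- function(panel) {
  info <- markerInfo(panel)
  if (nrow(info) < 2) return(data.frame(marker1 = character(), marker2 = character()))
  idx <- combn(nrow(info), 2)
  keep <- info$protein[idx[1, ]] != info$protein[idx[2, ]]
  data.frame(marker1 = info$marker[idx[1, keep]],
             marker2 = info$marker[idx[2, keep]],
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' Probability-ordering convention: the p-value sums the hypergeometric
#' probabilities (margins fixed) of all tables at most as probable as the one
#' observed, with a relative tie tolerance of about 1e-7. A table with an
#' empty margin carries no testable association and returns 1 by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisherExact2x2(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1.0)
  min(fisher.test(table)$p.value, 1.0)
}

#' Classify a (pair, feature) test as synergistic, putative or none
#'
#' Synergistic: the pair association is significant (`p_pair < alpha`) while
#' neither single-marker association is. Putative: the pair association is
#' significant and strictly smaller than both single-marker p-values, without
#' being fully synergistic. Everything else is `"none"`.
#'
#' @param pPair,pSingle1,pSingle2 Fisher p-values in (0, 1] (vectorized).
#' @param alpha significance level (default 0.05).
#' @return character vector of labels.
#' @examples
#' classifySynergy(0.016, 0.442, 0.357)  # "synergistic"
#' classifySynergy(0.003, 0.682, 0.012)  # "putative"
#' @export
classifySynergy <- function(pPair, pSingle1, pSingle2, alpha = 0.05) {
  stopifnot(all(c(pPair, pSingle1, pSingle2) > 0),
            all(c(pPair, pSingle1, pSingle2) <= 1))
  syn <- pPair < alpha & pSingle1 >= alpha & pSingle2 >= alpha
  put <- pPair < alpha & pPair < pSingle1 & pPair < pSingle2 & !syn
  ifelse(syn, "synergistic", ifelse(put, "putative", "none"))
}

.count2x2 <- function(exposed, adverse) {
  keep <- !is.na(exposed) & !is.na(adverse)
  matrix(c(sum(exposed[keep] & adverse[keep]), sum(exposed[keep] & !adverse[keep]),
           sum(!exposed[keep] & adverse[keep]), sum(!exposed[keep] & !adverse[keep])),
         2, 2, byrow = TRUE,
         dimnames = list(c("exposed", "other"), c("adverse", "notAdverse")))
}

#' Screen all marker pairs for (putative) synergistic correlation
#'
#' For every enumerated pair and each of the five dichotomized clinical
#' features, builds the pair 2x2 (both markers abnormal versus otherwise, by
#' adverse versus not) and the two single-marker 2x2s, tests each by Fisher's
#' exact test, classifies by [classifySynergy()], attaches q-values of the
#' pair p within each clinical-feature family (or one global family) and the
#' pair log-rank p-value (both-abnormal versus the rest over the full
#' follow-up). Pairs flagged under several features count once in the
#' deduplicated predicted list.
#'
#' @param ihc an [IHCCohort].
#' @param clinical clinical data.frame sharing the IHC patient ids (column
#'   `patient`).
#' @param alpha significance level (default 0.05).
#' @param fdrFamily `"feature"` (default, one q-value family per clinical
#'   feature) or `"global"`.
#' @param fdrMethod passed to [fdrQvalues()].
#' @param censoredAsNonAdverse passed to [dichotomizeFeature()].
#' @return list with `records` (one row per pair x feature: pSingle1,
#'   pSingle2, pPair, qPair, logrankPair, label) and `predictedPairs`
#'   (deduplicated pairs with label != "none").
#' @export
synergyScreen <- function(ihc, clinical, alpha = 0.05,
                          fdrFamily = c("feature", "global"),
                          fdrMethod = "storey", censoredAsNonAdverse = FALSE) {
  fdrFamily <- match.arg(fdrFamily)
  clinical <- as.data.frame(clinical)
  abn <- abnormalityMatrix(ihc)
  stopifnot(identical(rownames(abn), clinical$patient))
  pairs <- enumeratePairs(ihc@panel)

  ## pair log-rank (both-abnormal vs rest) does not depend on the feature
  lrPair <- vapply(seq_len(nrow(pairs)), function(i) {
    both <- abn[, pairs$marker1[i]] & abn[, pairs$marker2[i]]
    if (length(unique(both)) < 2) return(NA_real_)
    logrankP(clinical$survivalMonths, clinical$event, both)[["p"]]
  }, numeric(1))

  recs <- list()
  for (f in FEATURES) {
    adv <- dichotomizeFeature(clinical, f, censoredAsNonAdverse)
    degenerate <- length(unique(adv[!is.na(adv)])) < 2
    if (degenerate)
      warning("feature '", f, "' has no variation among evaluable patients; ",
              "all its p-values are set to 1")
    pSingle <- vapply(colnames(abn), function(mk) {
      if (degenerate) 1.0 else fisherExact2x2(.count2x2(abn[, mk], adv))
    }, numeric(1))
    pPair <- vapply(seq_len(nrow(pairs)), function(i) {
      if (degenerate) return(1.0)
      both <- abn[, pairs$marker1[i]] & abn[, pairs$marker2[i]]
      fisherExact2x2(.count2x2(both, adv))
    }, numeric(1))
    recs[[f]] <- data.frame(
      marker1 = pairs$marker1, marker2 = pairs$marker2, feature = f,
      pSingle1 = unname(pSingle[pairs$marker1]),
      pSingle2 = unname(pSingle[pairs$marker2]),
      pPair = pPair, logrankPair = lrPair, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (fdrFamily == "feature") {
    records$qPair <- NA_real_
    for (f in FEATURES) {
      i <- records$feature == f
      records$qPair[i] <- as.numeric(fdrQvalues(records$pPair[i], method = fdrMethod))
    }
  } else {
    records$qPair <- as.numeric(fdrQvalues(records$pPair, method = fdrMethod))
  }
  records$label <- classifySynergy(records$pPair, records$pSingle1,
                                   records$pSingle2, alpha)
  hits <- records[records$label != "none", c("marker1", "marker2")]
  predicted <- unique(hits)
  predicted <- predicted[order(predicted$marker1, predicted$marker2), , drop = FALSE]
  rownames(predicted) <- NULL
  list(records = records, predictedPairs = predicted)
}

#' Expand known synthetic-lethal pairs by the 2-hop rule
#'
#' If A-B and B-C are known pairs then A-C is proposed, for all A != C with
#' A-C not already known. Output is deterministic: unordered pairs sorted
#' lexicographically.
#'
#' @param knownPairs data.frame with two columns of gene symbols (or a
#'   2-column matrix).
#' @return data.frame with columns `gene1`, `gene2` of proposed pairs.
#' @examples
#' twoHopCandidates(data.frame(a = c("PARP1", "BRCA1"),
#'                             b = c("BRCA1", "TP53")))  # PARP1-TP53
#' @export
twoHopCandidates <- function(knownPairs) {
  kp <- as.matrix(knownPairs)
  empty <- data.frame(gene1 = character(), gene2 = character())
  if (nrow(kp) == 0) return(empty)
  stopifnot(ncol(kp) == 2)
  norm <- function(a, b) paste(pmin(a, b), pmax(a, b))
  known <- unique(norm(kp[, 1], kp[, 2]))
  adj <- split(c(kp[, 2], kp[, 1]), c(kp[, 1], kp[, 2]))
  out <- character()
  for (nb in adj) {
    nb <- unique(nb)
    if (length(nb) >= 2) {
      cmb <- combn(sort(nb), 2)
      out <- c(out, norm(cmb[1, ], cmb[2, ]))
    }
  }
  out <- sort(setdiff(unique(out), known))
  if (!length(out)) return(empty)
  parts <- do.call(rbind, strsplit(out, " ", fixed = TRUE))
  data.frame(gene1 = parts[, 1], gene2 = parts[, 2], stringsAsFactors = FALSE)
}
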