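#' Compute per-patient tumor/normal log2-ratios
#'
#' @param tumor,normal numeric matrices of strictly positive expression values
#'   with identical gene (row) and patient (column) indexing.
#' @return a [PairedExpression] with `logRatio = log2(tumor) - log2(normal)`.
#' @examples
#' t <- matrix(3,  1, 1, dimnames = list("FEN1", "P1"))
#' n <- matrix(1.5, 1, 1, dimnames = list("FEN1", "P1"))
#' logRatios(computeLogRatios(t, n))  # 1
#' @export
computeLogRatios <- function(tumor, normal) {
  tumor <- as.matrix(tumor); normal <- as.matrix(normal)
  if (!identical(dimnames(tumor), dimnames(normal)) ||
      !identical(dim(tumor), dim(normal)))
    stop("tumor and normal matrices must share the same gene/patient indexing")
  bad <- which(tumor <= 0 | normal <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive expression value for gene ", rownames(tumor)[bad[1, 1]],
         ", patient ", colnames(tumor)[bad[1, 2]])
  }
  PairedExpression(log2(tumor) - log2(normal))
}

## Up/down calls at a fold cutoff; the half-open "neither" zone
## [1/cutoff, cutoff) maps to neither up nor down.
.patternCalls <- function(lr, foldCutoff) {
  t <- log2(foldCutoff)
  list(up = lr >= t, down = lr <= -t)
}

.extractPairRatios <- function(x, pair) {
  lr <- logRatios(x)
  miss <- setdiff(pair, rownames(lr))
  if (length(miss)) stop("gene(s) not in the expression panel: ",
                         paste(miss, collapse = ", "))
  g1 <- lr[pair[1], ]; g2 <- lr[pair[2], ]
  keep <- !is.na(g1) & !is.na(g2)   # pairwise-complete patients
  list(g1 = g1[keep], g2 = g2[keep], n = sum(keep))
}

#' Fractions of the four co-differential-expression patterns for a gene pair
#'
#' A patient is "up" for a gene iff its log2-ratio is at least
#' `log2(foldCutoff)` and "down" iff at most `-log2(foldCutoff)`. Each patient
#' contributes to at most one of the (up,up), (up,down), (down,up), (down,down)
#' patterns; patients with either gene in the neither zone contribute to none,
#' so the four fractions need not sum to 1.
#'
#' @param x a [PairedExpression] or log2-ratio matrix (genes x patients).
#' @param pair character vector of two gene symbols.
#' @param foldCutoff fold-change cutoff for up/down regulation (default 1.5).
#' @return named numeric vector `c(uu, ud, du, dd)` of pattern fractions, with
#'   attributes `n` (patients used) and `pair`.
#' @export
patternFractions <- function(x, pair, foldCutoff = 1.5) {
  stopifnot(length(pair) == 2, foldCutoff > 1)
  d <- .extractPairRatios(x, pair)
  if (d$n == 0) stop("no pairwise-complete patients for ", paste(pair, collapse = "-"))
  c1 <- .patternCalls(d$g1, foldCutoff)
  c2 <- .patternCalls(d$g2, foldCutoff)
  out <- c(uu = sum(c1$up & c2$up), ud = sum(c1$up & c2$down),
           du = sum(c1$down & c2$up), dd = sum(c1$down & c2$down)) / d$n
  attr(out, "n") <- d$n
  attr(out, "pair") <- pair
  out
}

## Pattern counts for a set of sign-flip assignments.
## signs: matrix (n_assignments x n_patients) of +/-1; returns counts matrix
## (n_assignments x 4). A flip exchanges a patient's tumor/normal labels,
## negating that patient's log-ratios for BOTH genes jointly.
.flipPatternCounts <- function(signs, g1, g2, foldCutoff) {
  t <- log2(foldCutoff)
  x1 <- sweep(signs, 2, g1, `*`)
  x2 <- sweep(signs, 2, g2, `*`)
  up1 <- x1 >= t; dn1 <- x1 <= -t
  up2 <- x2 >= t; dn2 <- x2 <= -t
  cbind(uu = rowSums(up1 & up2), ud = rowSums(up1 & dn2),
        du = rowSums(dn1 & up2), dd = rowSums(dn1 & dn2))
}

.allSignAssignments <- function(n) {
  as.matrix(expand.grid(rep(list(c(1, -1)), n), KEEP.OUT.ATTRS = FALSE))
}

#' Label-exchange permutation p-value for a pattern fraction
#'
#' Each permutation independently exchanges, per patient, the tumor and normal
#' tissue labels with probability 1/2; an exchange negates that patient's
#' log-ratios for both genes of the pair jointly. The statistic is the fraction
#' of the target pattern and the p-value is `(1 + #\{permuted >= observed\}) /
#' (1 + nPerm)` (add-one convention, so p > 0; set `addOne = FALSE` for the raw
#' `c/N` estimate). When `2^n <= nPerm` the full set of `2^n` sign assignments
#' is enumerated instead and the p-value is the exact tail fraction
#' `#\{assignments >= observed\} / 2^n` (the identity assignment guarantees
#' p > 0).
#'
#' @inheritParams patternFractions
#' @param pattern one of `"uu"`, `"ud"`, `"du"`, `"dd"`.
#' @param nPerm number of label exchanges (default 10000).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default `NULL` enumerates automatically when `2^n <= nPerm`.
#' @param addOne use the add-one p-value convention in Monte-Carlo mode.
#' @return p-value in (0, 1], with attributes `observed` (fraction) and
#'   `exhaustive`.
#' @export
permutationPvalue <- function(x, pair, pattern = c("uu", "ud", "du", "dd"),
                              foldCutoff = 1.5, nPerm = 10000, seed = NULL,
                              exhaustive = NULL, addOne = TRUE) {
  pattern <- match.arg(pattern)
  p <- permutationPvalues(x, pair, foldCutoff = foldCutoff, nPerm = nPerm,
                          seed = seed, exhaustive = exhaustive, addOne = addOne)
  out <- p$p[[pattern]]
  attr(out, "observed") <- p$observed[[pattern]]
  attr(out, "exhaustive") <- p$exhaustive
  out
}

#' Permutation p-values of all four patterns for one gene pair
#'
#' Same null as [permutationPvalue()], sharing a single set of label exchanges
#' across the four pattern statistics.
#'
#' @inheritParams permutationPvalue
#' @return list with `observed` (4 fractions), `p` (4 p-values), `n`,
#'   `exhaustive`.
#' @export
permutationPvalues <- function(x, pair, foldCutoff = 1.5, nPerm = 10000,
                               seed = NULL, exhaustive = NULL, addOne = TRUE) {
  stopifnot(nPerm >= 1)
  d <- .extractPairRatios(x, pair)
  if (d$n == 0) stop("no pairwise-complete patients for ", paste(pair, collapse = "-"))
  obsCounts <- .flipPatternCounts(matrix(1, 1, d$n), d$g1, d$g2, foldCutoff)[1, ]
  if (is.null(exhaustive)) exhaustive <- (2^d$n <= nPerm)
  if (exhaustive) {
    signs <- .allSignAssignments(d$n)
    counts <- .flipPatternCounts(signs, d$g1, d$g2, foldCutoff)
    p <- vapply(names(obsCounts),
                function(k) sum(counts[, k] >= obsCounts[[k]]) / nrow(signs),
                numeric(1))
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(1, -1), nPerm * d$n, replace = TRUE), nPerm, d$n)
    counts <- .flipPatternCounts(signs, d$g1, d$g2, foldCutoff)
    p <- vapply(names(obsCounts), function(k) {
      c_ <- sum(counts[, k] >= obsCounts[[k]])
      if (addOne) (1 + c_) / (1 + nPerm) else c_ / nPerm
    }, numeric(1))
  }
  list(observed = obsCounts / d$n, p = p, n = d$n, exhaustive = exhaustive)
}

#' q-values for a family of p-values (Storey or Benjamini-Hochberg)
#'
#' Storey mode estimates the null proportion pi0 on the lambda grid
#' 0.05, 0.10, ..., 0.95 as `#\{p > lambda\} / (m (1 - lambda))`, smooths with a
#' cubic smoothing spline (df = 3) and evaluates at the largest lambda,
#' clipping to (0, 1]. q-values are the step-up
#' `pi0 * min_\{p_j >= p_i\} (m p_j / rank_j)` clipped to [0, 1]; BH mode fixes
#' pi0 at 1.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param method `"storey"` (default) or `"bh"`.
#' @return numeric vector of q-values, with attribute `pi0`.
#' @export
fdrQvalues <- function(pvalues, method = c("storey", "bh")) {
  method <- match.arg(method)
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  pi0 <- 1
  if (method == "storey" && m >= 2) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  o <- order(p, decreasing = TRUE)  # largest p first
  ro <- order(o)
  ranks <- m:1                      # rank of the sorted-descending p's
  q <- pmin(pi0 * m * p[o] / ranks, 1)
  q <- cummin(q)                    # enforce monotonicity (step-up minimum)
  out <- q[ro]
  attr(out, "pi0") <- pi0
  out
}

#' Screen candidate gene pairs by co-differential-expression patterns
#'
#' For every pair in `pairs`, computes the four pattern fractions, their
#' permutation p-values (one shared set of label exchanges per pair) and
#' q-values over the family of all tested (pair, pattern) hypotheses.
#'
#' @inheritParams permutationPvalue
#' @param pairs data.frame with columns `gene1`, `gene2` (extra columns such as
#'   `source` are carried through).
#' @param fdrMethod passed to [fdrQvalues()].
#' @param minFraction inclusion rule: a pair is flagged `included` when its
#'   largest pattern fraction exceeds this value (default 0.01).
#' @return data.frame with one row per (pair, pattern): observed fraction,
#'   permutation p, q, `included`, and the candidate `rank` of the pair
#'   (NA for excluded pairs); ordered as [selectCandidates()] ranks them.
#' @export
screenExpression <- function(x, pairs, foldCutoff = 1.5, nPerm = 10000,
                             seed = NULL, fdrMethod = "storey",
                             minFraction = 0.01) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("gene1", "gene2") %in% names(pairs)), nrow(pairs) >= 1)
  if (!is.null(seed)) set.seed(seed)
  pairSeeds <- sample.int(.Machine$integer.max - 1L, nrow(pairs))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- c(pairs$gene1[i], pairs$gene2[i])
    pp <- permutationPvalues(x, pr, foldCutoff = foldCutoff, nPerm = nPerm,
                             seed = pairSeeds[i])
    data.frame(gene1 = pr[1], gene2 = pr[2],
               pattern = c("uu", "ud", "du", "dd"),
               fraction = as.numeric(pp$observed),
               p = as.numeric(pp$p), n = pp$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- as.numeric(fdrQvalues(res$p, method = fdrMethod))
  sel <- selectCandidates(res, minFraction = minFraction)
  key <- paste(res$gene1, res$gene2)
  res$included <- key %in% paste(sel$gene1, sel$gene2)
  res$rank <- sel$rank[match(key, paste(sel$gene1, sel$gene2))]
  res[order(ifelse(is.na(res$rank), Inf, res$rank), res$gene1, res$gene2), ]
}

#' Select and rank candidate pairs from screen results
#'
#' Keeps pairs whose largest pattern fraction exceeds `minFraction` and sorts
#' them in decreasing lexicographic order of the (up,up), (up,down), (down,up),
#' then (down,down) fractions; remaining ties break by gene-symbol order.
#'
#' @param results data.frame in the long format of [screenExpression()]
#'   (columns `gene1`, `gene2`, `pattern`, `fraction`), or a wide data.frame
#'   with columns `gene1`, `gene2`, `uu`, `ud`, `du`, `dd`.
#' @param minFraction inclusion threshold on the maximum pattern fraction.
#' @return data.frame of kept pairs with their four fractions and `rank`.
#' @export
selectCandidates <- function(results, minFraction = 0.01) {
  results <- as.data.frame(results)
  if ("pattern" %in% names(results)) {
    wide <- stats::reshape(results[, c("gene1", "gene2", "pattern", "fraction")],
                           idvar = c("gene1", "gene2"), timevar = "pattern",
                           direction = "wide")
    names(wide) <- sub("^fraction\\.", "", names(wide))
  } else wide <- results
  stopifnot(all(c("uu", "ud", "du", "dd") %in% names(wide)))
  keep <- pmax(wide$uu, wide$ud, wide$du, wide$dd) > minFraction
  wide <- wide[keep, , drop = FALSE]
  o <- order(-wide$uu, -wide$ud, -wide$du, -wide$dd, wide$gene1, wide$gene2)
  wide <- wide[o, , drop = FALSE]
  wide$rank <- seq_len(nrow(wide))
  rownames(wide) <- NULL
  wide
}
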