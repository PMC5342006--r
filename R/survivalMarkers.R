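#' @importFrom survival Surv survfit survdiff coxph
NULL

.checkSurvival <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
}

#' Kaplan-Meier product-limit curves per group
#'
#' @param times follow-up times (months).
#' @param events 0/1 event indicators.
#' @param groups group labels (one group if omitted).
#' @return data.frame with columns `group`, `time`, `surv`, `nRisk`, `nEvent`:
#'   the step-curve support points (event and censoring times). Curves start
#'   at 1 and step down only at event times; a group with no events stays
#'   flat at 1.
#' @export
kmEstimate <- function(times, events, groups = NULL) {
  .checkSurvival(times, events)
  if (is.null(groups)) groups <- rep("all", length(times))
  stopifnot(length(groups) == length(times), !anyNA(groups))
  d <- data.frame(time = times, event = events, group = as.character(groups))
  out <- lapply(split(d, d$group), function(g) {
    fit <- survfit(Surv(time, event) ~ 1, data = g)
    data.frame(group = g$group[1], time = fit$time, surv = fit$surv,
               nRisk = fit$n.risk, nEvent = fit$n.event)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mantel-Haenszel log-rank test between survival curves
#'
#' Chi-square statistic in the sum (O - E)^2 form with hypergeometric
#' variance; p-value from a chi-square distribution with k - 1 degrees of
#' freedom for k groups.
#'
#' @inheritParams kmEstimate
#' @param groups labels defining at least two non-empty groups.
#' @return named vector `c(chisq, p)`.
#' @export
logrankP <- function(times, events, groups) {
  .checkSurvival(times, events)
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) < 2) stop("log-rank test needs at least two non-empty groups")
  fit <- survdiff(Surv(times, events) ~ g)
  df <- length(fit$n) - 1
  c(chisq = unname(fit$chisq), p = pchisq(fit$chisq, df, lower.tail = FALSE))
}

.coxSummaryRow <- function(fit, conf = 0.95) {
  s <- summary(fit, conf.int = conf)
  data.frame(variable = rownames(s$coefficients),
             coef = s$coefficients[, "coef"],
             hr = s$conf.int[, "exp(coef)"],
             ciLow = s$conf.int[, 3],
             ciHigh = s$conf.int[, 4],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate Cox proportional-hazards fit for one variable
#'
#' Partial-likelihood fit with the Efron tie approximation; reports the hazard
#' ratio, 95% confidence interval and Wald p-value.
#'
#' @param data data.frame with columns `time`, `event` and the variable.
#' @param variable column name of the covariate (must vary).
#' @return data.frame with one row (`variable`, `coef`, `hr`, `ciLow`,
#'   `ciHigh`, `p`) plus attribute `fit` (the `coxph` object).
#' @export
coxUnivariate <- function(data, variable) {
  data <- as.data.frame(data)
  .checkSurvival(data$time, data$event)
  if (sum(data$event) == 0) stop("no events in the data; cannot fit a hazard model")
  v <- data[[variable]]
  if (is.null(v)) stop("unknown variable: ", variable)
  if (length(unique(v)) < 2) stop("variable '", variable, "' is constant")
  fit <- coxph(stats::reformulate(variable, response = "Surv(time, event)"),
               data = data, ties = "efron")
  out <- .coxSummaryRow(fit)
  attr(out, "fit") <- fit
  out
}

.coxAIC <- function(vars, data) {
  if (length(vars) == 0) {
    fit <- coxph(Surv(time, event) ~ 1, data = data)
    ## null model: no parameters; AIC = -2 * null partial log-likelihood
    return(list(fit = fit, aic = -2 * fit$loglik[1]))
  }
  fit <- coxph(stats::reformulate(vars, response = "Surv(time, event)"),
               data = data, ties = "efron")
  list(fit = fit, aic = -2 * fit$loglik[2] + 2 * length(coef(fit)))
}

#' Bidirectional stepwise-AIC multivariate Cox regression
#'
#' Starts from the full candidate model and repeatedly applies whichever
#' single-variable drop or add most reduces the AIC of the partial-likelihood
#' fit, until no move reduces it.
#'
#' @param data data.frame with `time`, `event` and candidate columns.
#' @param candidates character vector of candidate variable names.
#' @return list with `fit` (the final `coxph`), `selected` (variable names),
#'   `aic`, `table` (per-variable HR summary) and `trace` (data.frame of the
#'   moves taken).
#' @export
coxStepwise <- function(data, candidates) {
  data <- as.data.frame(data)
  .checkSurvival(data$time, data$event)
  if (sum(data$event) == 0) stop("no events in the data; cannot fit a hazard model")
  candidates <- unique(candidates)
  varying <- vapply(candidates, function(v) length(unique(data[[v]])) >= 2, logical(1))
  candidates <- candidates[varying]
  current <- candidates
  cur <- .coxSummaryTry(current, data)
  trace <- data.frame(step = 0L, move = "start",
                      variable = paste(current, collapse = "+"),
                      aic = cur$aic, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    moves <- list()
    for (v in current)
      moves[[paste0("- ", v)]] <- setdiff(current, v)
    for (v in setdiff(candidates, current))
      moves[[paste0("+ ", v)]] <- c(current, v)
    if (!length(moves)) break
    aics <- vapply(moves, function(vars) .coxSummaryTry(vars, data)$aic, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= cur$aic - 1e-10) break
    step <- step + 1L
    current <- moves[[best]]
    cur <- .coxSummaryTry(current, data)
    trace <- rbind(trace, data.frame(step = step, move = names(moves)[best],
                                     variable = paste(current, collapse = "+"),
                                     aic = cur$aic))
  }
  tab <- if (length(current)) .coxSummaryRow(cur$fit) else
    data.frame(variable = character(), coef = numeric(), hr = numeric(),
               ciLow = numeric(), ciHigh = numeric(), p = numeric())
  list(fit = cur$fit, selected = current, aic = cur$aic, table = tab, trace = trace)
}

.coxSummaryTry <- function(vars, data) {
  res <- try(.coxAIC(vars, data), silent = TRUE)
  if (inherits(res, "try-error"))
    stop("Cox fit failed for candidate set {", paste(vars, collapse = ", "), "}: ",
         attr(res, "condition")$message)
  res
}

#' Variance inflation factors of an indicator matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression (with intercept) of column j on the other columns. Perfectly
#' collinear columns report `Inf`.
#'
#' @param x numeric matrix or data.frame with at least two columns and more
#'   rows than columns.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vifScores <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, nrow(x) > ncol(x))
  vapply(seq_len(ncol(x)), function(j) {
    fit <- lm(x[, j] ~ x[, -j, drop = FALSE])
    ## lm warns on an essentially perfect fit; that case is reported as Inf
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(x))
}

#' Build an expression-based marker rule
#'
#' Describes a one- or two-gene fold-change rule such as "2-fold
#' over-expression of RAD54B" or the pair rule "FEN1 up and RAD54B up": a
#' subject is flagged iff every gene passes its directional fold cutoff.
#'
#' @param genes one or two gene symbols.
#' @param directions `"up"` or `"down"` per gene.
#' @param foldCutoff fold cutoff per gene (recycled; default 2), boundary
#'   inclusive; per-gene overrides (e.g. a laxer cutoff for one gene in one
#'   cohort) are given positionally.
#' @param reference `"matched-normal"` (values are already log2 tumor/normal
#'   ratios) or `"cohort-median"` (flag against the per-gene cohort median).
#' @return an `expressionMarkerRule` list.
#' @export
expressionMarkerRule <- function(genes, directions = rep("up", length(genes)),
                                 foldCutoff = 2.0,
                                 reference = c("matched-normal", "cohort-median")) {
  reference <- match.arg(reference)
  directions <- match.arg(directions, c("up", "down"), several.ok = TRUE)
  foldCutoff <- rep_len(foldCutoff, length(genes))
  stopifnot(length(directions) == length(genes), all(foldCutoff > 1))
  structure(list(genes = genes, directions = directions,
                 foldCutoff = foldCutoff, reference = reference),
            class = "expressionMarkerRule")
}

#' Apply an expression marker rule to a cohort
#'
#' A subject is flagged iff every gene in the rule passes its directional
#' fold cutoff: "up" needs `log2 ratio >= log2(cutoff)`, "down" needs
#' `log2 ratio <= -log2(cutoff)` (fold at most `1/cutoff`). With
#' `reference = "cohort-median"` the per-gene cohort median of `expression`
#' is subtracted first; with `reference = "matched-normal"` the values are
#' taken as log2 tumor/normal ratios as-is.
#'
#' @param expression a [PairedExpression], or a numeric matrix of log2 values
#'   (genes x subjects).
#' @param rule an [expressionMarkerRule()].
#' @return logical vector, one flag per subject.
#' @export
expressionMarkerIndicator <- function(expression, rule) {
  stopifnot(inherits(rule, "expressionMarkerRule"))
  if (rule$reference == "matched-normal" && is.null(expression))
    stop("reference 'matched-normal' requires paired log-ratio data")
  lr <- logRatios(expression)
  miss <- setdiff(rule$genes, rownames(lr))
  if (length(miss)) stop("rule gene(s) not in the expression data: ",
                         paste(miss, collapse = ", "))
  lr <- lr[rule$genes, , drop = FALSE]
  if (rule$reference == "cohort-median")
    lr <- sweep(lr, 1, apply(lr, 1, median, na.rm = TRUE))
  pass <- matrix(NA, ncol(lr), length(rule$genes))
  for (i in seq_along(rule$genes)) {
    t <- log2(rule$foldCutoff[i])
    pass[, i] <- if (rule$directions[i] == "up") lr[i, ] >= t else lr[i, ] <= -t
  }
  flags <- apply(pass, 1, all)
  names(flags) <- colnames(lr)
  flags
}
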