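#' Train a proportional-hazards marker risk model
#'
#' Fits a multivariate Cox regression of survival on one or more binary
#' marker indicators, optionally with age and stage covariates, and stores
#' the coefficients so risk scores can be transferred to validation cohorts
#' sharing the same design variables.
#'
#' @param training data.frame with columns `time`, `event`, the marker
#'   indicator columns and (if `withCovariates`) `age65` and `stageHigh`.
#' @param markers character vector of marker indicator column names.
#' @param withCovariates add `age65` and `stageHigh` to the design.
#' @param training_id label recorded in the model.
#' @return a [RiskModel].
#' @export
fitRiskModel <- function(training, markers, withCovariates = FALSE,
                         training_id = "training") {
  training <- as.data.frame(training)
  .checkSurvival(training$time, training$event)
  if (sum(training$event) == 0) stop("training cohort has no events")
  design <- c(markers, if (withCovariates) c("age65", "stageHigh"))
  miss <- setdiff(design, names(training))
  if (length(miss)) stop("training cohort lacks design variable(s): ",
                         paste(miss, collapse = ", "))
  for (v in design)
    if (length(unique(training[[v]])) < 2)
      stop("design variable '", v, "' is constant in the training cohort")
  fit <- coxph(stats::reformulate(design, response = "Surv(time, event)"),
               data = training, ties = "efron")
  new("RiskModel", coefficients = setNames(as.numeric(coef(fit)), design),
      design = design, withCovariates = withCovariates,
      training = training_id, fit = fit)
}

#' Predict per-subject risk scores from a fitted risk model
#'
#' The score is the linear predictor `sum(beta * x)` over the model's design
#' variables; deterministic.
#'
#' @param model a [RiskModel].
#' @param cohort data.frame providing every design variable.
#' @return numeric vector of risk scores.
#' @export
predictRisk <- function(model, cohort) {
  stopifnot(is(model, "RiskModel"))
  cohort <- as.data.frame(cohort)
  miss <- setdiff(model@design, names(cohort))
  if (length(miss)) stop("validation cohort lacks design variable(s): ",
                         paste(miss, collapse = ", "))
  x <- as.matrix(cohort[model@design])
  as.numeric(x %*% model@coefficients)
}

#' Gonen-Heller concordance probability estimate
#'
#' The model-based concordance of proportional-hazards risk scores:
#' `K = 2/(n(n-1)) * sum_\{i<j\} [ I(s_i >= s_j)/(1+exp(s_j-s_i)) +
#' I(s_j > s_i)/(1+exp(s_i-s_j)) ]`. Being a function of the linear-predictor
#' scores alone it is unaffected by censoring. Values near 1 indicate good
#' predictivity, 0.5 none (all-equal scores give exactly 0.5).
#'
#' @param scores numeric vector of linear-predictor risk scores (n >= 2).
#' @param validation ignored; accepted so the call mirrors [evaluateRisk()].
#' @return the estimate, a number in \[0.5-ish, 1).
#' @examples
#' cpe(c(0, log(2)))  # one pair: 1/(1 + exp(-log(2))) = 2/3
#' @export
cpe <- function(scores, validation = NULL) {
  s <- as.numeric(scores)
  n <- length(s)
  if (n < 2) stop("the concordance probability estimate needs at least 2 subjects")
  d <- outer(s, s, `-`)              # d[i, j] = s_i - s_j
  contrib <- ifelse(d >= 0, 1 / (1 + exp(-d)), 0) +
             ifelse(d < 0, 1 / (1 + exp(d)), 0)
  tot <- sum(contrib[upper.tri(contrib) | lower.tri(contrib)]) / 2
  ## each unordered pair contributes once; both orientations of d carry the
  ## same value so averaging over the full off-diagonal halves correctly
  2 / (n * (n - 1)) * tot
}

#' Evaluate transferred risk scores on a validation cohort
#'
#' Reports the hazard ratio (with 95% CI and Wald p) of the continuous risk
#' score from a univariate proportional-hazards fit, the Gonen-Heller
#' concordance probability estimate of the scores, and Kaplan-Meier curves of
#' the high/low risk groups from a median split of the scores (ties to the
#' low-risk group). Constant scores make the evaluation not applicable
#' (`applicable = FALSE`, all estimates `NA`).
#'
#' @param scores numeric risk scores from [predictRisk()].
#' @param validation data.frame with columns `time` and `event`.
#' @return list with `applicable`, `hr`, `ciLow`, `ciHigh`, `p`, `cpe`, `km`
#'   (the [kmEstimate()] table of the two risk groups) and `logrank` (high
#'   versus low risk).
#' @export
evaluateRisk <- function(scores, validation) {
  validation <- as.data.frame(validation)
  .checkSurvival(validation$time, validation$event)
  stopifnot(length(scores) == nrow(validation))
  if (length(unique(scores)) < 2) {
    return(list(applicable = FALSE, hr = NA_real_, ciLow = NA_real_,
                ciHigh = NA_real_, p = NA_real_, cpe = NA_real_,
                km = NULL, logrank = NA_real_))
  }
  d <- data.frame(time = validation$time, event = validation$event, score = scores)
  fit <- coxph(Surv(time, event) ~ score, data = d, ties = "efron")
  s <- .coxSummaryRow(fit)
  grp <- ifelse(scores > median(scores), "high", "low")
  lr <- if (length(unique(grp)) == 2)
    unname(logrankP(d$time, d$event, grp)["p"]) else NA_real_
  list(applicable = TRUE, hr = s$hr, ciLow = s$ciLow, ciHigh = s$ciHigh,
       p = s$p, cpe = cpe(scores),
       km = kmEstimate(d$time, d$event, grp), logrank = lr)
}
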