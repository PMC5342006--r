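#' @importFrom stats rnorm runif rexp rbinom plogis qlogis setNames
#'   fisher.test smooth.spline predict pchisq lm coef median
#' @importFrom utils read.delim write.table combn head
NULL

## Ordinal IHC staining-intensity scale, weakest to strongest.
GRADE_LEVELS <- c("0", "\u00b1", "1+", "2+", "3+")

FEATURES <- c("survival3y", "grade", "metastasis", "nodal", "stage")

gradeRank <- function(grade) {
  r <- match(grade, GRADE_LEVELS)
  if (anyNA(r) && !anyNA(grade)) {
    bad <- unique(grade[is.na(r) & !is.na(grade)])
    stop("unknown IHC grade symbol(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(GRADE_LEVELS, collapse = " "), ")")
  }
  r
}

#' Derive per-component RNG seeds from one study seed
#'
#' One global stream is split into fixed, labelled sub-streams so that adding
#' markers or survival settings never perturbs the expression draws.
#'
#' @param seed integer study seed.
#' @return named integer vector of component seeds.
#' @keywords internal
componentSeeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("expression", "ihc", "clinical", "survival")
  s
}

patientIds <- function(n) sprintf("P%03d", seq_len(n))
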