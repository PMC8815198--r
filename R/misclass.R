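## Closed-form genotype misclassification model with Monte-Carlo cross-check.
##
## Within a phenotype group, let fTrue be the true frequency of e4/4
## carriers, p1 the probability of calling a non-carrier e4/4 (type I) and
## p2 the probability of calling a carrier non-e4/4 (type II). Then the
## observed carrier frequency is
##     f_obs = fTrue * (1 - p2) + (1 - fTrue) * p1
## and the concordance between observed and true carrier status — the
## probability that an observed carrier really is one — is
##     fTrue * (1 - p2) / f_obs.
## Because f_obs is far smaller in controls than in cases, the same error
## rates dilute the observed control carriers much more: observed e4/4
## controls are less likely than observed e4/4 cases to truly be e4/4.

#' Construct a misclassification model
#'
#' @param fTrue true carrier frequency (or frequencies) in (0, 1).
#' @param p1 type-I rate: non-carrier called carrier.
#' @param p2 type-II rate: carrier called non-carrier.
#' @return a [MisclassModel-class] object. Slots recycle, so a vector of
#'   `fTrue` against scalar error rates is fine.
#' @export
#' @examples
#' m <- misclassModel(fTrue = c(0.019, 0.129), p1 = 0.01, p2 = 0.01)
#' observedFrequency(m)
#' concordanceObservedTrue(m)
misclassModel <- function(fTrue, p1 = 0, p2 = 0) {
  new("MisclassModel", fTrue = as.numeric(fTrue), p1 = as.numeric(p1),
      p2 = as.numeric(p2))
}

.fObs <- function(fTrue, p1, p2) fTrue * (1 - p2) + (1 - fTrue) * p1

#' @describeIn observedFrequency `fTrue*(1-p2) + (1-fTrue)*p1`.
#' @export
setMethod("observedFrequency", "MisclassModel", function(object) {
  .fObs(object@fTrue, object@p1, object@p2)
})

#' @describeIn concordanceObservedTrue `fTrue*(1-p2) / f_obs`; errors with
#'   `DIVIDE_BY_ZERO` when `f_obs` is 0 (only possible when `p1 = 0` and
#'   `p2 = 1`).
#' @export
setMethod("concordanceObservedTrue", "MisclassModel", function(object) {
  fo <- observedFrequency(object)
  if (any(fo == 0))
    stop("DIVIDE_BY_ZERO: observed frequency is zero", call. = FALSE)
  object@fTrue * (1 - object@p2) / fo
})

#' @describeIn monteCarloConcordance Simulate `n` subjects with true status
#'   Bernoulli(`fTrue`), flip per `p1`/`p2`, and return the empirical
#'   probability that an observed carrier is a true carrier. Scalar model
#'   only. Returns `NA` when no observed carriers arise.
#' @param n number of simulated subjects.
#' @param seed optional integer seed.
#' @export
setMethod("monteCarloConcordance", "MisclassModel",
          function(object, n = 1e6, seed = NULL, ...) {
  stopifnot(n >= 1,
            length(object@fTrue) == 1L, length(object@p1) == 1L,
            length(object@p2) == 1L)
  if (!is.null(seed)) set.seed(seed)
  truth <- rbinom(n, 1L, object@fTrue)
  obs <- integer(n)
  obs[truth == 1L] <- rbinom(sum(truth), 1L, 1 - object@p2)
  obs[truth == 0L] <- rbinom(sum(truth == 0L), 1L, object@p1)
  if (!any(obs == 1L)) return(NA_real_)  # NO_OBSERVED_CARRIERS
  mean(truth[obs == 1L])
})

setMethod("show", "MisclassModel", function(object) {
  k <- max(lengths(list(object@fTrue, object@p1, object@p2)))
  cat(sprintf("MisclassModel (%d point%s)\n", k, if (k > 1) "s" else ""))
  df <- data.frame(fTrue = object@fTrue, p1 = object@p1, p2 = object@p2,
                   fObs = observedFrequency(object),
                   concordance = concordanceObservedTrue(object))
  print(head(df, 10), digits = 4)
  if (k > 10) cat("  ...\n")
  invisible(NULL)
})

#' Concordance over a grid of error rates and true frequencies
#'
#' Evaluates the closed-form observed frequency and observed-vs-true
#' concordance at every combination of `fTrue`, `p1` and `p2`. The default
#' error grid spans 0–5%; the default `fTrue` values bracket typical
#' case-control observations for a rare risk genotype (about 1.9% of
#' controls and 12.9% of cases being e4/4).
#'
#' @param fTrue numeric vector of true carrier frequencies.
#' @param p1,p2 numeric vectors of error rates.
#' @param labels optional names for the `fTrue` values (e.g. `"control"`,
#'   `"case"`).
#' @return data.table with columns `group`, `fTrue`, `p1`, `p2`, `fObs`,
#'   `concordance`.
#' @export
sweepGrid <- function(fTrue = c(control = 0.019, case = 0.129),
                      p1 = seq(0, 0.05, by = 0.01),
                      p2 = seq(0, 0.05, by = 0.01),
                      labels = names(fTrue)) {
  stopifnot(length(fTrue) >= 1, length(p1) >= 1, length(p2) >= 1)
  if (is.null(labels)) labels <- sprintf("f%0.3f", fTrue)
  g <- CJ(group = labels, p1 = p1, p2 = p2, sorted = FALSE)
  g[, fTrue := fTrue[match(group, labels)]]
  g[, fObs := .fObs(fTrue, p1, p2)]
  g[, concordance := ifelse(fObs > 0, fTrue * (1 - p2) / fObs, NA_real_)]
  setcolorder(g, c("group", "fTrue", "p1", "p2", "fObs", "concordance"))
  g[]
}
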