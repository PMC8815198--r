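## S4 containers for the pipeline.

.SAMPLE_COLS <- c("sample_id", "subject_id", "cohort", "dx", "age", "sex",
                  paste0("PC", 1:5), "provided_apoe")
.EXCLUSION_LEVELS <- c("NONE", "DUP_DISCORDANT_PROVIDED", "WGS_WES_DISCORDANT",
                       "NO_APOE", "WES_CONTRADICTED",
                       "APPROACH2_IMPUTED_DISCORDANT", "NEW_SEQ_DISCORDANT",
                       "AGE_FILTER", "DX_FILTER")

#' ApoeCohort: a multi-source APOE genotyping cohort
#'
#' Holds the per-sample observations (one row per emitted sample, possibly
#' several per subject via duplicates), the per-subject harmonized records
#' produced by [harmonizeDuplicates()], and the parameters of the run.
#' Exclusion reasons are recorded in the subject table, never applied
#' silently: [analysisSet()] returns the retained subjects and
#' [exclusionLedger()] accounts for every input subject.
#'
#' @slot samples data.frame of per-sample observations (manifest columns plus
#'   direct site calls and imputed genotype columns).
#' @slot subjects data.frame of harmonized per-subject records; empty until
#'   [harmonizeDuplicates()] has run.
#' @slot dupPairs data.frame of duplicate sample pairs
#'   (`sample_id_a`, `sample_id_b`).
#' @slot params list of run parameters (`r2Min`, `minAge`, `approach`,
#'   `discordantPolicy`, stage flags).
#' @export
setClass("ApoeCohort", slots = c(
  samples  = "data.frame",
  subjects = "data.frame",
  dupPairs = "data.frame",
  params   = "list"
))

setValidity("ApoeCohort", function(object) {
  msgs <- character()
  miss <- setdiff(.SAMPLE_COLS, names(object@samples))
  if (length(miss))
    msgs <- c(msgs, paste("samples missing column(s):",
                          paste(miss, collapse = ", ")))
  if (anyDuplicated(object@samples$sample_id))
    msgs <- c(msgs, "duplicated sample_id in samples table")
  if (nrow(object@subjects)) {
    if (!"exclusion" %in% names(object@subjects))
      msgs <- c(msgs, "subjects table lacks exclusion column")
    else if (!all(object@subjects$exclusion %in% .EXCLUSION_LEVELS))
      msgs <- c(msgs, "unknown exclusion level in subjects table")
  }
  bad <- !is.na(object@samples$provided_apoe) &
    !object@samples$provided_apoe %in% APOE_GENOTYPES
  if (any(bad))
    msgs <- c(msgs, "non-canonical provided_apoe in samples table")
  if (length(msgs)) msgs else TRUE
})

#' HaplotypeFreqs: two-locus haplotype frequency estimate
#'
#' Result of [emHaplotypeFreqs()]: maximum-likelihood frequencies of the four
#' haplotypes of two biallelic loci (A = focal allele at locus one, B = focal
#' allele at locus two), estimated by EM over unphased genotype counts.
#'
#' @slot freqs named numeric of length 4 (`AB`, `Ab`, `aB`, `ab`), summing
#'   to 1.
#' @slot loglik observed-data multinomial log-likelihood at the estimate.
#' @slot nIter number of EM iterations used.
#' @slot n number of individuals in the genotype table.
#' @export
setClass("HaplotypeFreqs", slots = c(
  freqs  = "numeric",
  loglik = "numeric",
  nIter  = "integer",
  n      = "numeric"
))

setValidity("HaplotypeFreqs", function(object) {
  f <- object@freqs
  if (length(f) != 4L || !identical(names(f), c("AB", "Ab", "aB", "ab")))
    return("freqs must be named AB, Ab, aB, ab")
  if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-8)
    return("freqs must be a point on the 3-simplex")
  TRUE
})

#' MisclassModel: genotype misclassification model for a rare stratum
#'
#' Parameters of the closed-form misclassification model for e4/4 status
#' within a phenotype group: `fTrue` is the true e4/4 frequency, `p1` the
#' type-I rate (calling a non-carrier e4/4) and `p2` the type-II rate
#' (calling a carrier non-e4/4). Derived quantities: [observedFrequency()]
#' and [concordanceObservedTrue()].
#'
#' @slot fTrue true frequency in (0, 1); vectorized.
#' @slot p1 type-I misclassification rate in \[0, 1\].
#' @slot p2 type-II misclassification rate in \[0, 1\].
#' @export
setClass("MisclassModel", slots = c(
  fTrue = "numeric",
  p1    = "numeric",
  p2    = "numeric"
))

setValidity("MisclassModel", function(object) {
  if (any(object@fTrue <= 0 | object@fTrue >= 1))
    return("fTrue must lie in (0, 1)")
  if (any(c(object@p1, object@p2) < 0 | c(object@p1, object@p2) > 1))
    return("p1 and p2 must lie in [0, 1]")
  n <- lengths(list(object@fTrue, object@p1, object@p2))
  if (length(unique(n[n > 1L])) > 1L)
    return("fTrue, p1, p2 must be recyclable to a common length")
  TRUE
})
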