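## Synthetic multi-cohort generator with full ground truth.
##
## Emulates the structure of a multi-cohort AD case-control collection:
## APOE allele frequencies with the canonical disease-risk model (~3-fold per
## epsilon-4 copy, ~12-fold for 4/4, ~0.5 for epsilon-2), rs439401 in high LD
## (D' ~ 0.95) with epsilon-3 plus a rare epsilon-4-in-phase haplotype,
## per-source genotyping error (one "bad" cohort with elevated provided-APOE
## error), duplicate samples across cohorts, and missing sources.

#' Default cohort layout for the synthetic generator
#'
#' Six cohorts (total n = 20,000) of mixed source types: four array-only
#' cohorts (provided + imputed APOE, direct rs439401), one with WGS on top
#' and one with partial WES (rs429358 only). `BADCO` carries an elevated
#' provided-APOE error rate, mimicking a cohort whose legacy direct assay is
#' unreliable.
#'
#' @return data.frame with columns `name`, `n`, `profile`
#'   (`"array"`, `"array+wgs"`, `"array+wes"`), `provided_error`.
#' @export
defaultCohorts <- function() {
  data.frame(
    name = c("COH_A", "COH_B", "BADCO", "COH_C", "COH_D", "COH_E"),
    n = c(5000L, 4000L, 3000L, 3000L, 3000L, 2000L),
    profile = c("array", "array", "array", "array+wgs", "array+wes", "array"),
    provided_error = c(0.01, 0.01, 0.05, 0.005, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' All defaults are the study conditions of the simulated collection; see the
#' methods vignette for the rationale behind each value.
#'
#' @param seed integer master seed; every random draw descends from it.
#' @param cohorts data.frame as in [defaultCohorts()].
#' @param apoeFreqs named numeric simplex `c(e2=, e3=, e4=)` of allele
#'   frequencies.
#' @param freqT overall rs439401 T allele frequency.
#' @param targetDprime target D' between rs439401-T and \eqn{\epsilon}3
#'   (coupling phase).
#' @param rareInphaseFreq frequency of the rare \eqn{\epsilon}4–T haplotype.
#' @param orPerE4,orE4E4,orPerE2 disease odds ratios: per \eqn{\epsilon}4
#'   copy, for \eqn{\epsilon}4/4 total (beyond multiplicativity), per
#'   \eqn{\epsilon}2 copy.
#' @param basePrevalence AD probability for an \eqn{\epsilon}3/3 subject.
#' @param ageMeanSd mean and SD (years) of the age distribution (truncated at
#'   40).
#' @param dupRate probability a subject is re-emitted as a duplicate sample
#'   in a (possibly different) cohort.
#' @param providedMissingRate probability a sample lacks a provided genotype.
#' @param imputationErrorRate per-variant probability the imputed dosage
#'   centres on a wrong genotype.
#' @param wgsErrorRate per-variant error rate of direct (array/WGS/WES) calls.
#' @param newSeqRate fraction of subjects with a newly released sequencing
#'   call (used by the approach-2 consistency check; default 0 = not emitted).
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(seed = 1L,
                      cohorts = defaultCohorts(),
                      apoeFreqs = c(e2 = 0.08, e3 = 0.77, e4 = 0.15),
                      freqT = 0.35,
                      targetDprime = 0.95,
                      rareInphaseFreq = 0.002,
                      orPerE4 = 3, orE4E4 = 12, orPerE2 = 0.5,
                      basePrevalence = 0.35,
                      ageMeanSd = c(74, 8),
                      dupRate = 0.03,
                      providedMissingRate = 0.02,
                      imputationErrorRate = 0.005,
                      wgsErrorRate = 0.001,
                      newSeqRate = 0) {
  cfg <- list(seed = as.integer(seed), cohorts = cohorts,
              apoeFreqs = apoeFreqs, freqT = freqT,
              targetDprime = targetDprime, rareInphaseFreq = rareInphaseFreq,
              orPerE4 = orPerE4, orE4E4 = orE4E4, orPerE2 = orPerE2,
              basePrevalence = basePrevalence, ageMeanSd = ageMeanSd,
              dupRate = dupRate, providedMissingRate = providedMissingRate,
              imputationErrorRate = imputationErrorRate,
              wgsErrorRate = wgsErrorRate, newSeqRate = newSeqRate)
  stopifnot(
    is.data.frame(cohorts),
    all(c("name", "n", "profile", "provided_error") %in% names(cohorts)),
    all(cohorts$profile %in% c("array", "array+wgs", "array+wes")),
    abs(sum(apoeFreqs) - 1) < 1e-8, all(apoeFreqs >= 0),
    identical(sort(names(apoeFreqs)), c("e2", "e3", "e4")),
    freqT > 0, freqT < 1,
    targetDprime >= 0, targetDprime <= 1,
    rareInphaseFreq >= 0,
    orPerE4 > 0, orE4E4 > 0, orPerE2 > 0,
    basePrevalence > 0, basePrevalence < 1,
    length(ageMeanSd) == 2, ageMeanSd[2] > 0,
    all(c(dupRate, providedMissingRate, imputationErrorRate, wgsErrorRate,
          cohorts$provided_error, newSeqRate) >= 0),
    all(c(dupRate, providedMissingRate, imputationErrorRate, wgsErrorRate,
          cohorts$provided_error, newSeqRate) <= 1)
  )
  ## fail early if the LD target is infeasible
  haplotypeTable(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

#' Six-class haplotype distribution implied by a SimConfig
#'
#' Constructs the frequencies of the six haplotype classes
#' (\eqn{\epsilon}2/3/4 x rs439401 C/T) that hit the configured D' between
#' rs439401-T and \eqn{\epsilon}3 and the configured rare
#' \eqn{\epsilon}4–T frequency: the \eqn{\epsilon}3–T frequency is set to
#' `p3*pT + D'*Dmax`, the residual T mass is split between
#' \eqn{\epsilon}4–T (fixed at `rareInphaseFreq`) and \eqn{\epsilon}2–T.
#'
#' @param cfg a [simConfig()] list.
#' @return data.frame with columns `apoe` (allele), `t439401` (0/1), `freq`.
#' @export
haplotypeTable <- function(cfg) {
  f <- cfg$apoeFreqs
  p3 <- f[["e3"]]; pT <- cfg$freqT
  dmax <- min(p3 * (1 - pT), (1 - p3) * pT)
  D <- cfg$targetDprime * dmax
  h3T <- p3 * pT + D
  h4T <- cfg$rareInphaseFreq
  h2T <- pT - h3T - h4T
  hap <- data.frame(
    apoe = rep(c("e2", "e3", "e4"), each = 2),
    t439401 = rep(0:1, 3),
    freq = c(f[["e2"]] - h2T, h2T, p3 - h3T, h3T, f[["e4"]] - h4T, h4T)
  )
  if (any(hap$freq < -1e-12))
    stop("INFEASIBLE_LD: target D'/rare in-phase frequency incompatible with allele frequencies",
         call. = FALSE)
  hap$freq <- pmax(hap$freq, 0)
  hap
}

## draw genotypes uniformly from the admissible alternatives of `exclude`
.corruptUniform <- function(truthGeno, doCorrupt, universe) {
  out <- truthGeno
  idx <- which(doCorrupt)
  if (length(idx)) {
    k <- length(universe)
    pick <- sample.int(k - 1L, length(idx), replace = TRUE)
    cur <- match(truthGeno[idx], universe)
    pick <- pick + (pick >= cur)  # skip the true value
    out[idx] <- universe[pick]
  }
  out
}

#' Simulate ground-truth subjects
#'
#' Draws two phased haplotypes per subject from the six-class distribution of
#' [haplotypeTable()], assigns disease status from a logistic model with
#' log-odds terms for \eqn{\epsilon}4 dosage, an extra \eqn{\epsilon}4/4
#' term, and \eqn{\epsilon}2 dosage, and fills in age (normal truncated at
#' 40), sex, cohort and principal-component noise.
#'
#' @param cfg a [simConfig()] list.
#' @return data.table truth table, one row per subject, with phased
#'   haplotypes (`hap1_apoe`, `hap1_t`, ...), `true_apoe`, `true_t`
#'   (rs439401 T count), `t_on_e4` (T alleles on an \eqn{\epsilon}4
#'   background — the in-phase truth), phenotype and covariates.
#' @export
simulateHaplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  hap <- haplotypeTable(cfg)
  n <- sum(cfg$cohorts$n)
  i1 <- sample.int(6L, n, replace = TRUE, prob = hap$freq)
  i2 <- sample.int(6L, n, replace = TRUE, prob = hap$freq)
  a1 <- hap$apoe[i1]; a2 <- hap$apoe[i2]
  t1 <- hap$t439401[i1]; t2 <- hap$t439401[i2]

  apoe <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  n4 <- (a1 == "e4") + (a2 == "e4")
  n2 <- (a1 == "e2") + (a2 == "e2")
  eta <- qlogis(cfg$basePrevalence) + log(cfg$orPerE4) * n4 +
    (log(cfg$orE4E4) - 2 * log(cfg$orPerE4)) * (n4 == 2L) +
    log(cfg$orPerE2) * n2
  dxAD <- rbinom(n, 1L, plogis(eta))

  age <- rnorm(n, cfg$ageMeanSd[1], cfg$ageMeanSd[2])
  while (any(age < 40)) {
    low <- age < 40
    age[low] <- rnorm(sum(low), cfg$ageMeanSd[1], cfg$ageMeanSd[2])
  }

  truth <- data.table(
    subject_id = sprintf("S%06d", seq_len(n)),
    cohort = rep(cfg$cohorts$name, cfg$cohorts$n)[sample.int(n)],
    dx = ifelse(dxAD == 1L, "AD", "CN"),
    age = round(age, 1), sex = sample(c("F", "M"), n, TRUE, c(0.55, 0.45)),
    hap1_apoe = a1, hap1_t = t1, hap2_apoe = a2, hap2_t = t2,
    true_apoe = apoe, true_t = t1 + t2,
    t_on_e4 = (a1 == "e4") * t1 + (a2 == "e4") * t2
  )
  for (k in 1:5) truth[, (paste0("PC", k)) := rnorm(n)]
  truth[]
}

#' Emit per-sample observed sources from a truth table
#'
#' Produces the observable files of a multi-cohort collection: a sample
#' manifest (provided APOE with per-cohort symmetric genotype error and a
#' missingness rate), a long table of direct site calls (rs439401 for every
#' array sample; rs429358/rs7412 for WGS samples; rs429358 only for WES
#' samples; each with the direct-call error rate), imputed dosages for
#' rs429358/rs7412 (noise around the true — or, at the imputation error
#' rate, a wrong — genotype; per-cohort R-squared drawn in \[0.85, 0.99\]),
#' and a duplicate-pair table. Duplicate samples are re-emitted under
#' independent error draws in a randomly assigned cohort.
#'
#' @param truth output of [simulateHaplotypes()].
#' @param cfg the same [simConfig()] list.
#' @return list of data.tables: `manifest`, `sites`, `dosages`, `dups`,
#'   `newSeq` (NULL when `newSeqRate` is 0) and `truth` (passed through).
#' @export
emitObservedSources <- function(truth, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  truth <- as.data.table(truth)

  ## primary sample per subject + duplicate samples in a random cohort
  isDup <- runif(nrow(truth)) < cfg$dupRate
  prim <- truth[, .(subject_id, cohort)][, sample_id := paste0(subject_id, "_1")]
  dup <- truth[isDup, .(subject_id)]
  dup[, cohort := sample(cfg$cohorts$name, .N, replace = TRUE,
                         prob = cfg$cohorts$n)]
  dup[, sample_id := paste0(subject_id, "_2")]
  samp <- rbind(prim, dup)
  samp <- merge(samp, cfg$cohorts, by.x = "cohort", by.y = "name",
                sort = FALSE)
  samp <- merge(samp,
                truth[, c("subject_id", "dx", "age", "sex",
                          paste0("PC", 1:5), "true_apoe", "true_t"),
                      with = FALSE],
                by = "subject_id", sort = FALSE)
  setorder(samp, subject_id, sample_id)
  ns <- nrow(samp)

  samp[, has_provided := runif(ns) >= cfg$providedMissingRate]
  samp[, has_imputed := TRUE]
  samp[, has_wgs := profile == "array+wgs"]
  samp[, has_wes := profile == "array+wes"]

  ## provided APOE: symmetric uniform error kernel at the cohort's rate
  samp[, provided_apoe := .corruptUniform(
    true_apoe, runif(ns) < provided_error, APOE_GENOTYPES)]
  samp[has_provided == FALSE, provided_apoe := NA_character_]

  ## true site genotypes
  sn <- snpsFromApoe(samp$true_apoe)
  samp[, `:=`(true_429358 = sn$alt429358, true_7412 = sn$alt7412)]

  ## direct calls with the direct-call error rate
  call439 <- .corruptUniform(samp$true_t, runif(ns) < cfg$wgsErrorRate, 0:2)
  call429 <- .corruptUniform(samp$true_429358, runif(ns) < cfg$wgsErrorRate, 0:2)
  call741 <- .corruptUniform(samp$true_7412, runif(ns) < cfg$wgsErrorRate, 0:2)
  sites <- rbind(
    data.table(sample_id = samp$sample_id, variant_id = "rs439401",
               gt = as.integer(call439)),
    data.table(sample_id = samp$sample_id, variant_id = "rs429358",
               gt = ifelse(samp$has_wgs | samp$has_wes,
                           as.integer(call429), NA_integer_)),
    data.table(sample_id = samp$sample_id, variant_id = "rs7412",
               gt = ifelse(samp$has_wgs, as.integer(call741), NA_integer_))
  )

  ## imputed dosages: per cohort x variant R2, gaussian noise about the
  ## (possibly corrupted) genotype
  r2tab <- CJ(cohort = cfg$cohorts$name, variant_id = c("rs429358", "rs7412"))
  r2tab[, r2 := round(runif(.N, 0.85, 0.99), 3)]
  mkDos <- function(trueG, v) {
    g <- .corruptUniform(trueG, runif(ns) < cfg$imputationErrorRate, 0:2)
    d <- pmin(2, pmax(0, g + rnorm(ns, 0, 0.08)))
    dt <- data.table(sample_id = samp$sample_id, cohort = samp$cohort,
                     variant_id = v, dosage = round(d, 3))
    dt[r2tab, on = c("cohort", "variant_id"), r2 := i.r2]
    dt[, cohort := NULL]
    dt
  }
  dosages <- rbind(mkDos(samp$true_429358, "rs429358"),
                   mkDos(samp$true_7412, "rs7412"))

  ## duplicate pairs reference the emitted sample ids
  dups <- data.table(sample_id_a = paste0(dup$subject_id, "_1"),
                     sample_id_b = dup$sample_id)

  newSeq <- NULL
  if (cfg$newSeqRate > 0) {
    pick <- samp[runif(ns) < cfg$newSeqRate,
                 .(sample_id, true_apoe)]
    if (nrow(pick)) {
      pick[, apoe := .corruptUniform(true_apoe,
                                     runif(.N) < cfg$wgsErrorRate,
                                     APOE_GENOTYPES)]
      newSeq <- pick[, .(sample_id, apoe)]
    }
  }

  manifest <- samp[, c("sample_id", "subject_id", "cohort", "dx", "age",
                       "sex", paste0("PC", 1:5), "provided_apoe",
                       "has_provided", "has_imputed", "has_wgs", "has_wes"),
                   with = FALSE]
  list(manifest = manifest, sites = sites, dosages = dosages, dups = dups,
       newSeq = newSeq, truth = truth)
}

#' Simulate a complete synthetic multi-cohort data set
#'
#' [simulateHaplotypes()] followed by [emitObservedSources()] under the
#' configured seed. Deterministic: the same config yields byte-identical
#' tables.
#'
#' @param cfg a [simConfig()] list.
#' @return see [emitObservedSources()].
#' @export
simulateCohortData <- function(cfg = simConfig()) {
  emitObservedSources(simulateHaplotypes(cfg), cfg)
}
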