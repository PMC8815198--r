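## Shared fixture builders: everything is generated in code at test time.

## a minimal manifest row set; per-sample fields default to a healthy
## 70-year-old control with zero PCs
makeManifest <- function(sample_id, subject_id = sample_id,
                         cohort = "COH", dx = "CN", age = 70, sex = "F",
                         provided_apoe = NA_character_,
                         has_provided = !is.na(provided_apoe),
                         has_imputed = FALSE, has_wgs = FALSE,
                         has_wes = FALSE) {
  n <- length(sample_id)
  d <- data.frame(sample_id = sample_id, subject_id = subject_id,
                  cohort = cohort, dx = dx, age = age, sex = sex,
                  PC1 = 0, PC2 = 0, PC3 = 0, PC4 = 0, PC5 = 0,
                  provided_apoe = provided_apoe,
                  has_provided = has_provided, has_imputed = has_imputed,
                  has_wgs = has_wgs, has_wes = has_wes,
                  stringsAsFactors = FALSE)
  d[rep(seq_len(nrow(d)), length.out = n), , drop = FALSE]
}

## long site-call rows for one sample
makeSites <- function(sample_id, rs429358 = NA, rs7412 = NA, rs439401 = NA) {
  data.frame(sample_id = sample_id,
             variant_id = c("rs429358", "rs7412", "rs439401"),
             gt = as.integer(c(rs429358, rs7412, rs439401)),
             stringsAsFactors = FALSE)
}

## clean imputed dosages implying a given APOE genotype at high R2
makeDosages <- function(sample_id, apoe, r2 = 0.95) {
  sn <- snpsFromApoe(apoe)
  data.frame(sample_id = rep(sample_id, each = 2),
             variant_id = rep(c("rs429358", "rs7412"), length(sample_id)),
             dosage = as.numeric(rbind(sn$alt429358, sn$alt7412)),
             r2 = r2, stringsAsFactors = FALSE)
}

## a small, fast generator configuration (~2,000 subjects, 3 cohorts)
smallConfig <- function(seed = 1L, ...) {
  co <- data.frame(
    name = c("A", "B", "BAD"),
    n = c(800L, 700L, 500L),
    profile = c("array", "array+wgs", "array"),
    provided_error = c(0.01, 0.005, 0.05),
    stringsAsFactors = FALSE)
  simConfig(seed = seed, cohorts = co, ...)
}

## independent 1-D grid oracle for the two-locus haplotype MLE: allele
## margins are fully observed, so the only free parameter is p_AB inside its
## Frechet bounds; maximize the observed-data multinomial log-likelihood on
## a fine grid (no EM involved)
gridOracleHapFreqs <- function(counts, step = 1e-5) {
  n <- sum(counts)
  pA <- sum(counts * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  pab <- seq(lo, hi, by = step)
  ll <- vapply(pab, function(x) {
    p <- c(x, pA - x, pB - x, 1 - pA - pB + x)
    if (any(p < 0)) return(-Inf)
    ## explicit genotype cell probabilities under random union of haplotypes
    pAB <- p[1]; pAb <- p[2]; paB <- p[3]; pabf <- p[4]
    P <- matrix(0, 3, 3)
    P[1, 1] <- pabf^2;         P[1, 2] <- 2 * pabf * paB;  P[1, 3] <- paB^2
    P[2, 1] <- 2 * pabf * pAb; P[2, 3] <- 2 * paB * pAB
    P[2, 2] <- 2 * (pAB * pabf + pAb * paB)
    P[3, 1] <- pAb^2;          P[3, 2] <- 2 * pAb * pAB;   P[3, 3] <- pAB^2
    sum(counts[counts > 0] * log(P[counts > 0]))
  }, numeric(1))
  i <- which.max(ll)
  list(pAB = pab[i], loglik = ll[i])
}

## random 3x3 genotype table of n individuals from random haplotype freqs
randomGenotypeTable <- function(n, seed) {
  set.seed(seed)
  p <- as.numeric(stats::rexp(4)); p <- p / sum(p)
  h1 <- sample.int(4L, n, TRUE, p)
  h2 <- sample.int(4L, n, TRUE, p)
  aCount <- (h1 <= 2) + (h2 <= 2)             # haps 1,2 carry allele A
  bCount <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))  # haps 1,3 carry allele B
  genotypeCounts(aCount, bCount)
}
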