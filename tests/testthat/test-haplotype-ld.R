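test_that("EM equals direct haplotype counting when no phase is latent", {
  ## no double heterozygotes: every haplotype is observed directly
  counts <- matrix(c(10, 4, 1,
                     6, 0, 2,
                     3, 1, 5), nrow = 3, byrow = TRUE)
  h <- emHaplotypeFreqs(counts)
  n <- 2 * sum(counts)
  direct <- c(
    AB = (2 * counts[3, 3] + counts[3, 2] + counts[2, 3]) / n,
    Ab = (2 * counts[3, 1] + counts[3, 2] + counts[2, 1]) / n,
    aB = (2 * counts[1, 3] + counts[1, 2] + counts[2, 3]) / n,
    ab = (2 * counts[1, 1] + counts[1, 2] + counts[2, 1]) / n)
  expect_equal(haplotypeFreqs(h), direct, tolerance = 1e-12)
})

test_that("EM matches the grid-search likelihood oracle on small tables", {
  for (seed in c(1, 7, 23, 40, 55)) {
    counts <- randomGenotypeTable(n = 50, seed = seed)
    pA <- sum(counts * matrix(0:2, 3, 3)) / (2 * sum(counts))
    pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * sum(counts))
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) next  # no latent phase to test
    h <- emHaplotypeFreqs(counts)
    oracle <- gridOracleHapFreqs(counts)
    expect_lt(abs(unname(haplotypeFreqs(h)["AB"]) - oracle$pAB), 2e-5)
    expect_gte(h@loglik + 1e-8, oracle$loglik)
  }
})

test_that("EM output is a proper distribution and improves on its start", {
  for (seed in 1:10) {
    counts <- randomGenotypeTable(n = 200, seed = seed)
    h <- emHaplotypeFreqs(counts)
    f <- haplotypeFreqs(h)
    expect_lt(abs(sum(f) - 1), 1e-12)
    expect_true(all(f >= 0))
    pA <- f[["AB"]] + f[["Ab"]]; pB <- f[["AB"]] + f[["aB"]]
    if (pA > 0 && pA < 1 && pB > 0 && pB < 1) {
      dp <- dprime(h)
      expect_lte(abs(dp), 1 + 1e-12)
      D <- f[["AB"]] - pA * pB
      if (D != 0) expect_equal(sign(dp), sign(D))
      ## log-likelihood at the estimate is no worse than at the
      ## linkage-equilibrium start
      le <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
      expect_gte(h@loglik + 1e-9, apoeqc:::.glogLik(counts, le))
    }
  }
})

test_that("D' hits its landmarks: perfect coupling, independence, monomorphic", {
  ## perfect coupling: only AB and ab haplotypes
  coupled <- emHaplotypeFreqs(matrix(c(30, 0, 0, 0, 20, 0, 0, 0, 10), 3, 3))
  expect_equal(dprime(coupled), 1)
  ## independence constructed exactly
  h <- new("HaplotypeFreqs", freqs = c(AB = 0.12, Ab = 0.28, aB = 0.18,
                                       ab = 0.42), loglik = 0, nIter = 1L,
           n = 1)
  expect_equal(dprime(h), 0)
  ## a monomorphic locus has no defined D'
  mono <- emHaplotypeFreqs(matrix(c(0, 0, 0, 0, 0, 0, 10, 5, 2), 3,
                                  byrow = TRUE))
  f <- haplotypeFreqs(mono)
  expect_equal(f[["AB"]] - (f[["AB"]] + f[["Ab"]]) * (f[["AB"]] + f[["aB"]]),
               0, tolerance = 1e-12)
  expect_error(dprime(mono), "MONOMORPHIC")
  expect_error(emHaplotypeFreqs(matrix(0, 3, 3)), "EMPTY_TABLE")
})

test_that("the generator's planted D' is recovered from truth genotypes", {
  cfg <- smallConfig(seed = 19)
  tr <- simulateHaplotypes(cfg)
  cc <- genotypeCounts(apoeBiallelic(tr$true_apoe, "e3"), tr$true_t)
  ## n = 2,000 here; the acceptance suite checks the tight +/-0.02 bound at
  ## n = 50,000 — at this size allow ordinary sampling noise
  expect_lt(abs(dprime(emHaplotypeFreqs(cc)) - 0.95), 0.1)
})

test_that("strata encode phase guarantees correctly", {
  recs <- data.frame(
    subject_id = sprintf("s%d", 1:7),
    dx = "CN", age = 70, sex = "F",
    apoe = c("e4/e4", "e4/e4", "e3/e4", "e3/e4", "e3/e4", "e3/e3", "e2/e4"),
    rs439401 = c(1L, 2L, 0L, 1L, 2L, 1L, 2L))
  st <- assignStrata(recs)
  ## e4/4: any T is in phase with e4; additive coding equals the T count
  expect_equal(st$E44_ADDITIVE$gcode, c(1L, 2L))
  ## e3/4 WT-vs-HOM keeps only C/C and T/T; the single-T carrier is dropped
  expect_equal(st$E34_WT_VS_HOM$subject_id, c("s3", "s5"))
  expect_equal(st$E34_WT_VS_HOM$gcode, c(0L, 1L))
  expect_equal(nrow(st$E34_ADDITIVE), 3L)
  expect_equal(st$E33_ADDITIVE$gcode, 1L)
  ## e2/4 carriers enter no stratum, including the full-sample one
  for (s in names(st))
    expect_false("s7" %in% st[[s]]$subject_id)
  expect_equal(st$FULL_ADJUSTED$e4dos,
               c(2L, 2L, 1L, 1L, 1L, 0L))
})
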