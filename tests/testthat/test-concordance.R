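test_that("identical sources give rate 1 in every stratum", {
  cfg <- smallConfig(seed = 4, imputationErrorRate = 0, wgsErrorRate = 0)
  cfg$cohorts$provided_error <- 0
  sim <- simulateCohortData(cfg)
  coh <- runPipeline(sim, approach = 1)
  cc <- pairwiseConcordance(subjects(coh), "provided", "imputed",
                            by = "cohort")
  expect_true(all(cc$rate[cc$n_compared > 0] == 1))
})

test_that("the planted bad cohort has the lowest provided-vs-imputed rate", {
  sim <- simulateCohortData(smallConfig(seed = 21))
  coh <- runPipeline(sim, approach = 1)
  cc <- pairwiseConcordance(subjects(coh), "provided", "imputed",
                            by = "cohort")
  expect_equal(cc$cohort[which.min(cc$rate)], "BAD")
})

test_that("stratified agreement counts aggregate to the full-sample count", {
  sim <- simulateCohortData(smallConfig(seed = 6))
  coh <- runPipeline(sim, approach = 1)
  sub <- subjects(coh)
  full <- pairwiseConcordance(sub, "provided", "imputed")
  byCo <- pairwiseConcordance(sub, "provided", "imputed", by = "cohort")
  byDx <- pairwiseConcordance(sub, "provided", "imputed",
                              by = c("cohort", "dx"))
  expect_equal(sum(byCo$n_agree), full$n_agree)
  expect_equal(sum(byDx$n_agree), full$n_agree)
  expect_equal(sum(byDx$n_compared), full$n_compared)
  expect_true(all(byDx$rate >= 0 & byDx$rate <= 1, na.rm = TRUE))
})

test_that("unknown sources and missing groupings are rejected", {
  sim <- simulateCohortData(smallConfig(seed = 6))
  coh <- runPipeline(sim, approach = 1)
  expect_error(pairwiseConcordance(subjects(coh), "provided", "telepathy"),
               "UNKNOWN_SOURCE")
  expect_error(pairwiseConcordance(subjects(coh), "provided", "imputed",
                                   by = "nope"), "unknown grouping")
})

test_that("duplicate concordance is exact on error-free data and matches a direct count", {
  cfg0 <- smallConfig(seed = 10, wgsErrorRate = 0, dupRate = 0.2)
  sim0 <- simulateCohortData(cfg0)
  coh0 <- ApoeCohort(sim0$manifest, sim0$sites, dupPairs = sim0$dups)
  out0 <- duplicateVariantConcordance(coh0)
  expect_equal(out0$rate, 1)

  ## planted direct-call error e: expected pairwise agreement is
  ## (1-e)^2 + e^2/2 (both wrong and landing on the same of 2 alternatives)
  e <- 0.05
  cfg <- smallConfig(seed = 10, wgsErrorRate = e, dupRate = 0.2)
  sim <- simulateCohortData(cfg)
  coh <- ApoeCohort(sim$manifest, sim$sites, dupPairs = sim$dups)
  out <- duplicateVariantConcordance(coh, variantId = "rs439401")
  ## function output equals a brute-force count over the pair table
  g <- setNames(samples(coh)$gt_rs439401, samples(coh)$sample_id)
  agree <- g[sim$dups$sample_id_a] == g[sim$dups$sample_id_b]
  expect_equal(out$n_agree, sum(agree, na.rm = TRUE))
  expect_equal(out$rate, mean(agree, na.rm = TRUE))
  pExp <- (1 - e)^2 + e^2 / 2
  expect_lt(abs(out$rate - pExp),
            3 * sqrt(pExp * (1 - pExp) / out$n_pairs))
})

test_that("provided-vs-imputed concordance is lower in e4/4 controls than cases", {
  ## e4/4 status is rare in controls, so the same error rates dilute the
  ## observed control carriers far more than the cases: concordance with the
  ## (accurate) imputed genotype drops in the control stratum
  sim <- simulateCohortData(simConfig(seed = 99))
  coh <- runPipeline(sim, approach = 1)
  sub <- subjects(coh)
  cc <- pairwiseConcordance(sub[sub$exclusion == "NONE", ],
                            "provided", "imputed",
                            by = c("apoe_stratum", "dx"))
  e44 <- cc[cc$apoe_stratum == "e4/e4", ]
  expect_lt(e44$rate[e44$dx == "CN"], e44$rate[e44$dx == "AD"])
})

test_that("degenerate duplicate inputs are handled explicitly", {
  man <- makeManifest(c("a", "b"), provided_apoe = "e3/e3")
  coh <- ApoeCohort(man)
  expect_error(duplicateVariantConcordance(coh), "NO_PAIRS")
  ## pairs exist but no overlapping non-missing calls -> NA rate
  dups <- data.frame(sample_id_a = "a", sample_id_b = "b")
  coh2 <- ApoeCohort(man, dupPairs = dups)
  out <- duplicateVariantConcordance(coh2)
  expect_true(is.na(out$rate))
  expect_equal(out$n_pairs, 0L)
})
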