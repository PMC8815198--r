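## helpers build tiny hand-made cohorts; the generator covers scale.

test_that("sequencing outranks provided and imputation is ignored in approach 1", {
  man <- makeManifest(c("s1", "s2", "s3"),
                      provided_apoe = c("e3/e4", "e3/e4", NA),
                      has_wgs = c(TRUE, FALSE, FALSE),
                      has_wes = c(FALSE, FALSE, TRUE),
                      has_imputed = TRUE)
  sites <- rbind(makeSites("s1", rs429358 = 2, rs7412 = 0),  # WGS says e4/e4
                 makeSites("s3", rs429358 = 1))              # WES only
  dos <- makeDosages(c("s1", "s2", "s3"), c("e3/e3", "e3/e3", "e3/e4"))
  coh <- ApoeCohort(man, sites, dos)
  coh <- adjudicate(harmonizeDuplicates(coh), approach = 1)
  sub <- subjects(coh)
  sub <- sub[order(sub$subject_id), ]
  ## s1: WGS e4/e4 wins over provided e3/e4
  expect_equal(sub$apoe[1], "e4/e4")
  expect_equal(sub$apoe_source[1], "WGS")
  ## s2: provided stands although imputation disagrees
  expect_equal(sub$apoe[2], "e3/e4")
  expect_equal(sub$apoe_source[2], "PROVIDED")
  expect_equal(sub$exclusion[2], "NONE")
  ## s3: WES alone cannot separate e2 from e3
  expect_equal(sub$exclusion[3], "NO_APOE")
})

test_that("WES contradiction excludes; confirmation lets provided stand", {
  man <- makeManifest(c("s1", "s2"), provided_apoe = c("e4/e4", "e3/e4"),
                      has_wes = TRUE)
  sites <- rbind(makeSites("s1", rs429358 = 1),   # one C: contradicts 4/4
                 makeSites("s2", rs429358 = 1))   # one C: confirms 3/4
  coh <- adjudicate(harmonizeDuplicates(ApoeCohort(man, sites)), approach = 1)
  sub <- subjects(coh)[order(subjects(coh)$subject_id), ]
  expect_equal(sub$exclusion, c("WES_CONTRADICTED", "NONE"))
  expect_equal(sub$apoe[2], "e3/e4")
})

test_that("duplicate harmonization flags provided-only discordance", {
  man <- makeManifest(c("d1_a", "d1_b", "d2_a", "d2_b"),
                      subject_id = c("d1", "d1", "d2", "d2"),
                      provided_apoe = c("e3/e3", "e3/e4", "e3/e4", "e3/e4"))
  dups <- data.frame(sample_id_a = c("d1_a", "d2_a"),
                     sample_id_b = c("d1_b", "d2_b"))
  coh <- harmonizeDuplicates(ApoeCohort(man, dupPairs = dups))
  sub <- subjects(coh)[order(subjects(coh)$subject_id), ]
  expect_equal(nrow(sub), 2L)
  expect_equal(sub$exclusion, c("DUP_DISCORDANT_PROVIDED", "NONE"))
  ## the concordant pair merges to a single clean record
  expect_equal(sub$provided_apoe[2], "e3/e4")
  expect_equal(sub$n_samples, c(2L, 2L))
})

test_that("discordant sequencing across duplicates is an exclusion", {
  ## WGS-derived e3/e3 vs WES rs429358 ALT count 1 cannot both be right
  man <- makeManifest(c("x_a", "x_b"), subject_id = "x",
                      provided_apoe = "e3/e3",
                      has_wgs = c(TRUE, FALSE), has_wes = c(FALSE, TRUE))
  sites <- rbind(makeSites("x_a", rs429358 = 0, rs7412 = 0),
                 makeSites("x_b", rs429358 = 1))
  dups <- data.frame(sample_id_a = "x_a", sample_id_b = "x_b")
  coh <- harmonizeDuplicates(ApoeCohort(man, sites, dupPairs = dups))
  expect_equal(subjects(coh)$exclusion, "WGS_WES_DISCORDANT")
})

test_that("unknown samples in the duplicate table are an error", {
  man <- makeManifest("s1", provided_apoe = "e3/e3")
  dups <- data.frame(sample_id_a = "s1", sample_id_b = "ghost")
  expect_error(harmonizeDuplicates(ApoeCohort(man, dupPairs = dups)),
               "MISSING_SAMPLE")
})

test_that("approach 2 excludes provided-imputed discordance but spares sequencing", {
  man <- makeManifest(c("s1", "s2", "s3"),
                      provided_apoe = c("e4/e4", "e3/e4", "e3/e4"),
                      has_wgs = c(FALSE, FALSE, TRUE), has_imputed = TRUE)
  sites <- makeSites("s3", rs429358 = 1, rs7412 = 0)
  dos <- makeDosages(c("s1", "s2", "s3"), c("e3/e4", "e3/e4", "e3/e3"))
  coh <- harmonizeDuplicates(ApoeCohort(man, sites, dos))
  sub2 <- subjects(adjudicate(coh, approach = 2))
  sub2 <- sub2[order(sub2$subject_id), ]
  expect_equal(sub2$exclusion,
               c("APPROACH2_IMPUTED_DISCORDANT", "NONE", "NONE"))
  ## WGS-sourced s3 is immune even though imputation disagrees
  expect_equal(sub2$apoe[3], "e3/e4")
  ## the impute policy retains the subject under the imputed genotype
  subI <- subjects(adjudicate(coh, approach = 2, discordantPolicy = "impute"))
  subI <- subI[order(subI$subject_id), ]
  expect_equal(subI$exclusion[1], "NONE")
  expect_equal(subI$apoe[1], "e3/e4")
  expect_equal(subI$apoe_source[1], "IMPUTED")
})

test_that("low-quality imputation cannot trigger the approach-2 exclusion", {
  man <- makeManifest("s1", provided_apoe = "e4/e4", has_imputed = TRUE)
  dos <- makeDosages("s1", "e3/e4", r2 = 0.7)   # below the 0.8 floor
  coh <- harmonizeDuplicates(ApoeCohort(man, dosages = dos))
  sub <- subjects(adjudicate(coh, approach = 2))
  expect_equal(sub$exclusion, "NONE")
  expect_equal(sub$apoe, "e4/e4")
})

test_that("newly released sequencing contradicting the call excludes it", {
  man <- makeManifest(c("s1", "s2"), provided_apoe = "e4/e4",
                      has_imputed = TRUE)
  dos <- makeDosages(c("s1", "s2"), "e4/e4")
  ns <- data.frame(sample_id = c("s1", "s2"), apoe = c("e3/e4", "e4/e4"))
  coh <- harmonizeDuplicates(ApoeCohort(man, dosages = dos, newSeq = ns))
  sub <- subjects(adjudicate(coh, approach = 2))
  sub <- sub[order(sub$subject_id), ]
  expect_equal(sub$exclusion, c("NEW_SEQ_DISCORDANT", "NONE"))
})

test_that("the age floor is inclusive and bad diagnoses are dropped", {
  man <- makeManifest(c("s1", "s2", "s3", "s4"), provided_apoe = "e3/e3",
                      age = c(59.9, 60, 75, 75),
                      dx = c("CN", "CN", "MCI", NA))
  coh <- adjudicate(harmonizeDuplicates(ApoeCohort(man)), approach = 1)
  coh <- applyInclusionFilters(coh, minAge = 60)
  sub <- subjects(coh)[order(subjects(coh)$subject_id), ]
  expect_equal(sub$exclusion,
               c("AGE_FILTER", "NONE", "DX_FILTER", "DX_FILTER"))
})

test_that("approach-2 retention is a subset of approach 1 and counts reconcile", {
  for (seed in c(2, 17, 31)) {
    sim <- simulateCohortData(smallConfig(seed = seed, newSeqRate = 0.1))
    c1 <- runPipeline(sim, approach = 1)
    c2 <- runPipeline(sim, approach = 2)
    r1 <- analysisSet(c1)$subject_id
    r2 <- analysisSet(c2)$subject_id
    expect_true(all(r2 %in% r1))
    ## exclusion ledger is additive and accounts for every subject
    for (coh in list(c1, c2)) {
      led <- exclusionLedger(coh)
      expect_equal(sum(led$n), nrow(subjects(coh)))
    }
  }
})

test_that("with error-free sources the two approaches agree and no flags fire", {
  cfg <- smallConfig(seed = 8, imputationErrorRate = 0, wgsErrorRate = 0,
                     providedMissingRate = 0)
  cfg$cohorts$provided_error <- 0
  sim <- simulateCohortData(cfg)
  c1 <- runPipeline(sim, approach = 1)
  c2 <- runPipeline(sim, approach = 2)
  expect_identical(sort(analysisSet(c1)$subject_id),
                   sort(analysisSet(c2)$subject_id))
  led <- exclusionLedger(c2)
  discord <- led$n[led$exclusion %in%
                     c("DUP_DISCORDANT_PROVIDED", "WGS_WES_DISCORDANT",
                       "WES_CONTRADICTED", "APPROACH2_IMPUTED_DISCORDANT",
                       "NEW_SEQ_DISCORDANT")]
  expect_true(all(discord == 0))
  ## and every prioritized genotype equals the truth
  m <- merge(analysisSet(c1), sim$truth[, c("subject_id", "true_apoe")],
             by = "subject_id")
  expect_true(all(m$apoe == m$true_apoe))
})
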