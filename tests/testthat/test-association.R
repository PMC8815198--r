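test_that("carrier percentages reproduce exact count arithmetic", {
  mk <- function(nCarrier, nTotal, dx) {
    data.frame(dx = dx, tcount = rep(c(1L, 0L), c(nCarrier, nTotal - nCarrier)))
  }
  tab <- carrierTable(rbind(mk(14, 237, "CN"), mk(19, 1652, "AD")))
  expect_equal(tab$carrier_pct, c(5.91, 1.15))
  tab2 <- carrierTable(rbind(mk(2, 203, "CN"), mk(0, 50, "AD")))
  expect_equal(tab2$carrier_pct, c(0.99, 0.00))
  ## allelic MAF counts alleles, not carriers
  hom <- data.frame(dx = "CN", tcount = c(2L, 0L, 0L, 0L))
  expect_equal(carrierTable(hom)$maf_pct, 25)
  expect_error(carrierTable(data.frame()), "EMPTY_STRATUM")
})

test_that("crude odds ratios follow the cross-product with Wald intervals", {
  ## e4/4 approach-1 carrier table: 19/1652 AD vs 14/237 CN
  out <- crudeOr(19, 1633, 14, 223)
  expect_equal(round(out$or_, 3), 0.185)
  expect_equal(crudeOr(5, 5, 5, 5)$or_, 1)
  ## a zero cell stays finite through the Haldane-Anscombe correction
  z <- crudeOr(0, 100, 10, 90)
  expect_true(is.finite(z$or_) && z$or_ > 0)
  expect_error(crudeOr(0, 100, 0, 90), "ALL_ZERO_MARGIN")
})

test_that("an uncorrected crude OR equals the covariate-free logistic OR", {
  set.seed(5)
  d <- data.frame(dx = sample(c("CN", "AD"), 400, TRUE),
                  tcount = rbinom(400, 1, 0.3))
  d$gcode <- d$tcount
  a <- sum(d$dx == "AD" & d$gcode == 1); b <- sum(d$dx == "AD" & d$gcode == 0)
  cc <- sum(d$dx == "CN" & d$gcode == 1); dd <- sum(d$dx == "CN" & d$gcode == 0)
  crude <- crudeOr(a, b, cc, dd, correction = FALSE)
  fit <- fitStratum(d, "test", covariates = character(0))
  expect_equal(fit$or_, crude$or_, tolerance = 1e-6)
  expect_equal(fit$p, crude$p, tolerance = 1e-4)
})

test_that("degenerate strata are reported, not silently dropped", {
  d <- data.frame(dx = rep(c("CN", "AD"), each = 20), gcode = 0L,
                  tcount = 0L, age = 70, sex = "F")
  expect_equal(fitStratum(d, "flat")$note, "NO_VARIATION")
  ## perfectly separated genotype
  d2 <- data.frame(dx = rep(c("CN", "AD"), each = 20),
                   gcode = rep(c(0L, 1L), each = 20),
                   tcount = rep(c(0L, 1L), each = 20))
  out <- fitStratum(d2, "sep", covariates = character(0))
  expect_equal(out$note, "SEPARATION")
  expect_error(fitStratum(data.frame(), "empty"), "EMPTY_STRATUM")
})

test_that("confidence intervals cover a planted protective effect", {
  ## planted OR 0.5 on the genotype code, with nuisance covariates
  set.seed(77)
  hits <- 0L
  reps <- 300L
  for (r in seq_len(reps)) {
    n <- 900L
    g <- rbinom(n, 2, 0.25)
    age <- rnorm(n, 72, 6)
    sex <- sample(c("F", "M"), n, TRUE)
    eta <- 0.2 + log(0.5) * g + 0.01 * (age - 72)
    d <- data.frame(dx = ifelse(rbinom(n, 1, plogis(eta)) == 1, "AD", "CN"),
                    gcode = g, tcount = g, age = age, sex = sex)
    out <- fitStratum(d, "planted", covariates = c("age", "sex"))
    if (out$ci_lo <= 0.5 && 0.5 <= out$ci_hi) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.93)
})

test_that("error-free input yields identical approach-1 and approach-2 rows", {
  cfg <- smallConfig(seed = 12, imputationErrorRate = 0, wgsErrorRate = 0,
                     providedMissingRate = 0)
  cfg$cohorts$provided_error <- 0
  res <- compareApproaches(simulateCohortData(cfg))
  r1 <- res[res$approach == 1, setdiff(names(res), "approach")]
  r2 <- res[res$approach == 2, setdiff(names(res), "approach")]
  expect_equal(r1, r2, ignore_attr = TRUE)
  expect_true(all(res$carrier_freq_delta_cn == 0))
})

test_that("cohort adjustment is available as a sensitivity analysis", {
  sim <- simulateCohortData(smallConfig(seed = 14))
  coh <- runPipeline(sim, approach = 2)
  st <- assignStrata(analysisSet(coh))
  plain <- fitStratum(st$E33_ADDITIVE, "E33_ADDITIVE")
  adj <- fitStratum(st$E33_ADDITIVE, "E33_ADDITIVE", cohortAdjust = TRUE)
  expect_false(identical(plain$or_, adj$or_))
  expect_true(is.finite(adj$or_))
})
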