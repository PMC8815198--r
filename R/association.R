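## Stratified case-control association analyses: carrier tables, crude odds
## ratios, covariate-adjusted logistic fits, and the approach-1 vs approach-2
## paired comparison.

.DEFAULT_COVARIATES <- c("age", "sex", paste0("PC", 1:5))

#' Carrier counts, percentages and allele frequencies for one stratum
#'
#' Carriers hold at least one T allele at rs439401; the allelic frequency is
#' T alleles over `2n`. Percentages are rounded to two decimals.
#'
#' @param dat one stratum data.table from [assignStrata()] (needs `dx` and
#'   `tcount`).
#' @return data.table, one row per phenotype (`CN`, `AD`): `n`, `carriers`,
#'   `carrier_pct`, `maf_pct`.
#' @export
carrierTable <- function(dat) {
  d <- as.data.table(dat)
  if (!nrow(d)) stop("EMPTY_STRATUM: no subjects", call. = FALSE)
  out <- d[, .(n = .N, carriers = sum(tcount >= 1L),
               carrier_pct = round(100 * mean(tcount >= 1L), 2),
               maf_pct = round(100 * sum(tcount) / (2 * .N), 2)),
           keyby = .(dx = factor(dx, c("CN", "AD")))]
  out[]
}

#' Crude (unadjusted) odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with a Wald 95% CI on the log scale; when any
#' cell is zero the Haldane–Anscombe continuity correction adds 0.5 to all
#' four cells. This is the unadjusted sanity-check companion to the
#' covariate-adjusted [fitStratum()] models.
#'
#' @param caseExposed,caseUnexposed,controlExposed,controlUnexposed cell
#'   counts.
#' @param correction apply the 0.5 correction when a cell is zero (default
#'   TRUE).
#' @return one-row data.table: `or_`, `ci_lo`, `ci_hi`, `p`,
#'   `model = "CRUDE_2x2"`.
#' @export
#' @examples
#' crudeOr(19, 1633, 14, 223)
crudeOr <- function(caseExposed, caseUnexposed, controlExposed,
                    controlUnexposed, correction = TRUE) {
  cells <- c(caseExposed, caseUnexposed, controlExposed, controlUnexposed)
  stopifnot(length(cells) == 4, all(cells >= 0))
  if (caseExposed + controlExposed == 0 ||
      caseUnexposed + controlUnexposed == 0 ||
      caseExposed + caseUnexposed == 0 ||
      controlExposed + controlUnexposed == 0)
    stop("ALL_ZERO_MARGIN: a margin of the 2x2 table is empty", call. = FALSE)
  if (correction && any(cells == 0)) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  logOr <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(0.975)
  data.table(or_ = exp(logOr), ci_lo = exp(logOr - z * se),
             ci_hi = exp(logOr + z * se),
             p = 2 * stats::pnorm(-abs(logOr / se)), model = "CRUDE_2x2")
}

#' Covariate-adjusted logistic association for one stratum
#'
#' Logistic regression of AD status on the stratum's genotype coding plus
#' age, sex and the first five principal components (optionally cohort fixed
#' effects, and \eqn{\epsilon}2/\eqn{\epsilon}4 dosages for the full-sample
#' stratum). Inference is Wald. Covariates constant within the stratum are
#' dropped automatically. Quasi-separated fits are reported with
#' `note = "SEPARATION"` rather than silently dropped — inspect the carrier
#' counts; a constant genotype column yields `note = "NO_VARIATION"` with NA
#' estimates.
#'
#' @param dat one stratum data.table from [assignStrata()].
#' @param stratum stratum label for the output row.
#' @param covariates covariate column names (default age, sex, PC1..PC5).
#' @param cohortAdjust add cohort fixed effects (sensitivity analysis;
#'   default FALSE, the mega-analysis design).
#' @return one-row data.table: stratum label, per-phenotype totals and
#'   carrier counts, `maf_cn`/`maf_ad` (fractions), `or_`, `ci_lo`,
#'   `ci_hi`, `p`, `model`, `note`.
#' @export
fitStratum <- function(dat, stratum = "stratum",
                       covariates = .DEFAULT_COVARIATES,
                       cohortAdjust = FALSE) {
  d <- as.data.table(dat)
  if (!nrow(d)) stop("EMPTY_STRATUM: no subjects", call. = FALSE)
  d <- d[dx %in% c("CN", "AD")]
  model <- if (identical(stratum, "E34_WT_VS_HOM")) "WT_HOM_LOGISTIC"
           else "ADDITIVE_LOGISTIC"

  cn <- d[dx == "CN"]; ad <- d[dx == "AD"]
  base <- data.table(
    stratum = stratum,
    n_cn = nrow(cn), n_ad = nrow(ad),
    carriers_cn = sum(cn$tcount >= 1L), carriers_ad = sum(ad$tcount >= 1L),
    maf_cn = if (nrow(cn)) sum(cn$tcount) / (2 * nrow(cn)) else NA_real_,
    maf_ad = if (nrow(ad)) sum(ad$tcount) / (2 * nrow(ad)) else NA_real_)

  fail <- function(note) cbind(base, data.table(
    or_ = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
    model = model, note = note))
  if (nrow(cn) == 0 || nrow(ad) == 0) return(fail("NO_CASES_OR_CONTROLS"))
  if (data.table::uniqueN(d$gcode) < 2L) return(fail("NO_VARIATION"))

  covs <- c(covariates,
            if (all(c("e2dos", "e4dos") %in% names(d))) c("e2dos", "e4dos"),
            if (cohortAdjust) "cohort")
  covs <- covs[covs %in% names(d)]
  covs <- covs[vapply(covs, function(v) data.table::uniqueN(d[[v]]) > 1L,
                      logical(1))]
  fm <- stats::reformulate(c("gcode", covs), response = "dxBin")
  d[, dxBin := as.integer(dx == "AD")]

  note <- "OK"
  fit <- withCallingHandlers(
    glm(fm, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        note <<- "SEPARATION"
      invokeRestart("muffleWarning")
    })
  est <- coef(fit)[["gcode"]]
  se <- sqrt(diag(vcov(fit))[["gcode"]])
  if (!note %in% "OK" || abs(est) > 15) note <- "SEPARATION"
  z <- qnorm(0.975)
  cbind(base, data.table(
    or_ = exp(est), ci_lo = exp(est - z * se), ci_hi = exp(est + z * se),
    p = 2 * stats::pnorm(-abs(est / se)), model = model, note = note))
}

#' Paired association report under both filtering approaches
#'
#' Runs the full pipeline under approach 1 and approach 2 on the same input,
#' fits every analysis stratum under both, and returns the paired rows with
#' carrier-frequency deltas — the table that shows whether an apparent
#' in-phase effect survives the stricter genotype filter.
#'
#' @param sim a generator output list (see [runPipeline()]).
#' @param strata which strata to fit (default all five).
#' @param cohortAdjust add cohort fixed effects to every fit.
#' @param r2Min,minAge pipeline parameters.
#' @return data.table: one row per stratum x approach, [fitStratum()]
#'   columns plus `approach` and `carrier_freq_delta_cn`/`_ad` (approach 2
#'   minus approach 1 carrier fractions).
#' @export
compareApproaches <- function(sim,
                              strata = c("E44_ADDITIVE", "E34_WT_VS_HOM",
                                         "E34_ADDITIVE", "E33_ADDITIVE",
                                         "FULL_ADJUSTED"),
                              cohortAdjust = FALSE, r2Min = 0.8, minAge = 60) {
  fitOne <- function(approach) {
    coh <- runPipeline(sim, approach = approach, r2Min = r2Min,
                       minAge = minAge)
    st <- assignStrata(analysisSet(coh))
    rbindlist(lapply(strata, function(s) {
      if (!nrow(st[[s]])) {
        r <- data.table(stratum = s, n_cn = 0L, n_ad = 0L, carriers_cn = 0L,
                        carriers_ad = 0L, maf_cn = NA_real_,
                        maf_ad = NA_real_, or_ = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p = NA_real_, model = NA_character_,
                        note = "EMPTY_STRATUM")
        return(r)
      }
      fitStratum(st[[s]], stratum = s, cohortAdjust = cohortAdjust)
    }))[, approach := approach]
  }
  res <- rbind(fitOne(1), fitOne(2))
  wide <- dcast(res, stratum ~ approach,
                value.var = c("carriers_cn", "n_cn", "carriers_ad", "n_ad"))
  wide[, `:=`(
    carrier_freq_delta_cn = carriers_cn_2 / pmax(n_cn_2, 1L) -
      carriers_cn_1 / pmax(n_cn_1, 1L),
    carrier_freq_delta_ad = carriers_ad_2 / pmax(n_ad_2, 1L) -
      carriers_ad_1 / pmax(n_ad_1, 1L))]
  res[wide[, .(stratum, carrier_freq_delta_cn, carrier_freq_delta_ad)],
      on = "stratum",
      `:=`(carrier_freq_delta_cn = i.carrier_freq_delta_cn,
           carrier_freq_delta_ad = i.carrier_freq_delta_ad)]
  setorder(res, stratum, approach)
  res[]
}
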