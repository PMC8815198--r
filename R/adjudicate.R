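## Duplicate harmonization and the two APOE filtering approaches.

.POST_HARMONIZE_EXCLUSIONS <- c("NO_APOE", "WES_CONTRADICTED",
                                "APPROACH2_IMPUTED_DISCORDANT",
                                "NEW_SEQ_DISCORDANT", "AGE_FILTER",
                                "DX_FILTER")

## merge one multi-sample duplicate group into a single subject record
.mergeGroup <- function(g) {
  prov <- unique(g$provided_apoe[!is.na(g$provided_apoe)])
  wgs  <- unique(g$wgs_apoe[!is.na(g$wgs_apoe)])
  wes  <- unique(g$wes_alt429358[!is.na(g$wes_alt429358)])
  hasSeq <- length(wgs) > 0L || length(wes) > 0L

  excl <- "NONE"
  ## sequencing-derived calls must agree across duplicates: WGS vs WGS on the
  ## full genotype, WES vs WES and WES vs WGS on the epsilon-4 arm
  seqDisc <- length(wgs) > 1L || length(wes) > 1L ||
    (length(wgs) == 1L && length(wes) == 1L &&
       apoeAlleleCount(wgs, "e4") != wes)
  if (seqDisc) {
    excl <- "WGS_WES_DISCORDANT"
  } else if (length(prov) > 1L && !hasSeq) {
    ## provided-only subjects with discordant provided APOE across duplicates
    excl <- "DUP_DISCORDANT_PROVIDED"
  }

  ## best imputed source: highest minimum R2 across the two component variants
  impI <- which(g$imputed_ok)
  if (length(impI)) {
    minr2 <- pmin(g$r2_rs429358[impI], g$r2_rs7412[impI])
    best <- impI[which.max(minr2)]
  } else best <- NA_integer_

  ## rs439401 consensus across direct calls: modal value, WGS-backed samples
  ## win ties
  t39 <- g$gt_rs439401
  ok39 <- which(!is.na(t39))
  cons39 <- NA_integer_
  if (length(ok39)) {
    tab <- tapply(ifelse(g$has_wgs[ok39], 1.5, 1.0), t39[ok39], sum)
    cons39 <- as.integer(names(tab)[which.max(tab)])
  }

  ns <- g$new_seq_apoe[!is.na(g$new_seq_apoe)]

  list(subject_id = g$subject_id[1L], cohort = g$cohort[1L], dx = g$dx[1L],
       age = g$age[1L], sex = g$sex[1L],
       PC1 = g$PC1[1L], PC2 = g$PC2[1L], PC3 = g$PC3[1L], PC4 = g$PC4[1L],
       PC5 = g$PC5[1L],
       provided_apoe = if (length(prov) == 1L) prov else NA_character_,
       dup_discordant_provided = length(prov) > 1L,
       wgs_apoe = if (length(wgs) == 1L && !seqDisc) wgs else NA_character_,
       wes_alt429358 = if (length(wes) == 1L && !seqDisc) wes else NA_integer_,
       imputed_apoe = if (!is.na(best)) g$imputed_apoe[best] else NA_character_,
       imputed_ambiguous = if (!is.na(best)) g$imputed_ambiguous[best] else FALSE,
       imputed_ok = !is.na(best),
       rs439401 = cons39,
       new_seq_apoe = if (length(ns)) ns[1L] else NA_character_,
       n_samples = nrow(g),
       exclusion = excl)
}

#' @describeIn harmonizeDuplicates Group samples by the transitive closure of
#'   the duplicate-pair table (via graph components) and collapse each group
#'   into one subject record. Provided-only groups with discordant provided
#'   APOE are flagged `DUP_DISCORDANT_PROVIDED`; groups whose sequencing
#'   sources disagree (WGS vs WGS on the full genotype, or the WES rs429358
#'   ALT count vs the WGS-derived \eqn{\epsilon}4 count) are flagged
#'   `WGS_WES_DISCORDANT`. Nothing is dropped — flags are recorded in the
#'   subject table.
#' @export
setMethod("harmonizeDuplicates", "ApoeCohort", function(object, ...) {
  man <- as.data.table(object@samples)
  dp <- object@dupPairs
  unknown <- setdiff(unique(c(dp$sample_id_a, dp$sample_id_b)), man$sample_id)
  if (length(unknown))
    stop("MISSING_SAMPLE: duplicate pair references unknown sample(s): ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)

  man[, group_id := seq_len(.N)]
  if (nrow(dp)) {
    gr <- igraph::graph_from_data_frame(
      dp, directed = FALSE,
      vertices = data.frame(name = man$sample_id))
    memb <- igraph::components(gr)$membership
    man[, group_id := as.integer(memb[sample_id])]
  }

  sizes <- man[, .N, by = group_id]
  multi <- sizes[sizes$N > 1L]$group_id

  single <- man[!group_id %in% multi]
  subSingle <- single[, .(
    subject_id, cohort, dx, age, sex, PC1, PC2, PC3, PC4, PC5,
    provided_apoe, dup_discordant_provided = FALSE,
    wgs_apoe, wes_alt429358, imputed_apoe, imputed_ambiguous, imputed_ok,
    rs439401 = gt_rs439401, new_seq_apoe, n_samples = 1L,
    exclusion = "NONE")]

  if (length(multi)) {
    subMulti <- man[group_id %in% multi,
                    .mergeGroup(.SD), by = group_id][, group_id := NULL]
    sub <- rbind(subSingle, subMulti)
  } else sub <- subSingle

  sub[, `:=`(apoe = NA_character_, apoe_source = NA_character_,
             ambiguous = FALSE)]
  setorder(sub, subject_id)
  object@subjects <- as.data.frame(sub)
  object@params$harmonized <- TRUE
  object@params$approach <- NA_integer_
  validObject(object)
  object
})

#' @describeIn adjudicate Apply filtering approach 1 or 2.
#'
#'   **Approach 1** selects, per subject, the highest-quality available
#'   source: a WGS-derived genotype wins outright; otherwise the provided
#'   genotype stands, after verification against a partial WES rs429358 call
#'   when one exists (a contradicted subject is excluded as
#'   `WES_CONTRADICTED`). Imputation is entirely ignored. Subjects with no
#'   usable source — including WES-only subjects, whose \eqn{\epsilon}2 vs
#'   \eqn{\epsilon}3 arm is undetermined — are flagged `NO_APOE`.
#'
#'   **Approach 2** starts from approach 1 and additionally excludes any
#'   subject whose prioritized genotype came from the provided source but
#'   disagrees with a usable imputed genotype (both component variants at
#'   R-squared >= `r2Min` and confidently hard-called); sequencing-sourced
#'   subjects are immune. With `discordantPolicy = "impute"` such subjects
#'   are instead retained with their imputed genotype. Finally, any newly
#'   released sequencing call that contradicts the prioritized genotype
#'   flags the subject `NEW_SEQ_DISCORDANT`.
#'
#' @param approach 1 or 2.
#' @param discordantPolicy `"exclude"` (default) or `"impute"`; approach 2
#'   only.
#' @export
setMethod("adjudicate", "ApoeCohort", function(object, approach = 1,
                                               discordantPolicy = c("exclude", "impute"),
                                               ...) {
  discordantPolicy <- match.arg(discordantPolicy)
  if (!isTRUE(object@params$harmonized))
    stop("run harmonizeDuplicates() before adjudicate()", call. = FALSE)
  if (!approach %in% c(1, 2)) stop("approach must be 1 or 2", call. = FALSE)

  sub <- as.data.table(object@subjects)
  ## re-adjudication resets everything downstream of harmonization
  sub[exclusion %in% .POST_HARMONIZE_EXCLUSIONS, exclusion := "NONE"]
  sub[, `:=`(apoe = NA_character_, apoe_source = NA_character_,
             ambiguous = FALSE)]

  elig <- sub$exclusion == "NONE"
  hasW <- !is.na(sub$wgs_apoe)
  sub[elig & hasW, `:=`(apoe = wgs_apoe, apoe_source = "WGS")]

  useProv <- elig & !hasW & !is.na(sub$provided_apoe)
  chk <- which(useProv & !is.na(sub$wes_alt429358))
  if (length(chk)) {
    verdict <- wesVerifies(sub$provided_apoe[chk], sub$wes_alt429358[chk])
    contra <- chk[verdict == "CONTRADICTED"]
    sub[contra, exclusion := "WES_CONTRADICTED"]
    useProv[contra] <- FALSE
  }
  sub[which(useProv), `:=`(apoe = provided_apoe, apoe_source = "PROVIDED")]
  sub[elig & exclusion == "NONE" & is.na(apoe), exclusion := "NO_APOE"]

  if (approach == 2) {
    disc <- which(sub$exclusion == "NONE" &
                    sub$apoe_source %in% "PROVIDED" &
                    sub$imputed_ok &
                    sub$imputed_apoe != sub$apoe)
    if (discordantPolicy == "exclude") {
      sub[disc, exclusion := "APPROACH2_IMPUTED_DISCORDANT"]
    } else {
      sub[disc, `:=`(apoe = imputed_apoe, apoe_source = "IMPUTED",
                     ambiguous = imputed_ambiguous)]
    }
    newDisc <- which(sub$exclusion == "NONE" & !is.na(sub$new_seq_apoe) &
                       !is.na(sub$apoe) & sub$new_seq_apoe != sub$apoe)
    sub[newDisc, exclusion := "NEW_SEQ_DISCORDANT"]
  }

  object@subjects <- as.data.frame(sub)
  object@params$approach <- as.integer(approach)
  object@params$discordantPolicy <- discordantPolicy
  validObject(object)
  object
})

#' @describeIn applyInclusionFilters Flag subjects below the age floor
#'   (`AGE_FILTER`; the floor is inclusive, age 60.0 is retained with the
#'   default) and subjects whose diagnosis is not CN or AD (`DX_FILTER`).
#' @param minAge inclusive age floor in years (default 60).
#' @export
setMethod("applyInclusionFilters", "ApoeCohort", function(object, minAge = 60,
                                                          ...) {
  if (!nrow(object@subjects))
    stop("run harmonizeDuplicates()/adjudicate() first", call. = FALSE)
  sub <- as.data.table(object@subjects)
  sub[exclusion %in% c("AGE_FILTER", "DX_FILTER"), exclusion := "NONE"]
  sub[exclusion == "NONE" & (is.na(age) | age < minAge),
      exclusion := "AGE_FILTER"]
  sub[exclusion == "NONE" & (is.na(dx) | !dx %in% c("CN", "AD")),
      exclusion := "DX_FILTER"]
  object@subjects <- as.data.frame(sub)
  object@params$minAge <- minAge
  object@params$filtered <- TRUE
  validObject(object)
  object
})

#' Run the full adjudication pipeline on generator output
#'
#' Convenience wrapper: [ApoeCohort()] assembly, [harmonizeDuplicates()],
#' [adjudicate()] and [applyInclusionFilters()] in one call.
#'
#' @param sim a list as returned by [simulateCohortData()] or
#'   [readCohortFiles()] (`manifest`, `sites`, `dosages`, `dups`, optionally
#'   `newSeq`).
#' @param approach 1 or 2.
#' @param r2Min imputation-quality floor.
#' @param minAge inclusive age floor.
#' @param discordantPolicy see [adjudicate()].
#' @return an adjudicated, filtered [ApoeCohort-class] object.
#' @export
runPipeline <- function(sim, approach = 1, r2Min = 0.8, minAge = 60,
                        discordantPolicy = "exclude") {
  coh <- ApoeCohort(sim$manifest, sim$sites, sim$dosages,
                    dupPairs = sim$dups, newSeq = sim$newSeq, r2Min = r2Min)
  coh <- harmonizeDuplicates(coh)
  coh <- adjudicate(coh, approach = approach,
                    discordantPolicy = discordantPolicy)
  applyInclusionFilters(coh, minAge = minAge)
}
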