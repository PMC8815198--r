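## ApoeCohort assembly and accessors.

#' Assemble an ApoeCohort from manifest, site calls and dosages
#'
#' Joins the sample manifest with direct site calls (from the sites VCF) and
#' imputed dosages into one per-sample table, derives per-sample genotype
#' sources (WGS-derived APOE, WES rs429358 ALT count, imputed hard-called
#' APOE), and wraps everything in an [ApoeCohort-class] object.
#'
#' Sequencing-derived site combinations that would imply an
#' \eqn{\epsilon}1 haplotype, and imputed dosages outside the hard-call
#' window, are treated as missing for that source (and therefore surface
#' later as `NO_APOE` or simply as an absent source) — corrupted upstream
#' calls never abort the run at assembly time.
#'
#' @param manifest data.frame with columns `sample_id`, `subject_id`,
#'   `cohort`, `dx`, `age`, `sex`, `PC1`..`PC5`, `provided_apoe` and logical
#'   source flags `has_provided`, `has_imputed`, `has_wgs`, `has_wes`.
#' @param sites long data.frame of direct calls: `sample_id`, `variant_id`,
#'   `gt` (ALT count, `NA` = missing). Typically from [readSitesVcf()].
#' @param dosages data.frame of imputed dosages: `sample_id`, `variant_id`,
#'   `dosage`, `r2`.
#' @param dupPairs data.frame of duplicate pairs (`sample_id_a`,
#'   `sample_id_b`); may be empty.
#' @param newSeq optional data.frame (`sample_id`, `apoe`) of newly released
#'   sequencing calls used by the approach-2 consistency check.
#' @param r2Min imputation-quality floor for usable dosages (default 0.8).
#' @return an [ApoeCohort-class] object (subjects table empty until
#'   [harmonizeDuplicates()]).
#' @export
ApoeCohort <- function(manifest, sites = NULL, dosages = NULL,
                       dupPairs = NULL, newSeq = NULL, r2Min = 0.8) {
  man <- as.data.table(manifest)
  miss <- setdiff(.SAMPLE_COLS, names(man))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (fl in c("has_provided", "has_imputed", "has_wgs", "has_wes"))
    if (!fl %in% names(man)) man[, (fl) := FALSE]
  man[, provided_apoe := parseApoe(provided_apoe, quiet = FALSE)]

  ## direct calls, wide
  for (v in APOE_VARIANTS$variant_id) man[, (paste0("gt_", v)) := NA_integer_]
  if (!is.null(sites) && nrow(sites)) {
    st <- as.data.table(sites)
    st <- st[variant_id %in% APOE_VARIANTS$variant_id]
    unknown <- setdiff(st$sample_id, man$sample_id)
    if (length(unknown))
      stop("site calls for unknown sample(s): ",
           paste(head(unknown, 3), collapse = ", "), call. = FALSE)
    wide <- dcast(st, sample_id ~ variant_id, value.var = "gt")
    for (v in intersect(APOE_VARIANTS$variant_id, names(wide)))
      man[wide, on = "sample_id", (paste0("gt_", v)) := get(paste0("i.", v))]
  }

  ## imputed dosages, wide
  for (v in c("rs429358", "rs7412"))
    man[, c(paste0("dos_", v), paste0("r2_", v)) :=
          list(NA_real_, NA_real_)]
  if (!is.null(dosages) && nrow(dosages)) {
    ds <- as.data.table(dosages)
    if (any(!is.na(ds$dosage) & (ds$dosage < 0 | ds$dosage > 2)))
      stop("imputed dosage outside [0, 2]", call. = FALSE)
    for (v in c("rs429358", "rs7412")) {
      dv <- ds[variant_id == v]
      man[dv, on = "sample_id",
          c(paste0("dos_", v), paste0("r2_", v)) := list(i.dosage, i.r2)]
    }
  }

  ## per-sample derived sources
  wgsApoe <- rep(NA_character_, nrow(man))
  iw <- which(man$has_wgs)
  if (length(iw)) {
    gg <- apoeFromSnps(man$gt_rs429358[iw], man$gt_rs7412[iw],
                       onInconsistent = "na", onMissing = "na")
    wgsApoe[iw] <- gg$apoe
  }
  man[, wgs_apoe := wgsApoe]
  man[, wes_alt429358 := ifelse(has_wes & !has_wgs, gt_rs429358, NA_integer_)]

  hc4 <- hardCall(man$dos_rs429358, man$r2_rs429358, r2Min = r2Min,
                  lowR2 = "missing")
  hc2 <- hardCall(man$dos_rs7412, man$r2_rs7412, r2Min = r2Min,
                  lowR2 = "missing")
  imp <- apoeFromSnps(hc4, hc2, onInconsistent = "na", onMissing = "na")
  man[, imputed_apoe := imp$apoe]
  man[, imputed_ambiguous := imp$ambiguous]
  man[, imputed_ok := !is.na(imp$apoe)]

  if (!is.null(newSeq) && nrow(newSeq)) {
    ns <- as.data.table(newSeq)
    ns[, apoe := parseApoe(apoe, quiet = TRUE)]
    man[ns, on = "sample_id", new_seq_apoe := i.apoe]
  } else man[, new_seq_apoe := NA_character_]

  dp <- if (is.null(dupPairs)) {
    data.frame(sample_id_a = character(), sample_id_b = character())
  } else as.data.frame(dupPairs)[, c("sample_id_a", "sample_id_b")]

  new("ApoeCohort",
      samples = as.data.frame(man),
      subjects = data.frame(),
      dupPairs = dp,
      params = list(r2Min = r2Min, minAge = NA_real_, approach = NA_integer_,
                    discordantPolicy = "exclude",
                    harmonized = FALSE, filtered = FALSE))
}

#' @rdname ApoeCohort-class
#' @aliases samples,ApoeCohort-method
setMethod("samples", "ApoeCohort", function(object) object@samples)

#' @rdname ApoeCohort-class
#' @aliases subjects,ApoeCohort-method
setMethod("subjects", "ApoeCohort", function(object) object@subjects)

#' @rdname ApoeCohort-class
#' @aliases analysisSet,ApoeCohort-method
setMethod("analysisSet", "ApoeCohort", function(object) {
  if (!nrow(object@subjects))
    stop("run harmonizeDuplicates()/adjudicate() first", call. = FALSE)
  object@subjects[object@subjects$exclusion == "NONE", , drop = FALSE]
})

#' @rdname ApoeCohort-class
#' @aliases exclusionLedger,ApoeCohort-method
setMethod("exclusionLedger", "ApoeCohort", function(object) {
  if (!nrow(object@subjects))
    stop("run harmonizeDuplicates() first", call. = FALSE)
  tab <- table(factor(object@subjects$exclusion, levels = .EXCLUSION_LEVELS))
  data.frame(exclusion = names(tab), n = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "ApoeCohort", function(object) {
  cat("ApoeCohort:", nrow(object@samples), "samples")
  if (nrow(object@subjects)) {
    cat(",", nrow(object@subjects), "subjects")
    kept <- sum(object@subjects$exclusion == "NONE")
    cat(sprintf(" (%d retained, %d excluded)", kept,
                nrow(object@subjects) - kept))
  }
  cat("\n")
  p <- object@params
  cat(sprintf("  r2Min=%.2f  approach=%s  minAge=%s\n", p$r2Min,
              ifelse(is.na(p$approach), "-", p$approach),
              ifelse(is.na(p$minAge), "-", p$minAge)))
  if (nrow(object@subjects)) {
    led <- exclusionLedger(object)
    led <- led[led$n > 0 & led$exclusion != "NONE", ]
    if (nrow(led))
      cat("  exclusions:",
          paste(sprintf("%s=%d", led$exclusion, led$n), collapse = ", "),
          "\n")
  }
  invisible(NULL)
})
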