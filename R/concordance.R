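## Stratified concordance diagnostics between APOE genotype sources and
## duplicate-sample genotype concordance.

.SOURCE_COLS <- c(provided = "provided_apoe", imputed = "imputed_apoe",
                  wgs = "wgs_apoe", prioritized = "apoe",
                  new_seq = "new_seq_apoe")

#' Stratified concordance between two APOE genotype sources
#'
#' For every subject carrying both sources, counts exact agreement of the
#' unordered epsilon pair (no partial credit for sharing one allele), overall
#' or within strata. Typical uses: provided vs imputed per cohort (finding a
#' "bad" cohort), provided vs imputed within prioritized-genotype x
#' phenotype strata (where low-frequency strata reveal the dilution of rare
#' genotypes by misclassification), and the provided/imputed/WGS triple
#' check.
#'
#' @param recs data.frame of subject records ([subjects()] output). Rows are
#'   compared only where both source columns are non-missing.
#' @param sourceA,sourceB source names among `"provided"`, `"imputed"`,
#'   `"wgs"`, `"prioritized"`, `"new_seq"`.
#' @param by character vector of grouping columns; any column of `recs` plus
#'   the derived `"carrier_439401"` (at least one T allele at rs439401) and
#'   `"apoe_stratum"` (the prioritized genotype, as set by [adjudicate()]).
#'   `NULL` (default) compares the full sample as one stratum.
#' @param minN strata with fewer compared subjects than this are flagged
#'   `low_n` (reported regardless; default 5).
#' @return data.table with columns `stratum`, the grouping columns,
#'   `n_compared`, `n_agree`, `rate` (`NA` when nothing is compared) and
#'   `low_n`.
#' @export
pairwiseConcordance <- function(recs, sourceA, sourceB, by = NULL, minN = 5L) {
  for (s in c(sourceA, sourceB))
    if (!s %in% names(.SOURCE_COLS))
      stop("UNKNOWN_SOURCE: ", s, " (expected one of ",
           paste(names(.SOURCE_COLS), collapse = ", "), ")", call. = FALSE)
  d <- as.data.table(recs)
  a <- d[[.SOURCE_COLS[[sourceA]]]]
  b <- d[[.SOURCE_COLS[[sourceB]]]]
  if (is.null(a) || is.null(b))
    stop("source column(s) absent from records", call. = FALSE)
  d[, `:=`(srcA = a, srcB = b)]

  if (!is.null(by)) {
    if ("carrier_439401" %in% by)
      d[, carrier_439401 := !is.na(rs439401) & rs439401 >= 1L]
    if ("apoe_stratum" %in% by)
      d[, apoe_stratum := apoe]
    miss <- setdiff(by, names(d))
    if (length(miss))
      stop("unknown grouping column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }

  cmp <- d[!is.na(srcA) & !is.na(srcB)]
  if (is.null(by)) {
    out <- cmp[, .(n_compared = .N, n_agree = sum(srcA == srcB))]
    out[, stratum := "all"]
  } else {
    out <- cmp[, .(n_compared = .N, n_agree = sum(srcA == srcB)), keyby = by]
    ## strata present in the records but with nothing compared are reported
    allStrata <- unique(d[, by, with = FALSE])
    out <- out[allStrata, on = by]
    out[is.na(n_compared), `:=`(n_compared = 0L, n_agree = 0L)]
    out[, stratum := do.call(paste, c(.SD, sep = "/")), .SDcols = by]
  }
  out[, rate := ifelse(n_compared > 0, n_agree / n_compared, NA_real_)]
  out[, low_n := n_compared < minN]
  setcolorder(out, c("stratum", setdiff(names(out), "stratum")))
  setorder(out, stratum)
  out[]
}

#' Duplicate-sample genotype concordance at one variant
#'
#' Fraction of duplicate sample pairs whose unphased genotype at the variant
#' is identical, using each sample's direct call.
#'
#' @param object an [ApoeCohort-class] object, or a per-sample data.frame
#'   with columns `sample_id` and `gt_<variantId>`.
#' @param dupPairs duplicate-pair data.frame; taken from the cohort object
#'   when omitted.
#' @param variantId which variant to compare (default `"rs439401"`).
#' @return one-row data.table: `variant_id`, `n_pairs` (pairs with both
#'   calls non-missing), `n_agree`, `rate` (`NA` when no pair has two
#'   calls).
#' @export
duplicateVariantConcordance <- function(object, dupPairs = NULL,
                                        variantId = "rs439401") {
  if (is(object, "ApoeCohort")) {
    if (is.null(dupPairs)) dupPairs <- object@dupPairs
    object <- samples(object)
  }
  col <- paste0("gt_", variantId)
  if (!col %in% names(object))
    stop("no direct calls for variant ", variantId, call. = FALSE)
  if (is.null(dupPairs) || !nrow(dupPairs))
    stop("NO_PAIRS: no duplicate pairs to compare", call. = FALSE)
  g <- setNames(object[[col]], object$sample_id)
  ga <- g[dupPairs$sample_id_a]
  gb <- g[dupPairs$sample_id_b]
  ok <- !is.na(ga) & !is.na(gb)
  data.table(variant_id = variantId,
             n_pairs = sum(ok),
             n_agree = sum(ga[ok] == gb[ok]),
             rate = if (any(ok)) sum(ga[ok] == gb[ok]) / sum(ok) else NA_real_)
}
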