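## Readers and writers: sites VCF, manifest/dosage/duplicate TSVs, report
## files, and the run configuration.

.gtToAlt <- function(gt) {
  gt <- sub(":.*", "", gt)            # drop FORMAT payload beyond GT
  a <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  vapply(a, function(x) {
    if (length(x) != 2L || any(x == ".")) return(NA_integer_)
    sum(as.integer(x))
  }, integer(1))
}

#' Read direct site calls from a sites VCF
#'
#' Reads a VCF (4.2, GT field) holding the three pinned variants, matching
#' records by ID (never position, so genome build is irrelevant) and
#' validating REF/ALT against the pinned orientation in [APOE_VARIANTS].
#' Missing GT (`./.`) becomes a missing call.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @param require variant IDs that must be present (default all three
#'   pinned variants); an absent one raises `MISSING_VARIANT`.
#' @return long data.table: `sample_id`, `variant_id`, `gt` (ALT count or
#'   `NA`).
#' @export
readSitesVcf <- function(path, require = APOE_VARIANTS$variant_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)          # single-record VCF
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  keep <- fix$ID %in% APOE_VARIANTS$variant_id
  missing <- setdiff(require, fix$ID)
  if (length(missing))
    stop("MISSING_VARIANT: ", paste(missing, collapse = ", "),
         " absent from ", path, call. = FALSE)
  pin <- APOE_VARIANTS[match(fix$ID[keep], APOE_VARIANTS$variant_id), ]
  bad <- fix$REF[keep] != pin$ref | fix$ALT[keep] != pin$alt
  if (any(bad))
    stop("ALLELE_MISMATCH: REF/ALT orientation differs from the pinned ",
         "definition for ", paste(pin$variant_id[bad], collapse = ", "),
         call. = FALSE)
  gtm <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gtm))) gtm <- t(gtm)
  gtm <- gtm[keep, , drop = FALSE]
  rownames(gtm) <- fix$ID[keep]
  out <- data.table(
    variant_id = rep(rownames(gtm), ncol(gtm)),
    sample_id = rep(colnames(gtm), each = nrow(gtm)),
    gt = .gtToAlt(as.vector(gtm)))
  out[]
}

#' Write a sites VCF of direct calls
#'
#' Minimal VCF 4.2 writer for the three pinned biallelic sites with a GT
#' field per sample; the inverse of [readSitesVcf()].
#'
#' @param sites long data.frame (`sample_id`, `variant_id`, `gt`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSitesVcf <- function(sites, path) {
  st <- as.data.table(sites)
  wide <- dcast(st, sample_id ~ variant_id, value.var = "gt")
  sampleIds <- wide$sample_id
  gtStr <- function(g) fifelse(is.na(g), "./.",
                               c("0/0", "0/1", "1/1")[g + 1L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=19>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds), collapse = "\t")), con)
  for (i in seq_len(nrow(APOE_VARIANTS))) {
    vr <- APOE_VARIANTS[i, ]
    g <- if (vr$variant_id %in% names(wide)) wide[[vr$variant_id]]
         else rep(NA_integer_, length(sampleIds))
    writeLines(paste(c(vr$chrom, vr$pos, vr$variant_id, vr$ref, vr$alt,
                       ".", "PASS", ".", "GT", gtStr(g)), collapse = "\t"),
               con)
  }
  invisible(path)
}

.readTsv <- function(path, requiredCols, what) {
  d <- fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
  miss <- setdiff(requiredCols, names(d))
  if (length(miss))
    stop("HEADER_MISMATCH: ", what, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' Read a sample manifest TSV
#'
#' Validates the header, normalizes the provided APOE tokens
#' (order-insensitive, e.g. `"e4/e3"`), and leaves unparseable tokens
#' missing with a warning. Unknown diagnosis tokens are retained — they are
#' excluded later by [applyInclusionFilters()].
#'
#' @param path TSV path.
#' @return data.table of manifest records.
#' @export
readManifest <- function(path) {
  d <- .readTsv(path, .SAMPLE_COLS, "manifest")
  if (anyDuplicated(d$sample_id))
    stop("DUPLICATE_SAMPLE_ID in manifest", call. = FALSE)
  d[, provided_apoe := parseApoe(provided_apoe)]
  for (fl in c("has_provided", "has_imputed", "has_wgs", "has_wes"))
    if (fl %in% names(d)) d[, (fl) := as.logical(get(fl))]
  d[]
}

#' Read an imputed dosage TSV
#'
#' @param path TSV with columns `sample_id`, `variant_id`, `dosage`, `r2`.
#' @return data.table; dosages outside \[0, 2\] or r2 outside \[0, 1\] are a
#'   validation error.
#' @export
readDosages <- function(path) {
  d <- .readTsv(path, c("sample_id", "variant_id", "dosage", "r2"), "dosages")
  if (any(!is.na(d$dosage) & (d$dosage < 0 | d$dosage > 2)))
    stop("dosage outside [0, 2]", call. = FALSE)
  if (any(!is.na(d$r2) & (d$r2 < 0 | d$r2 > 1)))
    stop("r2 outside [0, 1]", call. = FALSE)
  d[]
}

#' Read a duplicate-pair TSV
#'
#' @param path TSV with columns `sample_id_a`, `sample_id_b`.
#' @return data.table of pairs.
#' @export
readDuplicates <- function(path) {
  .readTsv(path, c("sample_id_a", "sample_id_b"), "duplicates")[]
}

#' Write a generator output list to files
#'
#' Writes `manifest.tsv`, `sites.vcf`, `dosages.tsv`, `dups.tsv`,
#' `truth.tsv` (and `new_seq.tsv` when present) under a prefix.
#'
#' @param sim list from [simulateCohortData()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeCohortFiles <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  fwrite(sim$manifest, p("manifest.tsv"), sep = "\t", na = "NA", quote = FALSE)
  writeSitesVcf(sim$sites, p("sites.vcf"))
  fwrite(sim$dosages, p("dosages.tsv"), sep = "\t", na = "NA", quote = FALSE)
  fwrite(sim$dups, p("dups.tsv"), sep = "\t", na = "NA", quote = FALSE)
  out <- c(manifest = p("manifest.tsv"), sites = p("sites.vcf"),
           dosages = p("dosages.tsv"), dups = p("dups.tsv"))
  if (!is.null(sim$truth)) {
    fwrite(sim$truth, p("truth.tsv"), sep = "\t", na = "NA", quote = FALSE)
    out <- c(out, truth = p("truth.tsv"))
  }
  if (!is.null(sim$newSeq)) {
    fwrite(sim$newSeq, p("new_seq.tsv"), sep = "\t", na = "NA", quote = FALSE)
    out <- c(out, newSeq = p("new_seq.tsv"))
  }
  invisible(out)
}

#' Read a cohort data set back from files
#'
#' Inverse of [writeCohortFiles()]; round-trips the observed tables.
#'
#' @param dir directory written by [writeCohortFiles()].
#' @return list with `manifest`, `sites`, `dosages`, `dups` and, when
#'   present, `newSeq` and `truth`.
#' @export
readCohortFiles <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list(manifest = readManifest(p("manifest.tsv")),
              sites = readSitesVcf(p("sites.vcf")),
              dosages = readDosages(p("dosages.tsv")),
              dups = readDuplicates(p("dups.tsv")))
  if (file.exists(p("new_seq.tsv")))
    out$newSeq <- .readTsv(p("new_seq.tsv"), c("sample_id", "apoe"),
                           "new_seq")
  if (file.exists(p("truth.tsv")))
    out$truth <- fread(p("truth.tsv"), sep = "\t")
  out
}

#' Format a P-value in the report convention
#'
#' Scientific notation with two mantissa decimals, e.g. `"1.64E-07"`.
#'
#' @param p numeric vector of probabilities.
#' @return character vector.
#' @export
formatPvalue <- function(p) {
  out <- toupper(formatC(p, format = "e", digits = 2))
  out[is.na(p)] <- "NA"
  out
}

#' Write the analysis reports
#'
#' Deterministic column order and rounding: percentages and OR/CI to two
#' decimals, P-values in scientific notation ([formatPvalue()]). Writes an
#' association TSV, a concordance TSV and an exclusion-ledger TSV (when the
#' corresponding element is present), plus a JSON run summary.
#'
#' @param results named list with any of `association` (from
#'   [fitStratum()]/[compareApproaches()]), `concordance` (from
#'   [pairwiseConcordance()]), `ledger` (from [exclusionLedger()]) and
#'   `summary` (arbitrary run metadata: seed, config, counts).
#' @param prefix output path prefix; files are `<prefix>_association.tsv`
#'   etc.
#' @return named character vector of the written paths, invisibly.
#' @export
writeReports <- function(results, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (!is.null(results$association)) {
    a <- as.data.table(results$association)
    for (col in intersect(c("or_", "ci_lo", "ci_hi"), names(a)))
      a[, (col) := round(get(col), 2)]
    for (col in intersect(c("maf_cn", "maf_ad"), names(a)))
      a[, (col) := round(100 * get(col), 2)]
    if ("p" %in% names(a)) a[, p := formatPvalue(as.numeric(p))]
    f <- paste0(prefix, "_association.tsv")
    fwrite(a, f, sep = "\t", na = "NA", quote = FALSE)
    written["association"] <- f
  }
  if (!is.null(results$concordance)) {
    cc <- as.data.table(results$concordance)
    if ("rate" %in% names(cc)) cc[, rate := round(rate, 4)]
    f <- paste0(prefix, "_concordance.tsv")
    fwrite(cc, f, sep = "\t", na = "NA", quote = FALSE)
    written["concordance"] <- f
  }
  if (!is.null(results$ledger)) {
    f <- paste0(prefix, "_exclusions.tsv")
    fwrite(as.data.table(results$ledger), f, sep = "\t", na = "NA",
           quote = FALSE)
    written["ledger"] <- f
  }
  f <- paste0(prefix, "_summary.json")
  jsonlite::write_json(results$summary, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  written["summary"] <- f
  invisible(written)
}
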