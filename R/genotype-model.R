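## Deterministic mapping between rs429358/rs7412 site genotypes and
## APOE*2/3/4 genotypes, plus hard-calling of imputed dosages and the
## WES partial-verification semantics.

#' Pinned variant definitions
#'
#' The three variants the package operates on, with fixed REF/ALT orientation:
#' rs429358 T>C (ALT C marks the \eqn{\epsilon}4 arm), rs7412 C>T (ALT T marks
#' the \eqn{\epsilon}2 arm), and rs439401 C>T (the tested allele is T).
#' VCF records are matched by ID, not position, so genome build is irrelevant;
#' positions are GRCh38 and informational only.
#'
#' @format A data.frame with columns `variant_id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
APOE_VARIANTS <- data.frame(
  variant_id = c("rs429358", "rs7412", "rs439401"),
  chrom      = c("19", "19", "19"),
  pos        = c(44908684L, 44908822L, 44911194L),
  ref        = c("T", "C", "C"),
  alt        = c("C", "T", "T"),
  stringsAsFactors = FALSE
)

#' The six valid APOE*2/3/4 genotypes (canonical, sorted notation)
#' @export
APOE_GENOTYPES <- c("e2/e2", "e2/e3", "e2/e4", "e3/e3", "e3/e4", "e4/e4")

## genotype string for (n4, n2) with n3 = 2 - n4 - n2; NA where an epsilon-1
## haplotype would be forced (n4 + n2 > 2)
.APOE_BY_COUNTS <- matrix(
  c("e3/e3", "e2/e3", "e2/e2",
    "e3/e4", "e2/e4", NA,
    "e4/e4", NA,      NA),
  nrow = 3, byrow = TRUE,
  dimnames = list(n4 = 0:2, n2 = 0:2)
)

.checkAltCount <- function(x, what) {
  if (!all(is.na(x) | x %in% 0:2))
    stop(sprintf("%s must be ALT-allele counts in {0, 1, 2} or NA", what),
         call. = FALSE)
  as.integer(x)
}

#' Normalize an APOE genotype token
#'
#' Parses strings such as `"e4/e3"`, `"E2/e4"` or `"e3e4"` into the canonical
#' sorted form (`"e3/e4"`). Tokens that do not resolve to one of the six valid
#' genotypes become `NA` (with a warning unless `quiet = TRUE`).
#'
#' @param x character vector of genotype tokens.
#' @param quiet suppress the warning on unparseable tokens.
#' @return character vector of canonical genotypes or `NA`.
#' @export
#' @examples
#' parseApoe(c("e4/e3", "E2/E2", "bogus"), quiet = TRUE)
parseApoe <- function(x, quiet = FALSE) {
  x0 <- tolower(as.character(x))
  x0 <- gsub("[^e234]", "", x0)
  out <- rep(NA_character_, length(x0))
  hit <- grepl("^e[234]e[234]$", x0)
  a1 <- substr(x0[hit], 1L, 2L)
  a2 <- substr(x0[hit], 3L, 4L)
  out[hit] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad) && !quiet)
    warning(sprintf("%d unparseable APOE genotype token(s) set to NA", sum(bad)),
            call. = FALSE)
  out
}

#' Count copies of one epsilon allele in an APOE genotype
#'
#' @param g character vector of canonical genotypes (see [parseApoe()]).
#' @param allele one of `"e2"`, `"e3"`, `"e4"`.
#' @return integer vector of allele counts (0, 1, 2), `NA` for `NA` input.
#' @export
apoeAlleleCount <- function(g, allele = c("e4", "e2", "e3")) {
  allele <- match.arg(allele)
  n <- (substr(g, 1L, 2L) == allele) + (substr(g, 4L, 5L) == allele)
  as.integer(n)
}

#' Derive the APOE genotype from unphased rs429358 and rs7412 calls
#'
#' The number of \eqn{\epsilon}4 alleles equals the rs429358 ALT (C) count and
#' the number of \eqn{\epsilon}2 alleles equals the rs7412 ALT (T) count; the
#' remainder is \eqn{\epsilon}3. Combinations that would force a C-rs429358
#' and T-rs7412 pair onto one chromosome (an \eqn{\epsilon}1 haplotype, assumed
#' absent) are inconsistent: of the nine unphased combinations, six map to
#' valid genotypes and three are inconsistent. The double heterozygote is
#' resolved as \eqn{\epsilon}2/\eqn{\epsilon}4 with `ambiguous = TRUE`, since
#' the alternative phase would require an \eqn{\epsilon}1.
#'
#' @param alt429358,alt7412 integer ALT-allele counts (0, 1, 2; `NA` = missing
#'   call). Recycled to a common length.
#' @param onInconsistent `"error"` (default) raises `INCONSISTENT_HAPLOTYPE`;
#'   `"na"` returns `NA` for inconsistent combinations (pipeline mode, where a
#'   corrupted upstream call must not abort a run).
#' @param onMissing `"na"` (default) propagates missing input as `NA`;
#'   `"error"` raises `MISSING_INPUT`.
#' @return data.frame with columns `apoe` (character) and `ambiguous`
#'   (logical; TRUE only for the double heterozygote).
#' @export
#' @examples
#' apoeFromSnps(0, 0)  # e3/e3
#' apoeFromSnps(1, 1)  # e2/e4, phase-ambiguous
apoeFromSnps <- function(alt429358, alt7412,
                         onInconsistent = c("error", "na"),
                         onMissing = c("na", "error")) {
  onInconsistent <- match.arg(onInconsistent)
  onMissing <- match.arg(onMissing)
  n <- max(length(alt429358), length(alt7412))
  n4 <- rep_len(.checkAltCount(alt429358, "alt429358"), n)
  n2 <- rep_len(.checkAltCount(alt7412, "alt7412"), n)

  miss <- is.na(n4) | is.na(n2)
  if (any(miss) && onMissing == "error")
    stop("MISSING_INPUT: missing site call(s) at rs429358/rs7412", call. = FALSE)

  bad <- !miss & (n4 + n2 > 2L)
  if (any(bad) && onInconsistent == "error")
    stop(sprintf(
      "INCONSISTENT_HAPLOTYPE: %d combination(s) imply an epsilon-1 haplotype (C at rs429358 with T at rs7412 on one chromosome)",
      sum(bad)), call. = FALSE)

  apoe <- rep(NA_character_, n)
  ok <- !miss & !bad
  apoe[ok] <- .APOE_BY_COUNTS[cbind(n4[ok] + 1L, n2[ok] + 1L)]
  data.frame(apoe = apoe,
             ambiguous = ok & n4 == 1L & n2 == 1L,
             stringsAsFactors = FALSE)
}

#' Inverse mapping: site genotypes implied by an APOE genotype
#'
#' For each of the six valid genotypes, returns the unique unphased rs429358
#' and rs7412 ALT counts. Round-trips with [apoeFromSnps()].
#'
#' @param g character vector of canonical APOE genotypes.
#' @return data.frame with integer columns `alt429358`, `alt7412`.
#' @export
snpsFromApoe <- function(g) {
  g <- parseApoe(g, quiet = TRUE)
  if (any(!is.na(g) & !g %in% APOE_GENOTYPES))
    stop("invalid APOE genotype", call. = FALSE)
  data.frame(alt429358 = apoeAlleleCount(g, "e4"),
             alt7412   = apoeAlleleCount(g, "e2"))
}

#' Hard-call an imputed dosage into a discrete genotype
#'
#' Rounds the ALT-allele expected count to the nearest integer; dosages more
#' than `window` away from every integer are treated as missing. Dosage
#' records below the imputation-quality floor `r2Min` are unusable.
#'
#' @param dosage numeric vector of ALT dosages in \[0, 2\].
#' @param r2 per-variant imputation R-squared in \[0, 1\]; recycled.
#' @param r2Min usability floor (default 0.8).
#' @param window maximum distance from an integer for a confident call
#'   (default 0.4).
#' @param lowR2 `"error"` (default) raises `LOW_QUALITY` when `r2 < r2Min`;
#'   `"missing"` returns `NA` for such records (pipeline mode).
#' @return integer ALT counts (0, 1, 2) with `NA` for no-calls.
#' @export
#' @examples
#' hardCall(c(0.02, 1.05, 1.5), r2 = 0.95)
hardCall <- function(dosage, r2, r2Min = 0.8, window = 0.4,
                     lowR2 = c("error", "missing")) {
  lowR2 <- match.arg(lowR2)
  if (any(!is.na(dosage) & (dosage < 0 | dosage > 2)))
    stop("dosage outside [0, 2]", call. = FALSE)
  n <- max(length(dosage), length(r2))
  dosage <- rep_len(dosage, n)
  r2 <- rep_len(r2, n)
  low <- !is.na(r2) & r2 < r2Min
  if (any(low) && lowR2 == "error")
    stop(sprintf("LOW_QUALITY: %d dosage record(s) below R2 floor %.2f",
                 sum(low), r2Min), call. = FALSE)
  g <- as.integer(round(dosage))
  g[is.na(dosage) | abs(dosage - round(dosage)) > window | low | is.na(r2)] <- NA_integer_
  g
}

#' Verify a provided APOE genotype against a partial WES rs429358 call
#'
#' WES data covering only rs429358 carry the \eqn{\epsilon}4 arm but cannot
#' distinguish \eqn{\epsilon}2 from \eqn{\epsilon}3, so they can only verify a
#' provided 3/3, 3/4 or 4/4 genotype: the provided \eqn{\epsilon}4 count must
#' equal the WES ALT (C) count. Any provided genotype containing
#' \eqn{\epsilon}2 is non-informative.
#'
#' @param provided character vector of provided APOE genotypes (canonical).
#' @param wesAlt429358 integer WES ALT counts at rs429358 (0, 1, 2).
#' @param onMissing `"error"` (default) raises `MISSING_INPUT` on `NA` input;
#'   `"na"` propagates `NA`.
#' @return character vector in `{"CONFIRMED", "CONTRADICTED",
#'   "NON_INFORMATIVE"}`.
#' @export
#' @examples
#' wesVerifies(c("e3/e4", "e4/e4", "e2/e3"), c(1, 1, 0))
wesVerifies <- function(provided, wesAlt429358,
                        onMissing = c("error", "na")) {
  onMissing <- match.arg(onMissing)
  n <- max(length(provided), length(wesAlt429358))
  provided <- rep_len(parseApoe(provided, quiet = TRUE), n)
  wes <- rep_len(.checkAltCount(wesAlt429358, "wesAlt429358"), n)
  miss <- is.na(provided) | is.na(wes)
  if (any(miss) && onMissing == "error")
    stop("MISSING_INPUT: missing provided genotype or WES call", call. = FALSE)
  out <- rep(NA_character_, n)
  hasE2 <- apoeAlleleCount(provided, "e2") > 0L
  e4 <- apoeAlleleCount(provided, "e4")
  out[!miss & hasE2] <- "NON_INFORMATIVE"
  comp <- !miss & !hasE2
  out[comp] <- ifelse(e4[comp] == wes[comp], "CONFIRMED", "CONTRADICTED")
  out
}
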