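## Two-locus haplotype frequency estimation (EM over unphased genotypes),
## D/D', and construction of the phase-guaranteed analysis strata.

#' Collapse APOE genotypes to a biallelic focal-allele count
#'
#' LD between rs439401 and one epsilon allele is computed on a biallelic
#' collapse: the focal allele (e.g. \eqn{\epsilon}3) versus everything else.
#'
#' @param g character vector of canonical APOE genotypes.
#' @param allele focal allele, `"e3"` (default), `"e4"` or `"e2"`.
#' @return integer counts 0/1/2 of the focal allele.
#' @export
apoeBiallelic <- function(g, allele = c("e3", "e4", "e2")) {
  apoeAlleleCount(g, match.arg(allele))
}

#' Cross-tabulate two loci of unphased allele counts
#'
#' @param a,b integer vectors of allele counts (0, 1, 2); pairs with any
#'   missing value are dropped.
#' @return 3x3 integer matrix, rows = count of A, cols = count of B.
#' @export
genotypeCounts <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  table(factor(a[keep], 0:2), factor(b[keep], 0:2))
}

## observed-data multinomial log-likelihood of a 3x3 genotype table under
## random union of haplotypes with frequencies p = c(AB, Ab, aB, ab)
.glogLik <- function(counts, p) {
  pAB <- p[1]; pAb <- p[2]; paB <- p[3]; pab <- p[4]
  P <- matrix(0, 3, 3)
  P[1, 1] <- pab^2;        P[1, 2] <- 2 * pab * paB;  P[1, 3] <- paB^2
  P[2, 1] <- 2 * pab * pAb; P[2, 3] <- 2 * paB * pAB
  P[2, 2] <- 2 * (pAB * pab + pAb * paB)
  P[3, 1] <- pAb^2;        P[3, 2] <- 2 * pAb * pAB;  P[3, 3] <- pAB^2
  sum(counts[counts > 0] * log(P[counts > 0]))
}

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Only the double-heterozygote cell of the 3x3 genotype table has latent
#' phase; EM fractionally assigns it between the coupling (AB/ab) and
#' repulsion (Ab/aB) configurations. Initialization is at linkage
#' equilibrium; iteration stops when the largest frequency change falls
#' below `tol` (default 1e-8) or after `maxIter` iterations. The
#' observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param counts 3x3 matrix of genotype counts (rows = ALT count at locus A,
#'   cols = locus B), e.g. from [genotypeCounts()].
#' @param tol convergence tolerance on the frequencies.
#' @param maxIter iteration cap.
#' @return a [HaplotypeFreqs-class] object.
#' @export
emHaplotypeFreqs <- function(counts, tol = 1e-8, maxIter = 1000L) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3L, 3L)), all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("EMPTY_TABLE: no genotyped individuals", call. = FALSE)
  nh <- 2 * n

  ## phase-known haplotype contributions; cell [2,2] (double het) is latent
  i <- function(r, c) counts[r, c]
  kAB <- 2 * i(3, 3) + i(3, 2) + i(2, 3)
  kAb <- 2 * i(3, 1) + i(3, 2) + i(2, 1)
  kaB <- 2 * i(1, 3) + i(1, 2) + i(2, 3)
  kab <- 2 * i(1, 1) + i(1, 2) + i(2, 1)
  ndh <- i(2, 2)

  pA <- (kAB + kAb + ndh) / nh
  pB <- (kAB + kaB + ndh) / nh
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))

  iter <- 0L
  repeat {
    iter <- iter + 1L
    num <- p["AB"] * p["ab"]
    den <- num + p["Ab"] * p["aB"]
    w <- if (den > 0) as.numeric(num / den) else 0.5
    pNew <- c(AB = (kAB + w * ndh) / nh,
              Ab = (kAb + (1 - w) * ndh) / nh,
              aB = (kaB + (1 - w) * ndh) / nh,
              ab = (kab + w * ndh) / nh)
    delta <- max(abs(pNew - p))
    p <- pNew
    if (delta < tol || iter >= maxIter) break
  }

  new("HaplotypeFreqs", freqs = p, loglik = .glogLik(counts, p),
      nIter = iter, n = n)
}

#' @rdname HaplotypeFreqs-class
#' @aliases haplotypeFreqs,HaplotypeFreqs-method
setMethod("haplotypeFreqs", "HaplotypeFreqs", function(object) object@freqs)

setMethod("show", "HaplotypeFreqs", function(object) {
  f <- object@freqs
  cat(sprintf("HaplotypeFreqs (n = %g, %d EM iteration%s)\n", object@n,
              object@nIter, if (object@nIter > 1) "s" else ""))
  print(round(f, 5))
  pA <- f[["AB"]] + f[["Ab"]]; pB <- f[["AB"]] + f[["aB"]]
  ok <- pA > 0 && pA < 1 && pB > 0 && pB < 1
  cat(sprintf("  pA = %.4f  pB = %.4f  D = %.5f  D' = %s\n", pA, pB,
              f[["AB"]] - pA * pB,
              if (ok) sprintf("%.4f", dprime(object)) else "NA (monomorphic)"))
  invisible(NULL)
})

#' @describeIn dprime `D = p_AB - p_A p_B`, normalized by
#'   `Dmax = min(p_A(1-p_B), (1-p_A)p_B)` when `D > 0` and
#'   `min(p_A p_B, (1-p_A)(1-p_B))` when `D < 0`; `D = 0` returns 0.
#'   Errors with `MONOMORPHIC` if either locus has no variation.
#' @export
setMethod("dprime", "HaplotypeFreqs", function(object) {
  f <- object@freqs
  pA <- f[["AB"]] + f[["Ab"]]; pB <- f[["AB"]] + f[["aB"]]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("MONOMORPHIC: D' undefined when a locus has no variation",
         call. = FALSE)
  D <- f[["AB"]] - pA * pB
  if (D == 0) return(0)
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else       min(pA * pB, (1 - pA) * (1 - pB))
  D / dmax
})

#' Assign subjects to the phase-guaranteed analysis strata
#'
#' Builds the five analysis strata from adjudicated records with rs439401
#' calls. In \eqn{\epsilon}4/4 carriers both backgrounds are
#' \eqn{\epsilon}4, so any T allele is necessarily in phase with
#' \eqn{\epsilon}4 and an additive coding is valid. In \eqn{\epsilon}3/4
#' heterozygotes a single T may sit on either background, so the
#' phase-guaranteed design contrasts wild-type C/C (coded 0) against
#' homozygote T/T (coded 1), dropping heterozygotes. Additive
#' \eqn{\epsilon}3/4 and \eqn{\epsilon}3/3 strata and a full-sample stratum
#' (additive T count with \eqn{\epsilon}2/\eqn{\epsilon}4 dosage covariates)
#' complete the design. \eqn{\epsilon}2/4 carriers enter no stratum.
#'
#' @param recs data.frame of retained subjects (e.g. [analysisSet()]) with
#'   columns `apoe` and `rs439401`; rows with a missing rs439401 call are
#'   dropped.
#' @return named list of data.tables (`E44_ADDITIVE`, `E34_WT_VS_HOM`,
#'   `E34_ADDITIVE`, `E33_ADDITIVE`, `FULL_ADJUSTED`), each with the
#'   genotype coding `gcode`, the raw T count `tcount`, and (full stratum)
#'   `e2dos`/`e4dos`.
#' @export
assignStrata <- function(recs) {
  d <- as.data.table(recs)
  stopifnot(all(c("apoe", "rs439401") %in% names(d)))
  d <- d[!is.na(apoe) & !is.na(rs439401)]
  d[, tcount := as.integer(rs439401)]

  out <- list()
  out$E44_ADDITIVE <- d[apoe == "e4/e4"][, gcode := tcount]
  e34 <- d[apoe == "e3/e4"]
  out$E34_WT_VS_HOM <- e34[tcount %in% c(0L, 2L)][, gcode := tcount %/% 2L]
  out$E34_ADDITIVE <- copy(e34)[, gcode := tcount]
  out$E33_ADDITIVE <- d[apoe == "e3/e3"][, gcode := tcount]
  full <- d[apoe != "e2/e4"]
  full[, `:=`(gcode = tcount,
              e2dos = apoeAlleleCount(apoe, "e2"),
              e4dos = apoeAlleleCount(apoe, "e4"))]
  out$FULL_ADJUSTED <- full
  lapply(out, function(x) x[])
}
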