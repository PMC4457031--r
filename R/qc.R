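#' Segregation-ratio goodness-of-fit test
#'
#' Pearson chi-square (no continuity correction) of the observed
#' (unaffected, affected) counts among phenotyped F2 individuals against an
#' expected ratio, 3:1 by default as for a fully penetrant autosomal
#' recessive trait.
#'
#' @param ped a [pedigree()].
#' @param expected_ratio length-2 ratio (unaffected : affected).
#' @return list with \code{chi_square}, \code{df}, \code{p},
#'   \code{counts}, \code{expected}.
#' @export
segregation_test <- function(ped, expected_ratio = c(3, 1)) {
  f2 <- ped[ped$generation == "F2" & ped$phenotype != "unknown", ]
  if (nrow(f2) == 0L) stop("no phenotyped F2 individuals")
  counts <- c(unaffected = sum(f2$phenotype == "unaffected"),
              affected = sum(f2$phenotype == "affected"))
  ct <- stats::chisq.test(counts, p = expected_ratio / sum(expected_ratio))
  list(chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, counts = counts, expected = unname(ct$expected))
}

# Pearson HWE chi-square (1 df, no correction) on genotype counts
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0L) return(1)
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  exp_cnt <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - exp_cnt)^2 / exp_cnt)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' SNP marker quality control
#'
#' Removes markers with call rate below \code{call_rate_min}, minor allele
#' frequency below \code{maf_min}, Hardy-Weinberg equilibrium p-value below
#' \code{hwe_p_min} (Pearson chi-square on genotype counts over all
#' genotyped individuals), or unknown genomic position. Boundary semantics
#' are literal: values exactly at a threshold are kept. Idempotent: a second
#' application removes nothing.
#'
#' @param genotypes a [genotype_matrix()].
#' @param call_rate_min,maf_min,hwe_p_min thresholds.
#' @return list with \code{genotypes} (filtered) and \code{report}
#'   (per-marker data frame: call_rate, maf, hwe_p, kept, reason).
#' @export
qc_filter_markers <- function(genotypes, call_rate_min = 0.90,
                              maf_min = 0.05, hwe_p_min = 1e-6) {
  dos <- genotypes$dosage
  if (ncol(dos) == 0L) stop("genotype matrix has no markers")
  call_rate <- colMeans(!is.na(dos))
  p_b <- colMeans(dos, na.rm = TRUE) / 2
  p_b[is.nan(p_b)] <- 0
  maf <- pmin(p_b, 1 - p_b)
  hwe_p <- vapply(seq_len(ncol(dos)), function(m) {
    d <- dos[, m]
    hwe_chisq_p(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                sum(d == 2L, na.rm = TRUE))
  }, numeric(1L))
  pos_known <- !is.na(genotypes$markers$chrom) & !is.na(genotypes$markers$bp)
  reason <- rep(NA_character_, ncol(dos))
  reason[hwe_p < hwe_p_min] <- "hwe"
  reason[maf < maf_min] <- "maf"
  reason[call_rate < call_rate_min] <- "call_rate"
  reason[!pos_known] <- "position"
  kept <- is.na(reason)
  report <- data.frame(
    marker = genotypes$markers$id, call_rate = call_rate, maf = maf,
    hwe_p = hwe_p, kept = kept, reason = reason, stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  out <- genotype_matrix(genotypes$markers[kept, , drop = FALSE],
                         genotypes$dosage[, kept, drop = FALSE])
  list(genotypes = out, report = report)
}

#' Differential-missingness test (phenotype vs genotyping failure)
#'
#' Fisher exact test on the per-marker 2x2 table of (missing / called) x
#' (affected / unaffected), as used to detect phenotype-correlated
#' genotyping failure before association.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotype named vector over (a subset of) the genotyped
#'   individuals; values "affected"/"unaffected", logical, or 0/1
#'   (1 = affected).
#' @return named numeric vector of two-sided Fisher p-values per marker.
#' @export
differential_missingness_test <- function(genotypes, phenotype) {
  aff <- normalize_phenotype(phenotype)
  ids <- intersect(names(aff), rownames(genotypes$dosage))
  aff <- aff[ids]
  if (length(unique(aff)) < 2L)
    stop("phenotype has a single class; test undefined")
  dos <- genotypes$dosage[ids, , drop = FALSE]
  vapply(seq_len(ncol(dos)), function(m) {
    miss <- is.na(dos[, m])
    tab <- table(factor(miss, c(TRUE, FALSE)), factor(aff, c(1, 0)))
    stats::fisher.test(tab)$p.value
  }, numeric(1L)) -> p
  names(p) <- genotypes$markers$id
  p
}

# accepts "affected"/"unaffected"/"unknown", logical, or 0/1; returns named
# 0/1 vector with unknowns dropped
normalize_phenotype <- function(phenotype) {
  if (is.null(names(phenotype)))
    stop("phenotype must be a named vector (names = individual ids)")
  x <- if (is.character(phenotype)) {
    out <- ifelse(phenotype == "affected", 1,
                  ifelse(phenotype == "unaffected", 0, NA))
    out
  } else as.numeric(phenotype)
  x <- stats::setNames(x, names(phenotype))
  x[!is.na(x)]
}

# phenotype vector of the phenotyped F2s in a pedigree
f2_phenotype <- function(ped) {
  f2 <- ped[ped$generation == "F2", ]
  normalize_phenotype(stats::setNames(f2$phenotype, f2$id))
}
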