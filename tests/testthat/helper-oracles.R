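# Independent oracles and fixture builders shared across tests.
# Oracles are deliberately written from first principles (enumeration,
# closed forms, identities) so they never share code with the package paths
# they check.

# brute-force two-sided Fisher p for a 2x2 table [[a,b],[c,d]]:
# enumerate all tables with the same margins, sum probabilities (computed
# with choose()) not exceeding the observed table's probability
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, prob, numeric(1))
  p_obs <- prob(a)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# hand Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# exhaustive hypergeometric upper tail: P(overlap >= k) drawing q from a
# universe of m set genes and n non-set genes
hyper_upper_oracle <- function(k, m, n, q) {
  xs <- k:min(m, q)
  sum(choose(m, xs) * choose(n, q - xs)) / choose(m + n, q)
}

# equal-expression law via the negative-binomial identity:
# p(y | x) = dnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
ac_oracle <- function(x, y, n1, n2) {
  pr <- n1 / (n1 + n2)
  pointwise <- stats::dnbinom(y, size = x + 1, prob = pr)
  lower <- stats::pnbinom(y, size = x + 1, prob = pr)
  upper <- 1 - stats::pnbinom(y - 1, size = x + 1, prob = pr)
  list(pointwise = pointwise,
       p = min(1, 2 * min(lower, upper)))
}

# hand codon-table translation, first ORF from base 1, stops at "*"
translate_oracle <- function(seq) {
  codon_table <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  n_cod <- nchar(seq) %/% 3
  aa <- character(0)
  stop_at <- NA_integer_
  for (i in seq_len(n_cod)) {
    cd <- substr(seq, 3 * i - 2, 3 * i)
    r <- codon_table[[cd]]
    if (r == "*") { stop_at <- i; break }
    aa <- c(aa, r)
  }
  list(protein = paste(aa, collapse = ""), stop_at = stop_at)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# 891-bp amplicon with a single SmaI site placed so the fragments are
# 438 + 453 bp (synthetic stand-in mirroring the assay's printed sizes)
rflp_fixture_891 <- function(seed = 42) {
  set.seed(seed)
  repeat {
    s <- random_dna(891)
    # site CCCGGG starting at base 436 cuts after base 438
    s <- paste0(substr(s, 1, 435), "CCCGGG", substr(s, 442, 891))
    if (length(gregexpr("CCCGGG", s, fixed = TRUE)[[1]]) == 1 &&
        gregexpr("CCCGGG", s, fixed = TRUE)[[1]][1] == 436)
      return(s)
  }
}

# tiny genotype_matrix from a dosage matrix (rows = individuals)
toy_genotypes <- function(dosage, bp = NULL, chrom = "1") {
  n_mark <- ncol(dosage)
  if (is.null(bp)) bp <- seq_len(n_mark) * 1000L
  markers <- data.frame(
    id = paste0("m", seq_len(n_mark)), chrom = chrom, bp = bp,
    allele_a = "A", allele_b = "C", stringsAsFactors = FALSE)
  genotype_matrix(markers, dosage)
}

# hand-built five-variant exclusion-cascade toy: one variant removed at each
# Mendelian step plus one fully compliant survivor
cascade_toy <- function() {
  df <- data.frame(
    chrom = "18", pos = c(100L, 200L, 300L, 400L, 500L),
    id = paste0("v", 1:5), ref = "A", alt = "G",
    qual = 50, depth = 30L,
    class = c("coding_nonsyn", "coding_nonsyn", "coding_nonsyn",
              "noncoding", "coding_truncating"),
    gene = paste0("G", 1:5),
    gt_affected = c("het", "homalt", "homalt", "homalt", "homalt"),
    gt_sire = c("het", "homalt", "homref", "het", "het"),
    gt_dam = c("het", "het", "homref", "het", "het"),
    dp_affected = 30L, dp_sire = 30L, dp_dam = 30L,
    gq_affected = 60L, gq_sire = 60L, gq_dam = 60L,
    stringsAsFactors = FALSE)
  attr(df, "samples") <- c("affected", "sire", "dam")
  class(df) <- c("variant_table", "data.frame")
  df
}
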