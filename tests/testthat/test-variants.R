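make_variants <- function(pos, depth = 30, qual = 50, chrom = "18") {
  n <- length(pos)
  df <- data.frame(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    id = sprintf("v%d", seq_len(n)),
    ref = rep_len("A", n), alt = rep_len("G", n),
    qual = rep_len(qual, n), depth = as.integer(rep_len(depth, n)),
    class = rep_len("coding_nonsyn", n), gene = rep_len("G1", n),
    gt_affected = rep_len("homalt", n), gt_sire = rep_len("het", n),
    gt_dam = rep_len("het", n),
    stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

test_that("site QC applies literal depth, spacing and quality boundaries", {
  v <- make_variants(c(100, 200, 300, 400), depth = c(5, 6, 70, 71))
  res <- variant_site_qc(v)
  expect_equal(res$variants$pos, c(200L, 300L))
  expect_equal(res$trace$n_removed[res$trace$step == "depth"], 2)
  # spacing: 103 is 3 bp from 100 -> removed; 200 kept
  v2 <- make_variants(c(100, 103, 200))
  res2 <- variant_site_qc(v2)
  expect_equal(res2$variants$pos, c(100L, 200L))
  # quality boundary: 20 kept, 19.9 removed
  v3 <- make_variants(c(100, 200), qual = c(20, 19.9))
  expect_equal(variant_site_qc(v3)$variants$pos, 100L)
  # empty input passes through with an all-zero trace
  res0 <- variant_site_qc(make_variants(integer(0)))
  expect_equal(nrow(res0$variants), 0L)
  expect_true(all(res0$trace$n_removed == 0))
  # unsorted input is an error
  expect_error(variant_site_qc(make_variants(c(200, 100))), "sorted")
  # counts conserve at every step
  expect_equal(res$trace$n_in, res$trace$n_removed + res$trace$n_out)
})

test_that("the Mendelian cascade removes one toy variant per step", {
  toy <- cascade_toy()
  res <- mendelian_recessive_filter(toy)
  expect_equal(res$trace$n_removed, rep(1L, 4))
  expect_equal(res$variants$id, "v5")
  expect_equal(res$trace$n_in, res$trace$n_removed + res$trace$n_out)
  # empty input -> all-zero trace
  res0 <- mendelian_recessive_filter(toy[0, ])
  expect_true(all(res0$trace$n_removed == 0))
  # missing genotype columns are an error
  expect_error(mendelian_recessive_filter(toy, affected_id = "nope"),
               "genotype column")
})

test_that("a missing genotype removes a variant instead of passing it", {
  toy <- cascade_toy()[5, ]  # the fully compliant survivor
  toy$gt_dam <- "missing"
  res <- mendelian_recessive_filter(toy)
  expect_equal(nrow(res$variants), 0L)
  expect_equal(res$trace$n_removed[res$trace$step == "parent_homalt"], 1L)
})

test_that("the population screen separates fixed from segregating alleles", {
  v <- make_variants(c(100, 200, 300))
  panel <- rbind(v1 = rep(0L, 24),                      # absent -> kept
                 v2 = c(rep(1L, 8), rep(0L, 16)),       # freq 1/6 -> removed
                 v3 = c(rep(1L, 2), rep(0L, 22)))       # freq 1/24 ambiguous
  expect_warning(res <- population_screen(v, panel), "ambiguous")
  expect_setequal(res$variants$id, c("v1", "v3"))
  expect_equal(res$variants$ambiguous, c(FALSE, TRUE))
  expect_equal(res$trace$n_removed, 1L)
  expect_error(population_screen(v, panel[, 0]), "empty")
})

test_that("cosegregation check enforces the recessive genotype pattern", {
  ped <- pedigree(data.frame(
    id = c("S", "D", "FS", "FD", "k1", "k2", "k3"),
    sire = c("0", "0", "S", "S", "FS", "FS", "FS"),
    dam = c("0", "0", "D", "D", "FD", "FD", "FD"),
    sex = c("M", "F", "M", "F", "M", "F", "M"),
    generation = c("F0", "F0", "F1", "F1", "F2", "F2", "F2"),
    phenotype = c("unaffected", "unaffected", "unaffected", "unaffected",
                  "affected", "unaffected", "unaffected"),
    stringsAsFactors = FALSE))
  g <- c(S = "het", D = "het", FS = "het", FD = "het",
         k1 = "homalt", k2 = "het", k3 = "homref")
  res <- cosegregation_check(ped, g)
  expect_true(res$passes)
  g_bad <- g; g_bad[["k3"]] <- "homalt"
  res_bad <- cosegregation_check(ped, g_bad)
  expect_false(res_bad$passes)
  expect_match(res_bad$failures, "unaffected", all = FALSE)
  g_na <- g; g_na[["k1"]] <- "missing"
  expect_error(cosegregation_check(ped, g_na), "missing")
  # dosage coding is accepted too
  g_num <- c(S = 1, D = 1, FS = 1, FD = 1, k1 = 2, k2 = 1, k3 = 0)
  expect_true(cosegregation_check(ped, g_num)$passes)
})

test_that("in-silico digestion cuts where the site arithmetic says", {
  expect_equal(insilico_rflp("ACGTACGT"), 8L)  # no site -> whole length
  expect_equal(insilico_rflp("ACCCGGGT"), c(4L, 4L))
  expect_error(insilico_rflp("ACGN"), "non-ACGT")
  # fragments sum to length and count occurrences + 1 (palindromic sites)
  set.seed(31)
  for (i in 1:25) {
    half <- random_dna(3)
    site <- paste0(half, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(half))))
    s <- random_dna(400)
    fr <- insilico_rflp(s, site, 3L)
    n_sites <- sum(unlist(gregexpr(site, s, fixed = TRUE)) > 0)
    expect_equal(sum(fr), 400L)
    expect_equal(length(fr), n_sites + 1L)
  }
})

test_that("the two-allele amplicon digest mirrors the assay design", {
  mut <- rflp_fixture_891()
  expect_equal(insilico_rflp(mut), c(438L, 453L))
  # ablating the site models the wild-type allele: one uncut fragment
  wt <- sub("CCCGGG", "CCCGAG", mut, fixed = TRUE)
  expect_equal(insilico_rflp(wt), 891L)
})

test_that("truncation prediction matches a hand-translation oracle", {
  set.seed(17)
  # synonymous edit: protein unchanged, no premature stop
  cds <- paste0("ATG", "CTT", "GGA", "AAA", "TAA")  # M L G K *
  res <- predict_truncation(cds, list(position = 6, deleted = "T",
                                      inserted = "G"))  # CTT -> CTG (Leu)
  expect_equal(res$protein, "MLGK")
  expect_false(res$premature)
  # immediate in-frame stop at codon 2
  res2 <- predict_truncation(cds, list(position = 4, deleted = "CTT",
                                       inserted = "TAA"))
  expect_equal(res2$termination_residue, 2L)
  expect_true(res2$premature)
  # random frameshifting delins edits against the brute-force oracle
  for (i in 1:20) {
    n_cod <- sample(20:60, 1)
    body <- paste(sample(c("CTT", "GGA", "AAA", "TCC", "GAT", "TGG"),
                         n_cod, replace = TRUE), collapse = "")
    cds_i <- paste0("ATG", body, "TAA")
    pos <- sample(4:(nchar(cds_i) - 6), 1)
    del <- substr(cds_i, pos, pos)
    ins <- paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                 collapse = "")
    got <- predict_truncation(cds_i, list(position = pos, deleted = del,
                                          inserted = ins))
    edited <- paste0(substr(cds_i, 1, pos - 1), ins,
                     substr(cds_i, pos + 1, nchar(cds_i)))
    oracle <- translate_oracle(edited)
    expect_equal(got$termination_residue, oracle$stop_at)
    expect_equal(got$protein, oracle$protein)
  }
  expect_error(predict_truncation(cds, list(position = 99, deleted = "A",
                                            inserted = "T")), "beyond")
  expect_error(predict_truncation("TTGAAA", list(position = 1,
                                                 deleted = "T",
                                                 inserted = "A")), "ATG")
})
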