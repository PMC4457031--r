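# minimal pedigree: founders fixed for opposite alleles at every marker
tiny_cross <- function(f2_dosage, bp = NULL) {
  n_f2 <- nrow(f2_dosage)
  ids <- c("A0", "B0", "S1", "D1", sprintf("X%02d", seq_len(n_f2)))
  ped <- pedigree(data.frame(
    id = ids,
    sire = c("0", "0", "A0", "A0", rep("S1", n_f2)),
    dam = c("0", "0", "B0", "B0", rep("D1", n_f2)),
    sex = c("M", "F", "M", "F", rep("F", n_f2)),
    generation = c("F0", "F0", "F1", "F1", rep("F2", n_f2)),
    phenotype = "unknown", stringsAsFactors = FALSE))
  n_mark <- ncol(f2_dosage)
  dos <- rbind(matrix(rep(c(0L, 2L, 1L, 1L), n_mark), nrow = 4),
               f2_dosage)
  rownames(dos) <- ids
  list(ped = ped, gm = toy_genotypes(dos, bp = bp))
}

test_that("a fully informative marker forces founder origin", {
  tc <- tiny_cross(matrix(c(2L, 0L, 1L), nrow = 3, ncol = 3))
  ori <- infer_founder_origin(tc$ped, tc$gm)
  expect_equal(unname(ori$dosage_b["X01", ]), rep(2, 3))  # dosage 2 -> B,B
  expect_true(all(ori$paternal["X01", ] == "B" &
                    ori$maternal["X01", ] == "B"))
  expect_equal(unname(ori$dosage_b["X02", ]), rep(0, 3))
  expect_equal(unname(ori$dosage_b["X03", ]), rep(1, 3))
})

test_that("identical founders leave all origins unknown", {
  tc <- tiny_cross(matrix(1L, nrow = 2, ncol = 4))
  gm <- tc$gm
  gm$dosage["B0", ] <- 0L  # make founders identical (both hom A)
  gm$dosage["S1", ] <- 0L
  gm$dosage["D1", ] <- 0L
  ori <- infer_founder_origin(tc$ped, gm)
  expect_true(all(ori$paternal == "unknown"))
  expect_true(all(is.na(ori$dosage_b)))
})

test_that("inferred origins track the simulated truth", {
  sim <- simulate_f2_cross(seed = 11, n_f2 = 60, n_markers = 500,
                           genotype_error_rate = 0, missing_rate = 0)
  ori <- infer_founder_origin(sim$pedigree, sim$genotypes)
  td <- (sim$truth$pat_origin == "B") + (sim$truth$mat_origin == "B")
  acc <- mean(ori$dosage_b[rownames(td), ] == td, na.rm = TRUE)
  expect_gte(acc, 0.99)
})

test_that("trend-scan statistics equal the simple-regression oracle", {
  mk <- data.frame(id = "m1", chrom = "1", bp = 1000,
                   allele_a = "A", allele_b = "C",
                   stringsAsFactors = FALSE)
  dose <- matrix(c(2, 2, 1, 1, 0, 0), ncol = 1,
                 dimnames = list(sprintf("X%02d", 1:6), "m1"))
  origins <- structure(list(dosage_b = dose, markers = mk),
                       class = "founder_origin")
  phen <- stats::setNames(c(1, 1, 0, 0, 0, 0), rownames(dose))
  scan <- origin_association_scan(origins, phen)
  fit <- summary(stats::lm(phen ~ dose[, 1]))
  expect_equal(scan$results$stat, fit$coefficients[2, "t value"],
               tolerance = 1e-10)
  expect_equal(scan$results$p, fit$coefficients[2, "Pr(>|t|)"],
               tolerance = 1e-10)
  expect_equal(scan$threshold, 0.05 / 1)
})

test_that("two-sided p-values are invariant to swapping line labels", {
  sim <- simulate_f2_cross(seed = 12, n_f2 = 50, n_markers = 100)
  ori <- infer_founder_origin(sim$pedigree, sim$genotypes)
  phen <- stats::setNames(
    ifelse(sim$pedigree$phenotype == "affected", 1, 0)[
      sim$pedigree$generation == "F2"],
    sim$pedigree$id[sim$pedigree$generation == "F2"])
  s1 <- origin_association_scan(ori, phen)
  ori2 <- ori
  ori2$dosage_b <- 2 - ori$dosage_b
  s2 <- origin_association_scan(ori2, phen)
  expect_equal(s1$results$p, s2$results$p, tolerance = 1e-12)
})

test_that("the scan is calibrated under a permuted phenotype", {
  sim <- simulate_f2_cross(seed = 13, n_f2 = 75, n_markers = 600)
  ori <- infer_founder_origin(sim$pedigree, sim$genotypes)
  phen <- stats::setNames(
    ifelse(sim$pedigree$phenotype == "affected", 1, 0)[
      sim$pedigree$generation == "F2"],
    sim$pedigree$id[sim$pedigree$generation == "F2"])
  set.seed(77)
  fracs <- vapply(1:8, function(i) {
    perm <- stats::setNames(sample(phen), names(phen))
    s <- origin_association_scan(ori, perm)
    mean(s$results$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  # linked markers correlate, so only the mean rejection rate is stable
  expect_gt(mean(fracs), 0.005)
  expect_lt(mean(fracs), 0.15)
})

test_that("the Bonferroni threshold is exactly alpha over tested markers", {
  sim <- simulate_f2_cross(seed = 14, n_f2 = 40, n_markers = 120)
  ori <- infer_founder_origin(sim$pedigree, sim$genotypes)
  phen <- stats::setNames(
    ifelse(sim$pedigree$phenotype == "affected", 1, 0)[
      sim$pedigree$generation == "F2"],
    sim$pedigree$id[sim$pedigree$generation == "F2"])
  s <- origin_association_scan(ori, phen, alpha = 0.05)
  expect_identical(s$threshold, 0.05 / s$n_tests)
  expect_equal(sum(!is.na(s$results$p)), s$n_tests)
  expect_error(origin_association_scan(
    ori, stats::setNames(rep(0, length(phen)), names(phen))), "constant")
})

test_that("the top marker localizes the planted causal locus", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_f2_cross(seed = s, n_f2 = 75, n_markers = 800)
    ori <- infer_founder_origin(sim$pedigree, sim$genotypes)
    phen <- stats::setNames(
      ifelse(sim$pedigree$phenotype == "affected", 1, 0)[
        sim$pedigree$generation == "F2"],
      sim$pedigree$id[sim$pedigree$generation == "F2"])
    sc <- origin_association_scan(ori, phen)
    top <- sc$results[which.min(sc$results$p), ]
    abs(top$bp - sim$truth$causal_bp) <= 5e6
  }, logical(1))
  expect_gte(sum(hits), 4)
})
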