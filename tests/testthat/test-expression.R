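test_that("RPKM follows its defining arithmetic", {
  expect_equal(rpkm(10, 2e6, 500), 10)
  expect_equal(rpkm(0, 1e6, 500), 0)
  expect_equal(rpkm(20, 2e6, 500), 2 * rpkm(10, 2e6, 500))
  expect_equal(rpkm(10, 4e6, 500), rpkm(10, 2e6, 500) / 2)
  expect_error(rpkm(10, 0, 500), "N")
  expect_error(rpkm(10, 1e6, 0), "L")
  expect_error(rpkm(-1, 1e6, 500), "C")
})

test_that("equal-expression probabilities match their closed forms", {
  expect_equal(ac_equal_expression_test(0, 0, 1e6, 1e6)$pointwise, 0.5,
               tolerance = 1e-12)
  expect_equal(ac_equal_expression_test(1, 1, 1e6, 1e6)$pointwise, 0.25,
               tolerance = 1e-12)
  # equal libraries: pointwise p = C(x+y, x) / 2^(x+y+1)
  for (x in c(0, 3, 10, 25)) for (y in c(0, 2, 17, 30)) {
    expect_equal(ac_equal_expression_test(x, y, 5e5, 5e5)$pointwise,
                 choose(x + y, x) / 2^(x + y + 1), tolerance = 1e-12)
  }
})

test_that("pointwise law normalizes and matches the independent oracle", {
  for (ratio in c(0.5, 1, 2)) {
    n1 <- 1e6; n2 <- ratio * n1
    for (x in c(0, 5, 50)) {
      ks <- 0:(x + 400)
      pw <- vapply(ks, function(k)
        ac_equal_expression_test(x, k, n1, n2)$pointwise, numeric(1))
      expect_equal(sum(pw), 1, tolerance = 1e-10)
      oracle <- stats::dnbinom(ks, size = x + 1, prob = n1 / (n1 + n2))
      expect_lt(max(abs(pw - oracle)), 1e-12)
    }
  }
})

test_that("two-sided p is a valid probability and bounds its variants", {
  set.seed(5)
  for (i in 1:20) {
    x <- sample(0:80, 1); y <- sample(0:80, 1)
    n <- sample(c(5e5, 1e6), 1)
    p <- ac_equal_expression_test(x, y, n, n)$p
    expect_gte(p, 0); expect_lte(p, 1)
    # the test conditions on the first sample's count; the swapped call
    # conditions on the other and is a different (also valid) p-value
    ml <- ac_equal_expression_test(x, y, n, 2 * n,
                                   two_sided = "minlike")$p
    expect_lte(ml, 1)
    expect_gte(ml,
               ac_equal_expression_test(x, y, n, 2 * n)$pointwise - 1e-12)
  }
  expect_error(ac_equal_expression_test(-1, 0, 1e6, 1e6), "counts")
  expect_error(ac_equal_expression_test(0, 0, 0, 1e6), "totals")
})

test_that("BH adjustment equals the hand step-up computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(21)
  for (i in 1:10) {
    p <- stats::runif(sample(2:20, 1))^2
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  }
  p_tied <- c(0.5, 0.02, 0.02, 0.9)
  q <- bh_fdr(p_tied)
  expect_equal(q[2], q[3])
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
})

test_that("DEG calling honours thresholds, zeros and symmetry", {
  ct <- count_table(
    gene_id = c("both_zero", "wt_only", "mut_only", "balanced", "strong"),
    length_bp = c(500L, 500L, 500L, 1000L, 800L),
    count_wt = c(0L, 60L, 0L, 100L, 400L),
    count_mut = c(0L, 0L, 55L, 104L, 40L),
    n_wt = 1e6, n_mut = 1e6)
  res <- call_degs(ct)
  expect_false("both_zero" %in% res$gene_id)  # excluded before testing
  wt_only <- res[res$gene_id == "wt_only", ]
  expect_equal(wt_only$log2_ratio, Inf)
  expect_equal(wt_only$call, "down_in_mutant")  # zero passes fold criterion
  expect_equal(res[res$gene_id == "mut_only", "call"], "up_in_mutant")
  expect_equal(res[res$gene_id == "balanced", "call"], "ns")
  expect_equal(res[res$gene_id == "strong", "call"], "down_in_mutant")
  # gene order does not change the calls
  ct_perm <- count_table(ct$gene_id[c(3, 5, 1, 2, 4)],
                         ct$length_bp[c(3, 5, 1, 2, 4)],
                         ct$count_wt[c(3, 5, 1, 2, 4)],
                         ct$count_mut[c(3, 5, 1, 2, 4)],
                         n_wt = 1e6, n_mut = 1e6)
  res_perm <- call_degs(ct_perm)
  expect_equal(res_perm$call[match(res$gene_id, res_perm$gene_id)],
               res$call)
  # swapping the samples flips the log2 ratio sign
  ct_swap <- count_table(ct$gene_id, ct$length_bp, ct$count_mut,
                         ct$count_wt, n_wt = 1e6, n_mut = 1e6)
  res_swap <- call_degs(ct_swap)
  expect_equal(res_swap$log2_ratio[match(res$gene_id, res_swap$gene_id)],
               -res$log2_ratio)
  # boundary semantics: q exactly at 0.001 and |log2| exactly 1 pass
  expect_error(call_degs(ct[0, ]), "empty")
})

test_that("boundary q and log2 values count as significant", {
  # construct the decision rule directly: the call must flip only beyond
  # the thresholds, not at them
  ct <- count_table("g", 1000L, 200L, 100L, n_wt = 1e6, n_mut = 1e6)
  res <- call_degs(ct, fdr_max = res_q <- call_degs(ct)$q,
                   min_abs_log2 = 1)
  expect_equal(res$log2_ratio, 1)  # 200 vs 100 at equal totals
  expect_false(res$call == "ns")   # q == fdr_max and |log2| == 1 pass
})

test_that("DEG list merging reproduces the union arithmetic", {
  a <- sprintf("gA%03d", 1:174)
  b <- c(sprintf("GA%03d", 1:7), sprintf("gB%03d", 1:163))  # 7 shared
  m <- merge_deg_lists(a, b)
  expect_equal(nrow(m), 337L)
  expect_equal(sum(m$provenance == "both"), 7L)
  expect_equal(nrow(merge_deg_lists(c("x", "y"), c("z"))), 3L)
  expect_equal(nrow(merge_deg_lists(a, a)), 174L)
})

test_that("2^-ddCt fold changes follow the closed form", {
  qpcr <- data.frame(
    gene = rep(c("g1", "g2", "g3"), each = 4),
    group = rep(rep(c("wildtype", "mutant"), each = 2), 3),
    target_ct = c(20, 20, 21, 21,    # g1: dCt 5 -> 6, ddCt 1
                  20, 20, 19, 19,    # g2: ddCt 0
                  25, 25, 21, 21),   # g3: ddCt -2
    reference_ct = c(15, 15, 15, 15,
                     18, 18, 17, 17,
                     12, 12, 10, 10),
    stringsAsFactors = FALSE)
  res <- ddct_fold_change(qpcr)
  expect_equal(res$fold_change[res$gene == "g1"], 0.5)
  expect_equal(res$fold_change[res$gene == "g2"], 1.0)
  expect_equal(res$fold_change[res$gene == "g3"], 4.0)
  expect_error(ddct_fold_change(qpcr[, -4]), "columns")
})

test_that("over-representation p equals the exhaustive tail sum", {
  uni <- sprintf("u%03d", 1:100)
  gs <- uni[1:10]
  query <- c(uni[1:6], uni[50:63])  # 20 genes, overlap 6
  res <- overrepresentation_test(query, gs, uni)
  expect_equal(res$p, hyper_upper_oracle(6, 10, 90, 20), tolerance = 1e-12)
  expect_equal(res$ratio, "6/10")
  # gene set = universe -> overlap is certain
  expect_equal(overrepresentation_test(query, uni, uni)$p, 1)
  # zero overlap with a nonempty set
  res0 <- overrepresentation_test(uni[90:99], uni[1:10], uni)
  expect_equal(res0$ratio, "0/10")
  expect_gt(res0$p, 0.3)
  expect_error(overrepresentation_test(query, gs, character(0)), "universe")
})
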