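#' RPKM: reads per kilobase of transcript per million mapped reads
#'
#' \code{1e9 * C / (N * L)} for \code{C} reads uniquely aligned to a gene of
#' length \code{L} bases in a library of \code{N} uniquely aligned reads.
#'
#' @param C read count(s), >= 0.
#' @param N library total(s), >= 1.
#' @param L gene length(s) in bp, >= 1.
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(C, N, L) {
  if (any(N < 1)) stop("library total N must be >= 1")
  if (any(L < 1)) stop("gene length L must be >= 1")
  if (any(C < 0)) stop("count C must be >= 0")
  1e9 * as.numeric(C) / (as.numeric(N) * as.numeric(L))
}

#' Exact equal-expression test for two count libraries (Poisson model)
#'
#' Under equal expression, the count \code{y} in library 2 given \code{x}
#' in library 1 follows the law
#' \deqn{p(y | x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' for libraries of \code{N1} and \code{N2} total reads. Computed in log
#' space; overflow is a defect, never an error return. The two-sided
#' p-value doubles the smaller tail (default) or sums all outcomes no more
#' likely than the observed one ("minlike").
#'
#' @param x,y observed counts (vectors allowed, recycled together).
#' @param n1,n2 library totals.
#' @param two_sided "doubled_tail" or "minlike".
#' @return data frame with columns \code{pointwise} (p(y|x)) and \code{p}
#'   (two-sided p-value), one row per gene.
#' @export
ac_equal_expression_test <- function(x, y, n1, n2,
                                     two_sided = c("doubled_tail",
                                                   "minlike")) {
  two_sided <- match.arg(two_sided)
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  if (any(n1 < 1) || any(n2 < 1)) stop("library totals must be >= 1")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  log_point <- function(x, k, lr, l1r) {
    # log p(k | x); lr = log(n2/n1), l1r = log(1 + n2/n1)
    k * lr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * l1r
  }
  pointwise <- p <- numeric(n)
  for (i in seq_len(n)) {
    lr <- log(n2[i]) - log(n1[i])
    l1r <- log1p(n2[i] / n1[i])
    ks <- 0:y[i]
    lp <- log_point(x[i], ks, lr, l1r)
    pw <- exp(lp[length(lp)])
    pointwise[i] <- pw
    cum <- sum(exp(lp))                        # P(Y <= y)
    lower <- min(cum, 1)
    upper <- min(max(1 - (cum - pw), pw), 1)   # P(Y >= y), >= pointwise
    if (two_sided == "doubled_tail") {
      p[i] <- min(1, 2 * min(lower, upper))
    } else {
      # sum of all outcomes with probability <= p(y) (small tolerance for
      # ties under floating point)
      k_max <- max(y[i], stats::qnbinom(1e-14, size = x[i] + 1,
                                        prob = n1[i] / (n1[i] + n2[i]),
                                        lower.tail = FALSE)) + 10
      lp_all <- log_point(x[i], 0:k_max, lr, l1r)
      p[i] <- min(1, sum(exp(lp_all[lp_all <= lp[length(lp)] +
                                      1e-7])))
    }
  }
  data.frame(pointwise = pointwise, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values with enforced monotonicity; tied p-values receive
#' identical q-values and the result is invariant to input order.
#'
#' @param p_values numeric vector in [0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' Computes RPKM for both libraries, the exact Poisson equal-expression
#' p-value per gene, BH q-values, and calls a gene differentially expressed
#' when \code{q <= fdr_max} AND \code{|log2 ratio| >= min_abs_log2}
#' (boundary values pass). The log2 ratio is wild-type over mutant; calls
#' are labelled relative to the mutant sample. Genes with zero counts in
#' both libraries are excluded before testing; a zero in exactly one
#' library yields an infinite log2 ratio, which passes the fold-change
#' criterion automatically.
#'
#' @param counts a [count_table()].
#' @param fdr_max FDR threshold (default 0.001).
#' @param min_abs_log2 minimum |log2 ratio| (default 1).
#' @param two_sided two-sided convention of the exact test.
#' @return A \code{deg_result} data frame: gene_id, counts, rpkm_wt,
#'   rpkm_mut, log2_ratio, p, q, call (up_in_mutant / down_in_mutant / ns).
#' @export
call_degs <- function(counts, fdr_max = 0.001, min_abs_log2 = 1,
                      two_sided = "doubled_tail") {
  if (nrow(counts) == 0L) stop("empty count table")
  n1 <- attr(counts, "n_wt"); n2 <- attr(counts, "n_mut")
  keep <- counts$count_wt + counts$count_mut > 0L
  df <- counts[keep, , drop = FALSE]
  rpkm_wt <- rpkm(df$count_wt, n1, df$length_bp)
  rpkm_mut <- rpkm(df$count_mut, n2, df$length_bp)
  log2_ratio <- log2(rpkm_wt / rpkm_mut)
  ac <- ac_equal_expression_test(df$count_wt, df$count_mut, n1, n2,
                                 two_sided = two_sided)
  q <- bh_fdr(ac$p)
  sig <- q <= fdr_max & abs(log2_ratio) >= min_abs_log2
  call <- ifelse(!sig, "ns",
                 ifelse(log2_ratio > 0, "down_in_mutant", "up_in_mutant"))
  out <- data.frame(gene_id = df$gene_id, length_bp = df$length_bp,
                    count_wt = df$count_wt, count_mut = df$count_mut,
                    rpkm_wt = rpkm_wt, rpkm_mut = rpkm_mut,
                    log2_ratio = log2_ratio, p = ac$p, q = q, call = call,
                    stringsAsFactors = FALSE)
  class(out) <- c("deg_result", "data.frame")
  attr(out, "n_wt") <- n1; attr(out, "n_mut") <- n2
  out
}

#' Merge two DEG lists by identifier
#'
#' Set union keyed on case-folded gene identifiers, recording per-gene
#' provenance (a / b / both). The first-seen spelling is kept.
#'
#' @param list_a,list_b character vectors of gene identifiers (or data
#'   frames with a \code{gene_id} column).
#' @return data frame with \code{gene_id} and \code{provenance}.
#' @export
merge_deg_lists <- function(list_a, list_b) {
  ids_of <- function(x) if (is.data.frame(x)) x$gene_id else as.character(x)
  a <- ids_of(list_a); b <- ids_of(list_b)
  a <- a[!duplicated(tolower(a))]
  b <- b[!duplicated(tolower(b))]
  key_a <- tolower(a); key_b <- tolower(b)
  all_ids <- c(a, b[!(key_b %in% key_a)])
  key <- tolower(all_ids)
  provenance <- ifelse(key %in% key_a & key %in% key_b, "both",
                       ifelse(key %in% key_a, "a", "b"))
  data.frame(gene_id = all_ids, provenance = provenance,
             stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per gene: dCt = mean target Ct - mean reference Ct within each group;
#' ddCt = dCt(mutant) - dCt(wild-type); fold change = 2^-ddCt relative to
#' wild type.
#'
#' @param qpcr data frame with columns \code{gene}, \code{group}
#'   ("wildtype"/"mutant"), \code{target_ct}, \code{reference_ct}
#'   (one row per replicate).
#' @return data frame with \code{gene}, \code{ddct}, \code{fold_change}.
#' @export
ddct_fold_change <- function(qpcr) {
  needed <- c("gene", "group", "target_ct", "reference_ct")
  if (!all(needed %in% names(qpcr)))
    stop("qpcr needs columns: ", paste(needed, collapse = ", "))
  if (any(!is.finite(qpcr$target_ct)) || any(!is.finite(qpcr$reference_ct)))
    stop("Ct values must be finite")
  if (!all(c("wildtype", "mutant") %in% qpcr$group))
    stop("both groups (wildtype, mutant) required")
  genes <- unique(qpcr$gene)
  out <- lapply(genes, function(g) {
    sub <- qpcr[qpcr$gene == g, ]
    dct <- vapply(c("wildtype", "mutant"), function(grp) {
      s <- sub[sub$group == grp, ]
      if (nrow(s) == 0L)
        stop("gene ", g, " has no ", grp, " measurements")
      mean(s$target_ct) - mean(s$reference_ct)
    }, numeric(1L))
    ddct <- dct[["mutant"]] - dct[["wildtype"]]
    data.frame(gene = g, ddct = ddct, fold_change = 2^(-ddct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value for the overlap between a query set
#' and each gene set within a universe, BH-adjusted across sets. A generic
#' stand-in for commercial enrichment suites; results are reported with the
#' conventional "overlap/set size" ratio.
#'
#' @param query_set character vector (subset of universe).
#' @param gene_sets named list of character vectors (subsets of universe),
#'   or a single character vector.
#' @param universe character vector of all genes considered.
#' @return data frame: set, overlap, size, ratio, p, q.
#' @export
overrepresentation_test <- function(query_set, gene_sets, universe) {
  if (length(universe) == 0L) stop("universe is empty")
  if (!is.list(gene_sets)) gene_sets <- list(set1 = gene_sets)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  query <- intersect(unique(query_set), universe)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(query, gs))
    p <- stats::phyper(k - 1, length(gs), length(universe) - length(gs),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, size = length(gs),
               ratio = paste0(k, "/", length(gs)), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}
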