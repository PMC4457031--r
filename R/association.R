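#' Infer founder-line origin of every F2 gamete at every marker
#'
#' In a two-founder full-sib F2 cross, each F2 chromosome is a mosaic of
#' segments descending from the founder sire's line (line A) or the founder
#' dam's line (line B). Origins are inferred by deterministic trio-logic
#' phasing of the F1 parents (which founder contributed each F1 allele)
#' followed by a per-individual Viterbi smoothing pass over the four ordered
#' origin-pair states, with Haldane transition probabilities between
#' adjacent markers and a genotyping-error emission model. Uninformative or
#' conflicting sites are resolved by the smoothing; if a chromosome carries
#' no informative marker at all (founders identical), its origins are
#' labelled unknown.
#'
#' @param ped a [pedigree()] containing both F0 founders, the F1 parents and
#'   the F2s.
#' @param genotypes a [genotype_matrix()] over the same individuals.
#' @param error_rate assumed genotyping error rate of the emission model.
#' @param cm_per_mb genetic map density for the Haldane transitions.
#' @return A \code{founder_origin} object: list with character matrices
#'   \code{paternal} and \code{maternal} (F2 x marker, values "A", "B" or
#'   "unknown"), numeric matrix \code{dosage_b} (count of line-B origins,
#'   NA where unknown), \code{markers}, and founder ids.
#' @export
infer_founder_origin <- function(ped, genotypes, error_rate = 0.005,
                                 cm_per_mb = 1) {
  f0 <- ped[ped$generation == "F0", ]
  if (nrow(f0) < 2L || !all(c("M", "F") %in% f0$sex))
    stop("pedigree must contain both F0 founders")
  line_a_id <- f0$id[f0$sex == "M"][1L]
  line_b_id <- f0$id[f0$sex == "F"][1L]
  f2 <- ped[ped$generation == "F2", ]
  if (nrow(f2) == 0L) stop("pedigree contains no F2 individuals")
  f1_sire <- unique(f2$sire); f1_dam <- unique(f2$dam)
  if (length(f1_sire) != 1L || length(f1_dam) != 1L)
    stop("all F2s must share one F1 sire and one F1 dam")
  dos <- genotypes$dosage
  mk <- genotypes$markers
  g_a <- dos[line_a_id, ]; g_b <- dos[line_b_id, ]

  # trio-logic phasing of an F1: P(B allele | line-A origin), P(B | line-B)
  phase_f1 <- function(g1) {
    ea <- ifelse(is.na(g_a), 0.5, g_a / 2)
    eb <- ifelse(is.na(g_b), 0.5, g_b / 2)
    hom0 <- !is.na(g1) & g1 == 0L
    hom2 <- !is.na(g1) & g1 == 2L
    ea[hom0] <- 0; eb[hom0] <- 0
    ea[hom2] <- 1; eb[hom2] <- 1
    het <- !is.na(g1) & g1 == 1L
    a_hom0 <- het & !is.na(g_a) & g_a == 0L
    a_hom2 <- het & !is.na(g_a) & g_a == 2L
    ea[a_hom0] <- 0; eb[a_hom0] <- 1
    ea[a_hom2] <- 1; eb[a_hom2] <- 0
    rest <- het & !(a_hom0 | a_hom2)
    b_hom0 <- rest & !is.na(g_b) & g_b == 0L
    b_hom2 <- rest & !is.na(g_b) & g_b == 2L
    eb[b_hom0] <- 0; ea[b_hom0] <- 1
    eb[b_hom2] <- 1; ea[b_hom2] <- 0
    list(ea = ea, eb = eb)
  }
  ph_s <- phase_f1(dos[f1_sire, ])
  ph_d <- phase_f1(dos[f1_dam, ])

  n_mark <- nrow(mk)
  f2_ids <- f2$id
  n_ind <- length(f2_ids)
  pat <- mat <- matrix("unknown", n_ind, n_mark,
                       dimnames = list(f2_ids, mk$id))
  informative <- (abs(ph_s$ea - ph_s$eb) > 1e-9) |
    (abs(ph_d$ea - ph_d$eb) > 1e-9)

  if (any(informative)) {
    states <- cbind(pat = c("A", "A", "B", "B"), mat = c("A", "B", "A", "B"))
    eps <- error_rate
    for (chr in unique(mk$chrom)) {
      sel <- which(mk$chrom == chr)
      if (!any(informative[sel])) next
      bp <- mk$bp[sel]
      m_chr <- length(sel)
      # emission table: P(observed dosage | state), markers x states x 0:2
      emis <- array(NA_real_, c(m_chr, 4L, 3L))
      for (s in 1:4) {
        pp <- if (states[s, "pat"] == "A") ph_s$ea[sel] else ph_s$eb[sel]
        pm <- if (states[s, "mat"] == "A") ph_d$ea[sel] else ph_d$eb[sel]
        pt <- cbind((1 - pp) * (1 - pm), pp * (1 - pm) + (1 - pp) * pm,
                    pp * pm)
        for (d in 0:2) {
          obs <- matrix(eps / 2, m_chr, 3L)
          obs[, d + 1L] <- 1 - eps
          emis[, s, d + 1L] <- rowSums(pt * obs)
        }
      }
      log_emis <- log(pmax(emis, 1e-300))
      d_morgan <- diff(bp) * cm_per_mb / 1e6 / 100
      r <- 0.5 * (1 - exp(-2 * d_morgan))  # Haldane
      obs_dos <- dos[f2_ids, sel, drop = FALSE]
      delta <- matrix(log(0.25), n_ind, 4L)
      e1 <- matrix(0, n_ind, 4L)
      for (s in 1:4) {
        e <- log_emis[1L, s, obs_dos[, 1L] + 1L]
        e[is.na(obs_dos[, 1L])] <- 0
        e1[, s] <- e
      }
      delta <- delta + e1
      ptr <- array(1L, c(n_ind, 4L, m_chr))
      for (m in seq_len(m_chr)[-1L]) {
        rr <- r[m - 1L]
        lt <- log(outer(c(1 - rr, rr), c(1 - rr, rr)))  # per-gamete kron
        # joint transition s' -> s: product of per-gamete switches
        logT <- matrix(0, 4L, 4L)
        for (s1 in 1:4) for (s2 in 1:4) {
          sw_p <- (states[s1, "pat"] != states[s2, "pat"]) + 1L
          sw_m <- (states[s1, "mat"] != states[s2, "mat"]) + 1L
          logT[s1, s2] <- lt[sw_p, sw_m]
        }
        new_delta <- matrix(-Inf, n_ind, 4L)
        for (s in 1:4) {
          cand <- sweep(delta, 2L, logT[, s], "+")
          best <- max.col(cand, ties.method = "first")
          ptr[, s, m] <- best
          e <- log_emis[m, s, obs_dos[, m] + 1L]
          e[is.na(obs_dos[, m])] <- 0
          new_delta[, s] <- cand[cbind(seq_len(n_ind), best)] + e
        }
        delta <- new_delta
      }
      path <- matrix(1L, n_ind, m_chr)
      path[, m_chr] <- max.col(delta, ties.method = "first")
      if (m_chr > 1L) for (m in rev(seq_len(m_chr - 1L)))
        path[, m] <- ptr[cbind(seq_len(n_ind), path[, m + 1L], m + 1L)]
      pat[, sel] <- matrix(states[path, "pat"], n_ind, m_chr)
      mat[, sel] <- matrix(states[path, "mat"], n_ind, m_chr)
      # individuals with no genotype on this chromosome stay unknown
      all_missing <- rowSums(!is.na(obs_dos)) == 0L
      pat[all_missing, sel] <- "unknown"
      mat[all_missing, sel] <- "unknown"
    }
  }
  dosage_b <- (pat == "B") + (mat == "B")
  dosage_b[pat == "unknown" | mat == "unknown"] <- NA
  structure(list(paternal = pat, maternal = mat, dosage_b = dosage_b,
                 markers = mk, line_a_id = line_a_id, line_b_id = line_b_id,
                 f1_sire = f1_sire, f1_dam = f1_dam),
            class = "founder_origin")
}

#' Per-marker founder-origin association scan with Bonferroni control
#'
#' Regresses the binary phenotype on the line-B origin dosage (0/1/2) at
#' each marker and reports the slope t statistic with its two-sided p-value
#' (trend test), or a Welch two-group test between the homozygous line-A
#' and homozygous line-B origin classes. Markers with unknown origin in
#' more than \code{max_unknown_frac} of individuals, or with constant
#' origin dosage, are skipped and not counted in the number of tests N.
#' The genome-wide threshold is \code{alpha / N}.
#'
#' @param origins a \code{founder_origin} from [infer_founder_origin()].
#' @param phenotype named vector over the F2s ("affected"/"unaffected",
#'   logical or 0/1).
#' @param alpha genome-wide type-I error rate.
#' @param max_unknown_frac skip markers with more unknown origins than this.
#' @param method "trend" (dosage regression) or "welch".
#' @return An \code{assoc_scan} object: list with \code{results} (marker,
#'   chrom, bp, n, stat, p, significant), \code{n_tests}, \code{alpha},
#'   \code{threshold}, \code{method}.
#' @export
origin_association_scan <- function(origins, phenotype, alpha = 0.05,
                                    max_unknown_frac = 0.5,
                                    method = c("trend", "welch")) {
  method <- match.arg(method)
  aff <- normalize_phenotype(phenotype)
  ids <- intersect(names(aff), rownames(origins$dosage_b))
  if (length(ids) < 3L) stop("need at least 3 phenotyped individuals")
  aff <- aff[ids]
  if (stats::var(aff) == 0) stop("phenotype is constant")
  D <- origins$dosage_b[ids, , drop = FALSE]
  n_mark <- ncol(D)
  stat <- p <- rep(NA_real_, n_mark)
  n_used <- integer(n_mark)
  for (m in seq_len(n_mark)) {
    d <- D[, m]
    ok <- !is.na(d)
    if (mean(!ok) > max_unknown_frac) next
    x <- d[ok]; y <- aff[ok]
    n <- length(x)
    n_used[m] <- n
    if (method == "trend") {
      if (n < 3L || stats::var(x) == 0 || stats::var(y) == 0) next
      r <- stats::cor(x, y)
      r <- max(min(r, 1), -1)
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      stat[m] <- tt
      p[m] <- 2 * stats::pt(-abs(tt), df = n - 2)
    } else {
      g0 <- y[x == 0]; g2 <- y[x == 2]
      if (length(g0) < 2L || length(g2) < 2L) next
      if (stats::var(g0) == 0 && stats::var(g2) == 0) next
      wt <- stats::t.test(g0, g2)
      stat[m] <- unname(wt$statistic)
      p[m] <- wt$p.value
    }
  }
  tested <- !is.na(p)
  n_tests <- sum(tested)
  if (n_tests == 0L) stop("no marker could be tested")
  threshold <- alpha / n_tests
  results <- data.frame(
    marker = origins$markers$id, chrom = origins$markers$chrom,
    bp = origins$markers$bp, n = n_used, stat = stat, p = p,
    significant = !is.na(p) & p <= threshold, stringsAsFactors = FALSE)
  structure(list(results = results, n_tests = n_tests, alpha = alpha,
                 threshold = threshold, method = method),
            class = "assoc_scan")
}

#' @exportS3Method base::print
print.assoc_scan <- function(x, ...) {
  top <- x$results[which.min(x$results$p), ]
  cat(sprintf(
    "association scan (%s): %d markers tested, threshold %.3g (= %.2f/%d)\n",
    x$method, x$n_tests, x$threshold, x$alpha, x$n_tests))
  cat(sprintf("  %d significant; top marker %s at %s:%s (p = %.3g)\n",
              sum(x$results$significant), top$marker, top$chrom,
              format(top$bp, big.mark = ","), top$p))
  invisible(x)
}
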