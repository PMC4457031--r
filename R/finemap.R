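#' Shared-homozygosity (IBD) scan among affected individuals
#'
#' Finds maximal runs of consecutive markers at which every affected
#' individual is homozygous for one identical allele. Missing genotypes are
#' compatible with any shared allele (strict matching available via
#' \code{strict_match}). \code{max_discordant} individuals per marker may
#' deviate from the shared allele before the marker breaks a run (default 0
#' = exact sharing); the tolerant mode treats an isolated discordant call as
#' a probable genotyping error. Runs shorter than \code{min_markers} are
#' dropped; intervals are returned sorted by marker count, descending.
#'
#' @param genotypes a [genotype_matrix()].
#' @param affected_ids ids of the affected individuals.
#' @param min_markers minimum run length in markers.
#' @param max_discordant per-marker tolerance for deviating individuals.
#' @param strict_match if TRUE, missing genotypes break sharing instead of
#'   being compatible.
#' @return list of [genomic_interval()]s (provenance "ibd_scan"), each with
#'   a \code{disease_haplotype} element: data frame (marker, bp, dosage,
#'   allele) of the shared homozygous allele run.
#' @export
shared_homozygosity_scan <- function(genotypes, affected_ids,
                                     min_markers = 2L, max_discordant = 0L,
                                     strict_match = FALSE) {
  affected_ids <- intersect(affected_ids, rownames(genotypes$dosage))
  if (length(affected_ids) == 0L)
    stop("no affected individuals with genotypes")
  dos <- genotypes$dosage[affected_ids, , drop = FALSE]
  mk <- genotypes$markers
  n_mark <- ncol(dos)
  compatible <- logical(n_mark)
  shared <- rep(NA_integer_, n_mark)
  for (m in seq_len(n_mark)) {
    d <- dos[, m]
    n_miss <- sum(is.na(d))
    if (strict_match && n_miss > 0L) { compatible[m] <- FALSE; next }
    d_obs <- d[!is.na(d)]
    if (length(d_obs) == 0L) { compatible[m] <- TRUE; next }  # all missing
    n0 <- sum(d_obs == 0L); n2 <- sum(d_obs == 2L)
    cand <- if (n2 >= n0) 2L else 0L
    n_disc <- length(d_obs) - max(n0, n2)
    if (max(n0, n2) >= 1L && n_disc <= max_discordant) {
      compatible[m] <- TRUE
      shared[m] <- cand
    }
  }
  intervals <- list()
  for (chr in unique(mk$chrom)) {
    sel <- which(mk$chrom == chr)
    runs <- rle(compatible[sel])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      if (!runs$values[k] || runs$lengths[k] < min_markers) next
      idx <- sel[starts[k]:ends[k]]
      hap_dos <- shared[idx]
      allele <- ifelse(is.na(hap_dos), NA_character_,
                       ifelse(hap_dos == 2L, mk$allele_b[idx],
                              mk$allele_a[idx]))
      iv <- genomic_interval(chr, mk$bp[idx[1L]], mk$bp[idx[length(idx)]],
                             n_markers = length(idx),
                             provenance = "ibd_scan",
                             marker_ids = mk$id[idx])
      iv$disease_haplotype <- data.frame(
        marker = mk$id[idx], bp = mk$bp[idx], dosage = hap_dos,
        allele = allele, stringsAsFactors = FALSE)
      intervals[[length(intervals) + 1L]] <- iv
    }
  }
  ord <- order(vapply(intervals, function(iv) iv$n_markers, numeric(1L)),
               decreasing = TRUE)
  intervals[ord]
}

#' Refine an IBD interval by recombination breakpoints
#'
#' Two exclusion rules narrow the candidate interval, both placing the
#' refined boundaries at the first markers NOT excluded (a conservative
#' inner-boundary convention, since true breakpoints fall between markers):
#'
#' \strong{Confirmed carriers} (\code{carriers_confirmed = TRUE}): a known
#' heterozygous carrier holds its disease allele on its disease-line
#' chromosome, so wherever that carrier shows zero copies of the disease
#' haplotype the disease-line chromosome must be recombinant (it carries
#' normal-haplotype alleles) and the locus cannot lie there. Use this rule
#' only for animals whose carrier status is externally established
#' (obligate carriers, progeny-tested animals): for an unconfirmed animal a
#' homozygous-normal segment is equally consistent with not carrying the
#' disease allele at all, and excluding on it can discard the true locus.
#'
#' \strong{Unconfirmed animals} (\code{carriers_confirmed = FALSE},
#' requires \code{origins}): an unaffected animal homozygous for the
#' disease-line origin over a subinterval cannot harbour the fully
#' penetrant locus there (it would be affected), a phenotype contradiction
#' that needs no carrier status. This is the rule the end-to-end pipeline
#' uses, passing every unaffected F2.
#'
#' An exclusion is believed only when supported by at least
#' \code{min_confirm} consecutive markers in the same animal, so an
#' isolated discordant call (a likely genotyping error) does not truncate
#' the interval; \code{min_confirm = 1} is the literal marker-by-marker
#' rule.
#'
#' @param interval an ibd_scan [genomic_interval()] with a
#'   \code{disease_haplotype} element (or one supplied separately).
#' @param genotypes a [genotype_matrix()].
#' @param carrier_ids ids of carrier (or, if unconfirmed, all unaffected)
#'   individuals.
#' @param disease_haplotype data frame (marker, bp, dosage) as produced by
#'   [shared_homozygosity_scan()]; defaults to the interval's own.
#' @param origins a \code{founder_origin} from [infer_founder_origin()];
#'   required when \code{carriers_confirmed = FALSE}.
#' @param min_confirm minimum consecutive-exclusion run per animal.
#' @param carriers_confirmed whether \code{carrier_ids} are known
#'   heterozygous carriers of the disease allele.
#' @return refined [genomic_interval()] (provenance "refined"); always a
#'   subinterval of the input.
#' @export
refine_by_carrier_recombinants <- function(interval, genotypes, carrier_ids,
                                           disease_haplotype = NULL,
                                           origins = NULL,
                                           min_confirm = 1L,
                                           carriers_confirmed = TRUE) {
  hap <- disease_haplotype %||% interval$disease_haplotype
  if (is.null(hap)) stop("disease_haplotype required")
  carrier_ids <- intersect(carrier_ids, rownames(genotypes$dosage))
  mk_idx <- match(hap$marker, genotypes$markers$id)
  if (anyNA(mk_idx)) stop("haplotype markers absent from genotype matrix")
  if (!carriers_confirmed && is.null(origins))
    stop("origins are required to refine with unconfirmed carriers")
  n_mark <- length(mk_idx)
  excluded <- logical(n_mark)
  known <- !is.na(hap$dosage)
  disease_line <- attr(hap, "disease_line") %||% "B"
  for (cid in carrier_ids) {
    if (carriers_confirmed) {
      d <- genotypes$dosage[cid, mk_idx]
      # zero copies of the disease allele = opposite homozygote
      excl <- known & !is.na(d) & d == (2L - hap$dosage)
    } else {
      ob <- origins$dosage_b[cid, match(hap$marker,
                                        origins$markers$id)]
      hom_disease <- if (disease_line == "B") ob == 2 else ob == 0
      excl <- !is.na(ob) & hom_disease
    }
    runs <- rle(as.vector(excl))
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      if (!runs$values[k] || runs$lengths[k] < min_confirm) next
      idx <- starts[k]:ends[k]
      if (!carriers_confirmed) {
        # a recombination breakpoint is localized only to the gap between
        # informative markers, so the outermost markers of an inferred
        # homozygous-origin block may belong to the neighbouring state:
        # exclude the block interior only
        idx <- idx[idx > starts[k] & idx < ends[k]]
      }
      if (length(idx)) excluded[idx] <- TRUE
    }
  }
  keep <- !excluded
  if (!any(keep))
    stop("refinement removed every marker: phenotype/haplotype inconsistent")
  runs <- rle(keep)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  best <- NULL; best_key <- c(-Inf, -Inf, Inf)
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    key <- c(length(idx), hap$bp[idx[length(idx)]] - hap$bp[idx[1L]],
             -hap$bp[idx[1L]])
    if (key[1L] > best_key[1L] ||
        (key[1L] == best_key[1L] && key[2L] > best_key[2L]) ||
        (key[1L] == best_key[1L] && key[2L] == best_key[2L] &&
         key[3L] > best_key[3L])) {
      best <- idx; best_key <- key
    }
  }
  out <- genomic_interval(interval$chrom, hap$bp[best[1L]],
                          hap$bp[best[length(best)]],
                          n_markers = length(best), provenance = "refined",
                          marker_ids = hap$marker[best])
  out$disease_haplotype <- hap[best, , drop = FALSE]
  out
}

#' Interval length in megabases
#'
#' Closed 1-based coordinates: length = (end - start + 1) / 1e6, so a
#' single-base interval has length 1e-6 Mb.
#'
#' @param interval an [genomic_interval()] or numeric vector
#'   \code{c(start_bp, end_bp)}.
#' @return length in Mb.
#' @export
interval_length_mb <- function(interval) {
  if (inherits(interval, "f2_interval"))
    (interval$end_bp - interval$start_bp + 1) / 1e6
  else if (is.numeric(interval) && length(interval) == 2L)
    (interval[2L] - interval[1L] + 1) / 1e6
  else stop("interval must be an f2_interval or c(start_bp, end_bp)")
}

#' End-to-end recessive-locus mapping
#'
#' Chains the mapping stages as an analyst would run them: marker QC,
#' founder-origin inference, the origin association scan, a
#' shared-homozygosity scan among the affecteds (taking the interval that
#' contains the top associated marker), and recombination-breakpoint
#' refinement driven by the phenotype contradiction: an unaffected F2
#' homozygous for the disease-line origin over a subinterval cannot
#' harbour the fully penetrant locus there. The homozygosity scan
#' tolerates one discordant animal per marker and refinement requires two
#' consecutive exclusion markers, so isolated genotyping errors neither
#' fragment the IBD segment nor truncate the refined interval.
#'
#' @param ped a [pedigree()].
#' @param genotypes a [genotype_matrix()].
#' @param config a [pipeline_config()].
#' @return list: \code{qc_report}, \code{scan}, \code{top_marker},
#'   \code{ibd_intervals}, \code{interval_ibd}, \code{carriers},
#'   \code{interval_refined}.
#' @export
map_recessive_locus <- function(ped, genotypes, config = pipeline_config()) {
  qc <- qc_filter_markers(genotypes,
                          call_rate_min = config$qc$call_rate_min,
                          maf_min = config$qc$maf_min,
                          hwe_p_min = config$qc$hwe_p_min)
  origins <- infer_founder_origin(ped, qc$genotypes)
  phen <- f2_phenotype(ped)
  scan <- origin_association_scan(
    origins, phen, alpha = config$association$alpha,
    max_unknown_frac = config$association$max_unknown_frac,
    method = config$association$method)
  top <- scan$results[which.min(scan$results$p), ]
  affected_ids <- names(phen)[phen == 1]
  ivs <- shared_homozygosity_scan(
    qc$genotypes, affected_ids,
    min_markers = config$finemap$min_markers,
    max_discordant = config$finemap$max_discordant,
    strict_match = config$finemap$strict_match)
  if (length(ivs) == 0L) stop("no shared homozygous interval found")
  containing <- Filter(function(iv) iv$chrom == top$chrom &&
                         iv$start_bp <= top$bp && iv$end_bp >= top$bp, ivs)
  iv <- if (length(containing)) containing[[1L]] else ivs[[1L]]
  # disease line = the founder-origin class the affecteds are homozygous
  # for at the peak marker
  dose_top <- origins$dosage_b[, match(top$marker, origins$markers$id)]
  aff_dose <- dose_top[intersect(affected_ids, names(dose_top))]
  disease_line <- if (stats::median(aff_dose, na.rm = TRUE) >= 1) "B"
  else "A"
  attr(iv$disease_haplotype, "disease_line") <- disease_line
  # phenotype-contradiction refinement over every unaffected F2: no carrier
  # status is known at mapping stage, so only homozygosity for the
  # disease-line origin is excluding evidence
  unaff <- intersect(names(phen)[phen == 0], rownames(origins$dosage_b))
  refined <- refine_by_carrier_recombinants(
    iv, qc$genotypes, unaff, origins = origins,
    min_confirm = config$finemap$refine_min_run,
    carriers_confirmed = FALSE)
  list(qc_report = qc$report, scan = scan, top_marker = top,
       ibd_intervals = ivs, interval_ibd = iv, origins = origins,
       disease_line = disease_line, interval_refined = refined)
}
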