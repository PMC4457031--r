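#' Variant-site quality control
#'
#' Three sequential site filters, applied in declared order with literal
#' boundary semantics: (1) depth outside [\code{depth_min},
#' \code{depth_max}] removed (6 and 70 are kept); (2) any variant closer
#' than \code{min_spacing_bp} to the immediately preceding variant in the
#' sorted input (kept or not) removed; (3) quality below
#' \code{quality_min} removed.
#'
#' @param variants variant table sorted by (chrom, pos).
#' @param depth_min,depth_max,min_spacing_bp,quality_min thresholds.
#' @return list with \code{variants} (survivors) and \code{trace}
#'   (a filter trace; counts conserve at every step).
#' @export
variant_site_qc <- function(variants, depth_min = 6, depth_max = 70,
                            min_spacing_bp = 5, quality_min = 20) {
  if (nrow(variants) > 1L) {
    ord <- order(variants$chrom, variants$pos)
    if (!identical(ord, seq_len(nrow(variants))))
      stop("variants must be sorted by (chrom, pos)")
  }
  n0 <- nrow(variants)
  keep_depth <- !is.na(variants$depth) & variants$depth >= depth_min &
    variants$depth <= depth_max
  v1 <- variants[keep_depth, , drop = FALSE]
  n1 <- nrow(v1)
  if (n1 > 0L) {
    gap <- c(Inf, diff(v1$pos))
    gap[c(FALSE, v1$chrom[-1L] != v1$chrom[-n1])] <- Inf
    keep_sp <- gap >= min_spacing_bp
  } else keep_sp <- logical(0)
  v2 <- v1[keep_sp, , drop = FALSE]
  n2 <- nrow(v2)
  keep_q <- !is.na(v2$qual) & v2$qual >= quality_min
  v3 <- v2[keep_q, , drop = FALSE]
  n3 <- nrow(v3)
  trace <- new_filter_trace(c("depth", "spacing", "quality"),
                            c(n0, n1, n2), c(n0 - n1, n1 - n2, n2 - n3),
                            c(n1, n2, n3))
  attr(trace, "survivors") <- v3$id
  list(variants = v3, trace = trace)
}

#' Mendelian recessive exclusion cascade (trio)
#'
#' Four steps, in order: (1) variants heterozygous in the affected are
#' removed; (2) variants homozygous-alt in a parent are removed (an
#' unaffected obligate carrier cannot be a mutant homozygote); (3) variants
#' inconsistent with the recessive model are removed (the affected must be
#' homozygous-alt with the alt allele present in both parents); (4)
#' non-coding variants are removed, keeping protein-altering classes
#' (coding_nonsyn, coding_truncating). A genotype that is missing at the
#' step that needs it removes the variant at that step ("unevaluable"),
#' never silently passes. Survivors are therefore homozygous-alt in the
#' affected, heterozygous in both parents, and protein-altering.
#'
#' @param variants variant table with \code{gt_<id>} columns.
#' @param affected_id,sire_id,dam_id sample names of the trio.
#' @return list with \code{variants} and \code{trace}.
#' @export
mendelian_recessive_filter <- function(variants, affected_id = "affected",
                                       sire_id = "sire", dam_id = "dam") {
  cols <- paste0("gt_", c(affected_id, sire_id, dam_id))
  miss_cols <- setdiff(cols, names(variants))
  if (length(miss_cols))
    stop("missing genotype column(s): ", paste(miss_cols, collapse = ", "))
  ga <- variants[[cols[1L]]]
  gs <- variants[[cols[2L]]]
  gd <- variants[[cols[3L]]]
  n0 <- nrow(variants)
  # step 1: heterozygous (or unevaluable) in the affected
  keep1 <- ga != "het" & ga != "missing"
  v1 <- variants[keep1, , drop = FALSE]
  gs1 <- gs[keep1]; gd1 <- gd[keep1]; ga1 <- ga[keep1]
  # step 2: homozygous-alt in a parent (or parent unevaluable)
  keep2 <- gs1 != "homalt" & gd1 != "homalt" &
    gs1 != "missing" & gd1 != "missing"
  v2 <- v1[keep2, , drop = FALSE]
  gs2 <- gs1[keep2]; gd2 <- gd1[keep2]; ga2 <- ga1[keep2]
  # step 3: recessive-model consistency: affected homalt, alt in both parents
  keep3 <- ga2 == "homalt" & gs2 %in% c("het", "homalt") &
    gd2 %in% c("het", "homalt")
  v3 <- v2[keep3, , drop = FALSE]
  # step 4: protein-altering classes only (unknown class unevaluable)
  keep4 <- !is.na(v3$class) & v3$class %in% c("coding_nonsyn",
                                              "coding_truncating")
  v4 <- v3[keep4, , drop = FALSE]
  ns <- c(n0, nrow(v1), nrow(v2), nrow(v3), nrow(v4))
  trace <- new_filter_trace(
    c("het_in_affected", "parent_homalt", "mendel_inconsistent",
      "noncoding"),
    ns[1:4], ns[1:4] - ns[2:5], ns[2:5])
  attr(trace, "survivors") <- v4$id
  list(variants = v4, trace = trace)
}

#' Population (panel) screen of candidate variants
#'
#' Variants whose alt allele segregates in a panel of presumed non-carriers
#' at frequency above \code{seg_freq_threshold} are removed; variants with
#' the alt allele absent are retained; frequencies in (0, threshold] are
#' retained but flagged ambiguous.
#'
#' @param variants variant table.
#' @param panel_genotypes dosage matrix (variants x panel individuals),
#'   rownames = variant ids.
#' @param seg_freq_threshold segregation frequency threshold (default 0.1).
#' @return list with \code{variants} (surviving, plus columns
#'   \code{panel_alt_freq}, \code{ambiguous}) and \code{trace}.
#' @export
population_screen <- function(variants, panel_genotypes,
                              seg_freq_threshold = 0.1) {
  if (is.null(dim(panel_genotypes)) || ncol(panel_genotypes) == 0L)
    stop("panel is empty")
  freq <- rowMeans(panel_genotypes[variants$id, , drop = FALSE],
                   na.rm = TRUE) / 2
  keep <- freq <= seg_freq_threshold
  out <- variants[keep, , drop = FALSE]
  out$panel_alt_freq <- unname(freq[keep])
  out$ambiguous <- out$panel_alt_freq > 0
  if (any(out$ambiguous))
    warning(sum(out$ambiguous), " variant(s) retained with nonzero panel ",
            "frequency <= ", seg_freq_threshold, " (flagged ambiguous)")
  trace <- new_filter_trace("panel_screen", nrow(variants),
                            nrow(variants) - nrow(out), nrow(out))
  attr(trace, "survivors") <- out$id
  list(variants = out, trace = trace)
}

#' Cosegregation check of a candidate variant in the full family
#'
#' Passes when all affected individuals are homozygous-alt, all obligate
#' carriers (parents of an affected) are heterozygous, and no unaffected
#' individual is homozygous-alt.
#'
#' @param ped a [pedigree()].
#' @param genotypes_at_variant named vector over phenotyped individuals;
#'   values homref/het/homalt/missing, or dosages 0/1/2.
#' @return list with \code{passes}, \code{failures} (character reasons) and
#'   \code{counts} (genotype x phenotype table).
#' @export
cosegregation_check <- function(ped, genotypes_at_variant) {
  g <- genotypes_at_variant
  if (is.numeric(g))
    g <- stats::setNames(c("homref", "het", "homalt")[g + 1L], names(g))
  aff <- ped$id[ped$phenotype == "affected"]
  unaff <- ped$id[ped$phenotype == "unaffected"]
  if (!all(aff %in% names(g)) || any(g[aff] == "missing"))
    stop("genotype missing for affected individual(s)")
  carriers <- unique(c(ped$sire[ped$id %in% aff], ped$dam[ped$id %in% aff]))
  carriers <- setdiff(carriers, "0")
  failures <- character(0)
  if (!all(g[aff] == "homalt"))
    failures <- c(failures, "affected not homozygous-alt")
  gc <- g[intersect(carriers, names(g))]
  if (length(gc) && !all(gc[gc != "missing"] == "het"))
    failures <- c(failures, "obligate carrier not heterozygous")
  gu <- g[intersect(unaff, names(g))]
  if (any(gu == "homalt"))
    failures <- c(failures, "unaffected homozygous-alt")
  phen <- stats::setNames(ped$phenotype, ped$id)[names(g)]
  counts <- table(genotype = g, phenotype = phen)
  list(passes = length(failures) == 0L, failures = failures,
       counts = counts)
}

#' In-silico PCR-RFLP digestion
#'
#' Cuts a sequence at every occurrence of the recognition site (both
#' strands; for palindromic sites such as SmaI CCCGGG the reverse-strand
#' cuts coincide) at \code{cut_offset} bases from the site's 5' end, and
#' returns the fragment lengths 5' to 3'. Fragment lengths always sum to
#' the sequence length; n sites produce at most n + 1 fragments.
#'
#' @param amplicon_sequence DNA string over A/C/G/T.
#' @param recognition_site recognition sequence (default SmaI, CCCGGG).
#' @param cut_offset cut position within the site, bases from its 5' end
#'   (SmaI: 3, a blunt cutter).
#' @return integer vector of fragment lengths.
#' @export
insilico_rflp <- function(amplicon_sequence, recognition_site = "CCCGGG",
                          cut_offset = 3L) {
  seq <- toupper(amplicon_sequence)
  site <- toupper(recognition_site)
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT characters")
  if (grepl("[^ACGT]", site)) stop("site contains non-ACGT characters")
  if (cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset must lie within the recognition site")
  len <- nchar(seq)
  dna <- Biostrings::DNAString(seq)
  fwd <- Biostrings::start(Biostrings::matchPattern(site, dna))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(site)))
  rev <- Biostrings::start(Biostrings::matchPattern(rc, dna))
  # a palindromic site matches on both strands at the same start: that is
  # one binding event and one fragment boundary, so reverse-strand starts
  # already seen on the forward strand are not cut again
  rev <- setdiff(rev, fwd)
  cuts <- sort(unique(c(fwd + cut_offset - 1L,
                        rev + nchar(site) - cut_offset - 1L)))
  cuts <- cuts[cuts >= 1L & cuts < len]
  diff(c(0L, cuts, len))
}

#' Predict protein truncation from a CDS edit
#'
#' Applies a deletion-insertion (or substitution) to a coding sequence,
#' translates with the standard genetic code, and reports the residue index
#' of the first stop codon. A frameshifting edit typically produces a
#' premature stop; the truncation residue is the codon index at which
#' translation terminates.
#'
#' @param cds_sequence CDS string, length divisible by 3, starting ATG.
#' @param variant list with \code{position} (1-based CDS coordinate),
#'   \code{deleted} (string removed, possibly ""), \code{inserted}
#'   (string inserted, possibly "").
#' @return list with \code{protein} (edited protein up to the stop),
#'   \code{protein_length}, \code{termination_residue} (codon index of the
#'   first stop, or NA if translation runs off the edited sequence) and
#'   \code{premature} (TRUE if the stop comes earlier than in the
#'   unedited CDS).
#' @export
predict_truncation <- function(cds_sequence, variant) {
  cds <- toupper(cds_sequence)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (substr(cds, 1L, 3L) != "ATG") stop("CDS must start with ATG")
  pos <- variant$position
  del <- toupper(variant$deleted %||% "")
  ins <- toupper(variant$inserted %||% "")
  if (pos < 1L || pos > nchar(cds)) stop("variant position beyond CDS")
  if (nchar(del) > 0L &&
      substr(cds, pos, pos + nchar(del) - 1L) != del)
    stop("deleted bases do not match the CDS at the given position")
  edited <- paste0(substr(cds, 1L, pos - 1L), ins,
                   substr(cds, pos + nchar(del), nchar(cds)))
  translate_to_stop <- function(s) {
    n_cod <- nchar(s) %/% 3L
    if (n_cod == 0L) return(list(protein = "", stop_at = NA_integer_))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1L, n_cod * 3L)),
      if.fuzzy.codon = "X"))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at == -1L)
      list(protein = aa, stop_at = NA_integer_)
    else
      list(protein = substr(aa, 1L, stop_at - 1L),
           stop_at = as.integer(stop_at))
  }
  ed <- translate_to_stop(edited)
  orig <- translate_to_stop(cds)
  premature <- !is.na(ed$stop_at) &&
    (is.na(orig$stop_at) || ed$stop_at < orig$stop_at)
  list(protein = ed$protein, protein_length = nchar(ed$protein),
       termination_residue = ed$stop_at, premature = premature)
}
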