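#' Simulate an F2 full-sib intercross with a planted recessive locus
#'
#' Two founders from divergent lines (drawn as line-representative
#' homozygotes, the classical inbred-line intercross model) produce two F1
#' full sibs, whose mating produces the F2. Meiotic crossovers follow a
#' Poisson process under the Haldane map (no interference) at
#' \code{cm_per_mb} cM per Mb. An F2 is affected if and only if it is
#' homozygous for founder-B (founder dam) origin at \code{causal_bp}: the
#' planted disorder is fully penetrant recessive, so affecteds segregate
#' 3:1 against unaffecteds in expectation. Genotyping error flips a dosage
#' to one of the other two values; missingness is applied independently.
#'
#' @param seed integer seed; the generator is a pure function of
#'   (seed, parameters).
#' @param n_f2 number of F2 offspring.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_markers number of SNP markers (>= 2), placed uniformly.
#' @param founder_divergence probability that a marker's line-B allele
#'   frequency is mirrored (1 - p) relative to line A; controls the fraction
#'   of informative markers.
#' @param genotype_error_rate per-call probability of a dosage flip.
#' @param missing_rate per-call probability of a missing genotype.
#' @param causal_bp position of the planted recessive locus.
#' @param chrom chromosome name.
#' @param cm_per_mb genetic map density (default 1 cM/Mb).
#' @return list with \code{pedigree}, \code{genotypes}
#'   (a [genotype_matrix()]) and \code{truth} (a \code{sim_truth} list:
#'   causal locus, affected ids, per-F2 carrier dosage, per-gamete founder
#'   origins at every marker, crossover positions).
#' @export
simulate_f2_cross <- function(seed, n_f2 = 75L, chrom_length_bp = 1e8,
                              n_markers = 1000L, founder_divergence = 0.7,
                              genotype_error_rate = 0.002,
                              missing_rate = 0.02, causal_bp = 5e7,
                              chrom = "18", cm_per_mb = 1) {
  if (causal_bp < 1 || causal_bp > chrom_length_bp)
    stop("causal_bp outside chromosome")
  if (n_markers < 2L) stop("n_markers must be >= 2")
  set.seed(seed)
  bp <- sort(sample.int(chrom_length_bp, n_markers))
  letters4 <- c("A", "C", "G", "T")
  al <- t(vapply(seq_len(n_markers),
                 function(i) sort(sample(letters4, 2L)), character(2L)))
  # founder haplotypes as B-allele indicators (founders homozygous)
  p_a <- stats::runif(n_markers)
  mirrored <- stats::runif(n_markers) < founder_divergence
  p_b <- ifelse(mirrored, 1 - p_a, p_a)
  hap_a <- stats::rbinom(n_markers, 1L, p_a)
  hap_b <- stats::rbinom(n_markers, 1L, p_b)

  morgan <- chrom_length_bp * cm_per_mb / 1e6 / 100
  draw_gamete <- function() {
    n_xo <- stats::rpois(1L, morgan)
    xo <- sort(stats::runif(n_xo, 1, chrom_length_bp))
    start <- sample(c("A", "B"), 1L)
    list(xo = xo, start = start)
  }
  gamete_origin <- function(g, pos) {
    flips <- findInterval(pos, g$xo)
    ifelse((flips + (g$start == "B")) %% 2L == 1L, "B", "A")
  }

  f2_ids <- sprintf("F2_%03d", seq_len(n_f2))
  ids <- c("F0_SIRE", "F0_DAM", "F1_SIRE", "F1_DAM", f2_ids)
  dosage <- matrix(NA_integer_, nrow = length(ids), ncol = n_markers,
                   dimnames = list(ids, NULL))
  dosage["F0_SIRE", ] <- 2L * hap_a
  dosage["F0_DAM", ] <- 2L * hap_b
  dosage["F1_SIRE", ] <- hap_a + hap_b
  dosage["F1_DAM", ] <- hap_a + hap_b

  pat_origin <- mat_origin <- matrix(NA_character_, n_f2, n_markers,
                                     dimnames = list(f2_ids, NULL))
  crossovers <- vector("list", n_f2)
  carrier_dosage <- integer(n_f2)
  names(carrier_dosage) <- f2_ids
  for (i in seq_len(n_f2)) {
    gp <- draw_gamete(); gm <- draw_gamete()
    crossovers[[i]] <- list(paternal = gp$xo, maternal = gm$xo)
    op <- gamete_origin(gp, bp); om <- gamete_origin(gm, bp)
    pat_origin[i, ] <- op; mat_origin[i, ] <- om
    allele_p <- ifelse(op == "B", hap_b, hap_a)
    allele_m <- ifelse(om == "B", hap_b, hap_a)
    dosage[f2_ids[i], ] <- allele_p + allele_m
    carrier_dosage[i] <- sum(gamete_origin(gp, causal_bp) == "B",
                             gamete_origin(gm, causal_bp) == "B")
  }
  affected <- carrier_dosage == 2L

  if (genotype_error_rate > 0) {
    err <- matrix(stats::runif(length(dosage)) < genotype_error_rate,
                  nrow = nrow(dosage))
    idx <- which(err & !is.na(dosage))
    if (length(idx)) {
      shift <- sample(1:2, length(idx), replace = TRUE)
      dosage[idx] <- (dosage[idx] + shift) %% 3L
    }
  }
  if (missing_rate > 0)
    dosage[matrix(stats::runif(length(dosage)) < missing_rate,
                  nrow = nrow(dosage))] <- NA_integer_

  marker_ids <- sprintf("snp_%04d", seq_len(n_markers))
  colnames(dosage) <- marker_ids
  rownames(pat_origin) <- rownames(mat_origin) <- f2_ids
  colnames(pat_origin) <- colnames(mat_origin) <- marker_ids
  markers <- data.frame(id = marker_ids, chrom = chrom, bp = bp,
                        allele_a = al[, 1L], allele_b = al[, 2L],
                        stringsAsFactors = FALSE)
  sex_f2 <- sample(c("M", "F"), n_f2, replace = TRUE)
  ped <- pedigree(data.frame(
    id = ids,
    sire = c("0", "0", "F0_SIRE", "F0_SIRE", rep("F1_SIRE", n_f2)),
    dam = c("0", "0", "F0_DAM", "F0_DAM", rep("F1_DAM", n_f2)),
    sex = c("M", "F", "M", "F", sex_f2),
    generation = c("F0", "F0", "F1", "F1", rep("F2", n_f2)),
    phenotype = c(rep("unaffected", 4L),
                  ifelse(affected, "affected", "unaffected")),
    stringsAsFactors = FALSE))
  truth <- structure(list(
    causal_chrom = chrom, causal_bp = causal_bp,
    affected_ids = f2_ids[affected], carrier_dosage = carrier_dosage,
    pat_origin = pat_origin, mat_origin = mat_origin,
    founder_hap_a = hap_a, founder_hap_b = hap_b,
    crossovers = crossovers, line_a_id = "F0_SIRE", line_b_id = "F0_DAM"),
    class = "sim_truth")
  list(pedigree = ped, genotypes = genotype_matrix(markers, dosage),
       truth = truth)
}

#' Simulate trio + panel variant calls with one planted truncating variant
#'
#' Emulates capture resequencing of a mapped interval in an affected
#' offspring and its two carrier parents, plus genotypes of an unrelated
#' presumed non-carrier panel. Exactly one planted protein-truncating
#' variant is homozygous-alt in the affected, heterozygous in both parents
#' and absent from the panel. Background variants fall into categories
#' removed by successive steps of the exclusion cascade; a fraction
#' (\code{prop_survivor}, default 5\%) mimics the cascade survivors that
#' only the population screen eliminates, segregating in the panel at
#' moderately high frequency. Site depths are drawn Poisson(35) -- the
#' post-deduplication unique-read depth the site filters see -- and
#' qualities uniform on [10, 60].
#'
#' @param seed integer seed.
#' @param interval an [genomic_interval()] to place variants in.
#' @param n_background number of background (non-causal) variants.
#' @param planted_effect list with \code{gene} and \code{class} of the
#'   planted variant.
#' @param panel_size unrelated panel size (default 24).
#' @param prop_survivor fraction of background variants built to survive the
#'   Mendelian cascade (removed only by the panel screen).
#' @param missing_rate per-genotype missing rate among background variants.
#' @return list with \code{variants} (variant table with gt/dp/gq columns
#'   for affected, sire, dam), \code{panel} (dosage matrix variants x panel)
#'   and \code{truth} (planted variant id).
#' @export
simulate_trio_variants <- function(seed, interval, n_background = 300L,
                                   planted_effect = list(
                                     gene = "GENE_01",
                                     class = "coding_truncating"),
                                   panel_size = 24L, prop_survivor = 0.05,
                                   missing_rate = 0.02) {
  if (interval$end_bp - interval$start_bp + 1 < n_background + 10L)
    stop("interval too small for requested variant count")
  set.seed(seed)
  n <- n_background + 1L
  planted_pos <- as.integer(round((interval$start_bp + interval$end_bp) / 2))
  pos <- integer(0)
  while (length(pos) < n_background) {
    cand <- sample(seq.int(interval$start_bp, interval$end_bp),
                   n_background - length(pos))
    cand <- cand[abs(cand - planted_pos) >= 5L]
    pos <- unique(c(pos, cand))
  }
  pos <- c(pos, planted_pos)
  planted_flag <- c(rep(FALSE, n_background), TRUE)
  ord <- order(pos)
  pos <- pos[ord]; planted_flag <- planted_flag[ord]

  # category probabilities; sample() renormalizes so prop_survivor just
  # replaces part of the non-survivor mass
  cats <- if (n_background > 0L)
    sample(c("het_aff", "parent_hom", "inconsistent", "noncoding",
             "survivor"), n_background, replace = TRUE,
           prob = c(0.45, 0.25, 0.10, 0.15, prop_survivor) /
             (0.95 + prop_survivor))
  else character(0)
  category <- character(n)
  category[!planted_flag] <- cats
  category[planted_flag] <- "planted"

  letters4 <- c("A", "C", "G", "T")
  ref <- sample(letters4, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(letters4, r), 1L),
                character(1L))
  gt_aff <- gt_sire <- gt_dam <- character(n)
  cls <- character(n)
  panel_freq <- numeric(n)
  coding_classes <- c("coding_nonsyn", "coding_syn")
  for (i in seq_len(n)) {
    switch(category[i],
      planted = {
        gt_aff[i] <- "homalt"; gt_sire[i] <- "het"; gt_dam[i] <- "het"
        cls[i] <- planted_effect$class; panel_freq[i] <- 0
      },
      het_aff = {
        gt_aff[i] <- "het"
        gt_sire[i] <- sample(c("het", "homref"), 1L)
        gt_dam[i] <- sample(c("het", "homalt"), 1L)
        cls[i] <- sample(c(coding_classes, "noncoding"), 1L)
        panel_freq[i] <- stats::runif(1, 0.1, 0.6)
      },
      parent_hom = {
        gt_aff[i] <- "homalt"
        if (stats::runif(1) < 0.5) {
          gt_sire[i] <- "homalt"; gt_dam[i] <- "het"
        } else {
          gt_sire[i] <- "het"; gt_dam[i] <- "homalt"
        }
        cls[i] <- sample(c(coding_classes, "noncoding"), 1L)
        panel_freq[i] <- stats::runif(1, 0.2, 0.7)
      },
      inconsistent = {
        gt_aff[i] <- "homalt"
        if (stats::runif(1) < 0.5) {
          gt_sire[i] <- "homref"; gt_dam[i] <- "het"
        } else {
          gt_sire[i] <- "het"; gt_dam[i] <- "homref"
        }
        cls[i] <- sample(c(coding_classes, "noncoding"), 1L)
        panel_freq[i] <- stats::runif(1, 0.1, 0.5)
      },
      noncoding = {
        gt_aff[i] <- "homalt"; gt_sire[i] <- "het"; gt_dam[i] <- "het"
        cls[i] <- "noncoding"
        panel_freq[i] <- stats::runif(1, 0.2, 0.6)
      },
      survivor = {
        gt_aff[i] <- "homalt"; gt_sire[i] <- "het"; gt_dam[i] <- "het"
        cls[i] <- "coding_nonsyn"
        panel_freq[i] <- stats::runif(1, 0.3, 0.7)
      })
  }
  if (missing_rate > 0) {
    for (v in c("gt_aff", "gt_sire", "gt_dam")) {
      g <- get(v)
      drop <- stats::runif(n) < missing_rate & category != "planted"
      g[drop] <- "missing"
      assign(v, g)
    }
  }
  depth <- stats::rpois(n, 35)
  depth[planted_flag] <- max(depth[planted_flag], 20L)
  qual <- round(stats::runif(n, 10, 60), 1)
  qual[planted_flag] <- round(stats::runif(1, 30, 60), 1)
  genes <- sample(sprintf("GENE_%02d", 1:5), n, replace = TRUE)
  genes[planted_flag] <- planted_effect$gene
  ids <- sprintf("var_%04d", seq_len(n))
  variants <- data.frame(
    chrom = interval$chrom, pos = pos, id = ids, ref = ref, alt = alt,
    qual = qual, depth = depth, class = cls, gene = genes,
    gt_affected = gt_aff, gt_sire = gt_sire, gt_dam = gt_dam,
    dp_affected = stats::rpois(n, 35), dp_sire = stats::rpois(n, 35),
    dp_dam = stats::rpois(n, 35),
    gq_affected = round(stats::runif(n, 20, 99)),
    gq_sire = round(stats::runif(n, 20, 99)),
    gq_dam = round(stats::runif(n, 20, 99)),
    stringsAsFactors = FALSE)
  panel <- t(vapply(panel_freq, function(f)
    stats::rbinom(panel_size, 2L, f), integer(panel_size)))
  rownames(panel) <- ids
  colnames(panel) <- sprintf("P%02d", seq_len(panel_size))
  class(variants) <- c("variant_table", "data.frame")
  attr(variants, "samples") <- c("affected", "sire", "dam")
  list(variants = variants, panel = panel,
       truth = list(planted_id = ids[planted_flag],
                    category = stats::setNames(category, ids)))
}

#' Simulate a two-library count table under Poisson sampling
#'
#' Per-gene rates are proportional to expression x length x library size;
#' differentially expressed genes have their mutant-library rate multiplied
#' by \code{2^log2fc}, with alternating sign so both directions are planted.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param library_sizes length-2 vector: nominal totals (wild-type, mutant).
#' @param gene_length_range min/max gene length in bp.
#' @param n_de number of differentially expressed genes (<= n_genes).
#' @param log2fc magnitude of the planted log2 fold change (mutant over
#'   wild-type); alternating genes get -log2fc.
#' @param dispersion if > 0, counts are drawn negative-binomial with this
#'   dispersion instead of Poisson (misspecification checks only).
#' @return list with \code{counts} (a [count_table()]) and \code{truth}
#'   (data frame gene_id, log2fc).
#' @export
simulate_counts <- function(seed, n_genes = 2000L,
                            library_sizes = c(1e6, 1e6),
                            gene_length_range = c(200L, 10000L), n_de = 0L,
                            log2fc = 2, dispersion = 0) {
  if (n_de > n_genes) stop("n_de must be <= n_genes")
  set.seed(seed)
  len <- sample(seq.int(gene_length_range[1L], gene_length_range[2L]),
                n_genes, replace = TRUE)
  expr <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
  abn <- expr * len
  abn <- abn / sum(abn)
  lfc <- numeric(n_genes)
  de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
  if (n_de > 0)
    lfc[de_idx] <- rep(c(log2fc, -log2fc), length.out = n_de)
  mu_wt <- abn * library_sizes[1L]
  mu_mut <- abn * 2^lfc * library_sizes[2L]
  draw <- function(mu) {
    if (dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else stats::rpois(length(mu), mu)
  }
  x <- draw(mu_wt); y <- draw(mu_mut)
  ids <- sprintf("gene_%05d", seq_len(n_genes))
  counts <- count_table(ids, len, x, y)
  truth <- data.frame(gene_id = ids, log2fc = lfc, stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Simulate correlated ranked gene lists with planted signal genes
#'
#' Each list scores genes as \code{sqrt(c) * base + sqrt(1 - c) * noise}
#' where \code{base} is a shared latent score boosted for signal genes:
#' concordance 1 makes all lists identical, concordance 0 makes them
#' independent permutations.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param n_lists number of ranked lists.
#' @param signal_genes number of planted signal genes.
#' @param concordance between-list correlation of scores, in [0, 1].
#' @param signal_boost additive score boost of signal genes (default 3).
#' @return list with \code{lists} (list of [ranked_list()]) and
#'   \code{truth} (signal gene ids).
#' @export
simulate_ranked_lists <- function(seed, n_genes = 500L, n_lists = 3L,
                                  signal_genes = 10L, concordance = 0.9,
                                  signal_boost = 3) {
  if (concordance < 0 || concordance > 1)
    stop("concordance must be in [0, 1]")
  set.seed(seed)
  ids <- sprintf("g%04d", seq_len(n_genes))
  signal <- sample(ids, signal_genes)
  base <- stats::rnorm(n_genes)
  base[ids %in% signal] <- base[ids %in% signal] + signal_boost
  lists <- lapply(seq_len(n_lists), function(l) {
    score <- sqrt(concordance) * base +
      sqrt(1 - concordance) * stats::rnorm(n_genes)
    ranked_list(ids, score, source = paste0("algorithm_", l))
  })
  list(lists = lists, truth = list(signal_ids = signal))
}
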