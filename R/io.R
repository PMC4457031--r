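#' Read PLINK-style text PED/MAP files
#'
#' PED columns: family id, individual id, father, mother, sex (1=M, 2=F),
#' phenotype (1=unaffected, 2=affected, 0/-9=unknown), then two allele columns
#' per marker (symbols A/C/G/T, 0=missing). MAP columns: chromosome, marker
#' id, genetic position (cM), physical position (bp). Markers are returned
#' sorted by (chromosome, position) and genotypes coded as B-allele dosage,
#' where allele B is the alphabetically later allele observed at the marker.
#' A half-missing genotype ("0 A") is treated as missing.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return list with elements \code{pedigree} and \code{genotypes}
#'   (a [genotype_matrix()]).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "bp"))
  map$chrom <- as.character(map$chrom)
  map$id <- as.character(map$id)
  if (anyDuplicated(map$id))
    stop("duplicate marker id in MAP: ", map$id[duplicated(map$id)][1L])
  n_mark <- nrow(map)
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  n_expect <- 6L + 2L * n_mark
  bad <- which(lengths(fields) != n_expect)
  if (length(bad))
    stop("PED line ", bad[1L], " has ", lengths(fields)[bad[1L]],
         " fields; expected ", n_expect)
  ped_mat <- do.call(rbind, fields)
  ids <- ped_mat[, 2L]
  if (anyDuplicated(ids))
    stop("duplicate individual id in PED: ", ids[duplicated(ids)][1L])
  alle <- ped_mat[, -(1:6), drop = FALSE]
  if (!all(alle %in% c("A", "C", "G", "T", "0")))
    stop("allele symbol outside {A,C,G,T,0} in PED")
  a1 <- alle[, seq(1L, 2L * n_mark, by = 2L), drop = FALSE]
  a2 <- alle[, seq(2L, 2L * n_mark, by = 2L), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA; a2[miss] <- NA
  dosage <- matrix(NA_integer_, nrow = length(ids), ncol = n_mark,
                   dimnames = list(ids, map$id))
  allele_a <- allele_b <- rep(NA_character_, n_mark)
  for (m in seq_len(n_mark)) {
    obs <- sort(unique(c(a1[, m], a2[, m])))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2L)
      stop("marker ", map$id[m], " has more than two alleles")
    if (length(obs) >= 1L) allele_a[m] <- obs[1L]
    if (length(obs) == 2L) allele_b[m] <- obs[2L]
    b <- if (length(obs) == 2L) obs[2L] else "\x01"  # never matches
    dosage[, m] <- (a1[, m] == b) + (a2[, m] == b)
  }
  sex <- c("1" = "M", "2" = "F")[ped_mat[, 5L]]
  phen <- c("1" = "unaffected", "2" = "affected")[ped_mat[, 6L]]
  phen[is.na(phen)] <- "unknown"
  ped <- pedigree(data.frame(
    id = ids,
    sire = ifelse(ped_mat[, 3L] == "0", "0", ped_mat[, 3L]),
    dam = ifelse(ped_mat[, 4L] == "0", "0", ped_mat[, 4L]),
    sex = unname(sex), generation = infer_generation(ped_mat[, 3L],
                                                     ped_mat[, 4L], ids),
    phenotype = unname(phen), stringsAsFactors = FALSE))
  markers <- data.frame(id = map$id, chrom = map$chrom, bp = map$bp,
                        allele_a = allele_a, allele_b = allele_b,
                        stringsAsFactors = FALSE)
  list(pedigree = ped, genotypes = genotype_matrix(markers, dosage))
}

# founders (both parents "0") -> F0; offspring of F0 -> F1; else F2
infer_generation <- function(sire, dam, ids) {
  gen <- integer(length(ids))
  names(gen) <- ids
  for (i in seq_along(ids)) {
    if (sire[i] == "0" && dam[i] == "0") gen[i] <- 0L
    else gen[i] <- max(gen[sire[i]], gen[dam[i]], na.rm = TRUE) + 1L
  }
  paste0("F", pmin(gen, 2L))
}

#' Write PLINK-style text PED/MAP files
#'
#' Inverse of [read_ped_map()]. The genetic position written to the MAP file
#' is \code{bp / 1e6} (1 cM per Mb).
#'
#' @param ped a [pedigree()].
#' @param genotypes a [genotype_matrix()] over the same individuals.
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(ped, genotypes, ped_path, map_path) {
  mk <- genotypes$markers
  utils::write.table(
    data.frame(mk$chrom, mk$id, mk$bp / 1e6, mk$bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  dos <- genotypes$dosage[ped$id, , drop = FALSE]
  n_mark <- nrow(mk)
  geno_str <- character(nrow(ped))
  a <- ifelse(is.na(mk$allele_a), "0", mk$allele_a)
  b <- ifelse(is.na(mk$allele_b), "0", mk$allele_b)
  for (i in seq_len(nrow(ped))) {
    d <- dos[i, ]
    g1 <- ifelse(is.na(d), "0", ifelse(d >= 1, b, a))
    g2 <- ifelse(is.na(d), "0", ifelse(d == 2, b, a))
    geno_str[i] <- paste(rbind(g1, g2), collapse = " ")
  }
  sex <- c(M = "1", F = "2")[ped$sex]
  phen <- c(unaffected = "1", affected = "2", unknown = "0")[ped$phenotype]
  lines <- paste("FAM1", ped$id, ped$sire, ped$dam, sex, phen, geno_str)
  writeLines(lines, ped_path)
  invisible(NULL)
}

#' Read a minimal VCF subset into a variant table
#'
#' Supports VCF v4.x with per-sample GT, DP and GQ. Site-level depth is taken
#' from \code{INFO DP}; functional class and gene from \code{INFO CLASS} and
#' \code{GENE} (set by annotation upstream; effect prediction is out of
#' scope). Multiallelic records are rejected or split per alternate allele.
#'
#' @param path VCF file.
#' @param multiallelic "reject" (default) errors on multiallelic sites;
#'   "split" emits one record per alternate allele, counting other alternate
#'   alleles as reference.
#' @return A \code{variant_table} data frame: chrom, pos, id, ref, alt, qual,
#'   depth, class, gene, plus per-sample columns \code{gt_*} (values homref /
#'   het / homalt / missing), \code{dp_*}, \code{gq_*}.
#' @export
read_vcf_min <- function(path, multiallelic = c("reject", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (nrow(fix) == 0L) stop("VCF contains no records")
  if (is.null(gt) || !"FORMAT" %in% colnames(gt))
    stop("VCF has no FORMAT/sample columns")
  if (!all(grepl("(^|:)GT(:|$)", gt[, "FORMAT"])))
    stop("FORMAT is missing the GT field")
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) stop("malformed POS in VCF")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi) && multiallelic == "reject")
    stop("multiallelic site at ", fix$CHROM[which(multi)[1L]], ":",
         pos[which(multi)[1L]], " (use multiallelic = 'split')")
  samples <- setdiff(colnames(gt), "FORMAT")
  info_field <- function(info, key) {
    vapply(info, function(x) {
      hit <- regmatches(x, regexpr(paste0("(^|;)", key, "=[^;]*"), x))
      if (length(hit) == 0L) NA_character_ else sub(".*=", "", hit)
    }, character(1L), USE.NAMES = FALSE)
  }
  fmt_index <- function(fmt, key) match(key, strsplit(fmt, ":", fixed = TRUE)[[1L]])
  parse_sample <- function(cell, fmt, alt_index) {
    parts <- strsplit(cell, ":", fixed = TRUE)[[1L]]
    i_gt <- fmt_index(fmt, "GT"); i_dp <- fmt_index(fmt, "DP")
    i_gq <- fmt_index(fmt, "GQ")
    g <- if (!is.na(i_gt) && i_gt <= length(parts)) parts[i_gt] else "./."
    al <- strsplit(g, "[/|]")[[1L]]
    code <- if (any(al == ".") || length(al) != 2L) "missing" else {
      n_alt <- sum(al == as.character(alt_index))
      c("homref", "het", "homalt")[n_alt + 1L]
    }
    dp <- if (!is.na(i_dp) && i_dp <= length(parts))
      suppressWarnings(as.integer(parts[i_dp])) else NA_integer_
    gq <- if (!is.na(i_gq) && i_gq <= length(parts))
      suppressWarnings(as.integer(parts[i_gq])) else NA_integer_
    list(gt = code, dp = dp, gq = gq)
  }
  rows <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1L]]
    for (k in seq_along(alts)) {
      rec <- data.frame(
        chrom = fix$CHROM[r], pos = pos[r],
        id = ifelse(is.na(fix$ID[r]) | fix$ID[r] == ".",
                    paste0(fix$CHROM[r], ":", pos[r]), fix$ID[r]),
        ref = fix$REF[r], alt = alts[k],
        qual = suppressWarnings(as.numeric(fix$QUAL[r])),
        stringsAsFactors = FALSE)
      info <- fix$INFO[r]
      rec$depth <- suppressWarnings(as.integer(info_field(info, "DP")))
      rec$class <- info_field(info, "CLASS")
      rec$gene <- info_field(info, "GENE")
      for (s in samples) {
        ps <- parse_sample(gt[r, s], gt[r, "FORMAT"], k)
        rec[[paste0("gt_", s)]] <- ps$gt
        rec[[paste0("dp_", s)]] <- ps$dp
        rec[[paste0("gq_", s)]] <- ps$gq
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  attr(out, "samples") <- samples
  out
}

#' Write a variant table as a minimal VCF
#'
#' Emits a fixed minimal header (VCFv4.2; INFO DP/CLASS/GENE; FORMAT
#' GT:DP:GQ) so that write -> read -> write is byte-stable.
#'
#' @param variants a \code{variant_table} from [read_vcf_min()] or
#'   [simulate_trio_variants()].
#' @param path output path.
#' @export
write_vcf_min <- function(variants, path) {
  samples <- attr(variants, "samples")
  if (is.null(samples))
    samples <- sub("^gt_", "", grep("^gt_", names(variants), value = TRUE))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_code <- c(homref = "0/0", het = "0/1", homalt = "1/1", missing = "./.")
  recs <- vapply(seq_len(nrow(variants)), function(r) {
    info <- paste0(
      "DP=", ifelse(is.na(variants$depth[r]), ".", variants$depth[r]),
      ifelse(is.na(variants$class[r]), "", paste0(";CLASS=", variants$class[r])),
      ifelse(is.na(variants$gene[r]), "", paste0(";GENE=", variants$gene[r])))
    cells <- vapply(samples, function(s) {
      dp <- variants[[paste0("dp_", s)]][r]
      gq <- variants[[paste0("gq_", s)]][r]
      paste(gt_code[[variants[[paste0("gt_", s)]][r]]],
            ifelse(is.na(dp), ".", dp), ifelse(is.na(gq), ".", gq), sep = ":")
    }, character(1L))
    paste(c(variants$chrom[r], variants$pos[r], variants$id[r],
            variants$ref[r], variants$alt[r],
            ifelse(is.na(variants$qual[r]), ".",
                   format(variants$qual[r], trim = TRUE)),
            "PASS", info, "GT:DP:GQ", cells), collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, recs), path)
  invisible(NULL)
}

#' Read a two-library gene count table
#'
#' Tab-separated with header \code{gene_id}, \code{length_bp},
#' \code{count_<wt-sample>}, \code{count_<mut-sample>}. Library totals are
#' the column sums.
#'
#' @param path TSV file.
#' @return A [count_table()].
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  cnt_cols <- grep("^count_", names(df), value = TRUE)
  if (length(cnt_cols) != 2L)
    stop("expected exactly two count_<sample> columns")
  count_table(df$gene_id, df$length_bp, df[[cnt_cols[1L]]],
              df[[cnt_cols[2L]]])
}

#' Write a count table as TSV
#' @param counts a [count_table()].
#' @param path output path.
#' @param samples names used in the \code{count_*} headers.
#' @export
write_counts <- function(counts, path, samples = c("wt", "mut")) {
  out <- data.frame(gene_id = counts$gene_id, length_bp = counts$length_bp,
                    a = counts$count_wt, b = counts$count_mut)
  names(out)[3:4] <- paste0("count_", samples)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a ranked gene list (TSV: gene_id, score)
#'
#' Rows are ordered by decreasing score; tied scores keep their input order.
#'
#' @param path TSV file with header \code{gene_id}, \code{score}.
#' @param source label; defaults to the file name.
#' @return A [ranked_list()].
#' @export
read_ranked_list <- function(path, source = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ranked_list(df$gene_id, df$score, source = source)
}

#' Read FASTA sequences as an uppercase named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write intervals as BED
#'
#' Internal coordinates are 1-based closed; BED is 0-based half-open, so
#' \code{start - 1} is written.
#'
#' @param intervals an [genomic_interval()] or list of them.
#' @param path output path.
#' @export
write_interval_bed <- function(intervals, path) {
  if (inherits(intervals, "f2_interval")) intervals <- list(intervals)
  lines <- vapply(intervals, function(iv)
    paste(iv$chrom, iv$start_bp - 1L, iv$end_bp, iv$provenance, sep = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(NULL)
}
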