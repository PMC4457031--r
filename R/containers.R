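#' Construct a pedigree table
#'
#' A pedigree is a data frame with one row per individual and columns
#' \code{id}, \code{sire}, \code{dam}, \code{sex} ("M"/"F"), \code{generation}
#' ("F0"/"F1"/"F2") and \code{phenotype} ("affected"/"unaffected"/"unknown").
#' Founders carry \code{"0"} for both parents. Parents must appear before
#' their offspring and generations must be consistent with parentage.
#'
#' @param df data frame with the columns listed above.
#' @return A \code{pedigree} object (a validated data frame).
#' @export
pedigree <- function(df) {
  needed <- c("id", "sire", "dam", "sex", "generation", "phenotype")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  df$id <- as.character(df$id)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  if (anyDuplicated(df$id))
    stop("duplicate individual id in pedigree: ",
         df$id[duplicated(df$id)][1L])
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (!all(df$generation %in% c("F0", "F1", "F2")))
    stop("generation must be one of F0, F1, F2")
  if (!all(df$phenotype %in% c("affected", "unaffected", "unknown")))
    stop("phenotype must be affected, unaffected or unknown")
  for (i in seq_len(nrow(df))) {
    for (p in c(df$sire[i], df$dam[i])) {
      if (p != "0") {
        j <- match(p, df$id)
        if (is.na(j))
          stop("parent '", p, "' of '", df$id[i], "' not in pedigree")
        if (j >= i)
          stop("parent '", p, "' must precede offspring '", df$id[i], "'")
      }
    }
  }
  gen_num <- c(F0 = 0L, F1 = 1L, F2 = 2L)[df$generation]
  for (i in seq_len(nrow(df))) {
    if (df$sire[i] != "0") {
      j <- match(df$sire[i], df$id)
      if (gen_num[j] != gen_num[i] - 1L)
        stop("generation of '", df$id[i], "' inconsistent with its parents")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Construct a genotype matrix
#'
#' Biallelic SNP genotypes stored as B-allele dosage in \{0, 1, 2\} with
#' \code{NA} for missing calls. Allele B is the alphabetically later allele;
#' the constructor swaps labels (and flips dosages) where needed so that the
#' coding is format-independent. Markers are sorted by (chromosome, position).
#'
#' @param markers data frame with columns \code{id}, \code{chrom}, \code{bp},
#'   \code{allele_a}, \code{allele_b}.
#' @param dosage integer matrix, individuals x markers, rownames = individual
#'   ids, colnames = marker ids.
#' @return A \code{genotype_matrix} object: list with elements \code{markers}
#'   and \code{dosage}.
#' @export
genotype_matrix <- function(markers, dosage) {
  needed <- c("id", "chrom", "bp", "allele_a", "allele_b")
  if (!all(needed %in% names(markers)))
    stop("markers needs columns: ", paste(needed, collapse = ", "))
  markers$id <- as.character(markers$id)
  if (anyDuplicated(markers$id))
    stop("duplicate marker id: ", markers$id[duplicated(markers$id)][1L])
  if (!is.matrix(dosage) || ncol(dosage) != nrow(markers))
    stop("dosage must be a matrix with one column per marker")
  if (is.null(rownames(dosage)))
    stop("dosage needs individual ids as rownames")
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate individual id in dosage rownames")
  colnames(dosage) <- markers$id
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  # enforce allele B = alphabetically later allele
  swap <- !is.na(markers$allele_b) & !is.na(markers$allele_a) &
    markers$allele_b < markers$allele_a
  if (any(swap)) {
    tmp <- markers$allele_a[swap]
    markers$allele_a[swap] <- markers$allele_b[swap]
    markers$allele_b[swap] <- tmp
    dosage[, swap] <- 2L - dosage[, swap]
  }
  ord <- order(markers$chrom, markers$bp)
  markers <- markers[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  if (any(stats::ave(markers$bp, markers$chrom,
                     FUN = function(x) c(1, diff(x))) <= 0))
    stop("marker positions must be strictly increasing within a chromosome")
  rownames(markers) <- NULL
  structure(list(markers = markers, dosage = dosage),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      nrow(x$markers), "markers on chromosome(s)",
      paste(unique(x$markers$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a genomic interval
#'
#' Coordinates are 1-based and inclusive on both ends everywhere in this
#' package; the length of an interval is \code{end - start + 1} bases. BED
#' export converts to 0-based half-open on write.
#'
#' @param chrom chromosome name.
#' @param start_bp,end_bp 1-based inclusive bounds, \code{start_bp <= end_bp}.
#' @param n_markers number of markers supporting the interval (optional).
#' @param provenance one of "ibd_scan", "refined", "manual".
#' @param marker_ids optional character vector of supporting marker ids; the
#'   first and last are the boundary markers.
#' @return An \code{f2_interval} object.
#' @export
genomic_interval <- function(chrom, start_bp, end_bp, n_markers = NA_integer_,
                             provenance = "manual", marker_ids = NULL) {
  if (start_bp > end_bp) stop("start_bp must be <= end_bp")
  if (start_bp < 1) stop("coordinates are 1-based; start_bp must be >= 1")
  structure(list(chrom = as.character(chrom), start_bp = start_bp,
                 end_bp = end_bp, n_markers = n_markers,
                 provenance = provenance, marker_ids = marker_ids),
            class = "f2_interval")
}

#' @exportS3Method base::print
print.f2_interval <- function(x, ...) {
  cat(sprintf("interval %s:%s-%s (%.3f Mb, %s markers, %s)\n", x$chrom,
              format(x$start_bp, big.mark = ","),
              format(x$end_bp, big.mark = ","),
              interval_length_mb(x),
              ifelse(is.na(x$n_markers), "?", x$n_markers), x$provenance))
  invisible(x)
}

#' Construct a two-library count table
#'
#' @param gene_id,length_bp character / integer vectors, one entry per gene.
#' @param count_wt,count_mut non-negative integer read counts for the
#'   wild-type and mutant libraries.
#' @param n_wt,n_mut library totals (uniquely aligned reads). Default: the
#'   column sums of the counts.
#' @return A \code{count_table} data frame with attributes \code{n_wt},
#'   \code{n_mut}.
#' @export
count_table <- function(gene_id, length_bp, count_wt, count_mut,
                        n_wt = sum(count_wt), n_mut = sum(count_mut)) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene id: ", gene_id[duplicated(gene_id)][1L])
  if (any(length_bp < 1)) stop("gene length must be >= 1 bp")
  if (any(count_wt < 0) || any(count_mut < 0)) stop("counts must be >= 0")
  df <- data.frame(gene_id = gene_id, length_bp = as.integer(length_bp),
                   count_wt = as.integer(count_wt),
                   count_mut = as.integer(count_mut),
                   stringsAsFactors = FALSE)
  attr(df, "n_wt") <- n_wt
  attr(df, "n_mut") <- n_mut
  class(df) <- c("count_table", "data.frame")
  df
}

#' Construct a ranked gene list
#'
#' Higher scores rank better. Ties keep their input order (stable sort).
#'
#' @param gene_id character vector, no duplicates.
#' @param score numeric scores, descending better.
#' @param source label for the ranking source.
#' @return A \code{ranked_list} data frame ordered by decreasing score.
#' @export
ranked_list <- function(gene_id, score, source = "unknown") {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene id in ranked list: ",
         gene_id[duplicated(gene_id)][1L])
  ord <- order(-score, method = "radix")  # radix sort is stable
  df <- data.frame(gene_id = gene_id[ord], score = score[ord],
                   stringsAsFactors = FALSE)
  attr(df, "source") <- source
  class(df) <- c("ranked_list", "data.frame")
  df
}

# internal: build a filter-trace row set; counts must conserve at every step
new_filter_trace <- function(steps, n_in, n_removed, n_out) {
  stopifnot(all(n_in == n_removed + n_out))
  structure(data.frame(step = steps, n_in = n_in, n_removed = n_removed,
                       n_out = n_out, stringsAsFactors = FALSE),
            class = c("filter_trace", "data.frame"))
}

#' @exportS3Method base::print
print.filter_trace <- function(x, ...) {
  cat("filter trace:\n")
  print.data.frame(x)
  invisible(x)
}
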