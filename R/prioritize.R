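#' Consensus of the top fraction of several ranked gene lists
#'
#' Takes the top \code{ceiling(fraction * n)} genes of each ranked list
#' (per-list length; ceiling so no convention would include a gene this one
#' excludes) and intersects across all lists. Pairwise overlap counts are
#' returned for Venn-style reporting.
#'
#' @param ranked_lists list of [ranked_list()] data frames (or ordered
#'   character vectors).
#' @param fraction top fraction per list, in (0, 1].
#' @return list with \code{consensus} (gene ids in every list's top
#'   fraction), \code{membership} (data frame gene x list, logical),
#'   \code{pairwise_counts} (matrix), \code{top_sizes}.
#' @export
top_fraction_consensus <- function(ranked_lists, fraction = 0.20) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (length(ranked_lists) < 2L) stop("need at least two ranked lists")
  ids_of <- function(x) if (is.data.frame(x)) x$gene_id else as.character(x)
  labels <- vapply(seq_along(ranked_lists), function(i)
    attr(ranked_lists[[i]], "source") %||% paste0("list_", i), character(1L))
  tops <- lapply(ranked_lists, function(rl) {
    ids <- ids_of(rl)
    utils::head(ids, ceiling(fraction * length(ids)))
  })
  names(tops) <- labels
  consensus <- Reduce(intersect, tops)
  union_ids <- unique(unlist(tops))
  membership <- data.frame(gene_id = union_ids, stringsAsFactors = FALSE)
  for (nm in labels) membership[[nm]] <- union_ids %in% tops[[nm]]
  pw <- outer(seq_along(tops), seq_along(tops),
              Vectorize(function(i, j) length(intersect(tops[[i]],
                                                        tops[[j]]))))
  dimnames(pw) <- list(labels, labels)
  list(consensus = consensus, membership = membership,
       pairwise_counts = pw,
       top_sizes = vapply(tops, length, integer(1L)))
}

#' Conservation fraction of a residue across an alignment window
#'
#' Fraction of non-focal species whose aligned residue equals the focal
#' species' residue at the given column. Gaps in non-focal species count as
#' mismatches; a gap at the focal residue is an error.
#'
#' @param alignment_window named character vector of equal-length aligned
#'   protein sequences.
#' @param focal_species name of the focal sequence.
#' @param position 1-based alignment column.
#' @return fraction in [0, 1].
#' @export
conservation_fraction <- function(alignment_window, focal_species,
                                  position) {
  if (!focal_species %in% names(alignment_window))
    stop("focal species not in alignment")
  lens <- nchar(alignment_window)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length")
  if (position < 1L || position > lens[1L])
    stop("position out of range")
  col <- substr(alignment_window, position, position)
  focal <- col[[focal_species]]
  if (focal == "-") stop("focal residue is a gap")
  others <- col[setdiff(names(alignment_window), focal_species)]
  if (length(others) == 0L) stop("alignment has no non-focal species")
  mean(others == focal)
}

#' Human coding-variant filter cascade
#'
#' Retains variants predicted damaging (score >= \code{damaging_min}),
#' conserved (conservation fraction >= \code{conservation_min}) and absent
#' from every required population database. Applied as a sequential cascade
#' whose trace conserves counts.
#'
#' @param variants data frame with columns \code{gene},
#'   \code{protein_change}, \code{damaging_score}, \code{conservation}, and
#'   one logical \code{present_<db>} column per database.
#' @param damaging_min minimum damaging score (default 0.85, the
#'   conventional "probably damaging" band).
#' @param conservation_min minimum conservation fraction (default 1 =
#'   fully conserved).
#' @param required_absent_dbs database names the variant must be absent
#'   from; each needs a \code{present_<db>} column.
#' @return list with \code{candidates} and \code{trace}.
#' @export
human_variant_filter <- function(variants, damaging_min = 0.85,
                                 conservation_min = 1.0,
                                 required_absent_dbs = c("g1000", "dbsnp",
                                                         "evs")) {
  db_cols <- paste0("present_", required_absent_dbs)
  missing_cols <- setdiff(db_cols, names(variants))
  if (length(missing_cols))
    stop("missing database flag column(s): ",
         paste(missing_cols, collapse = ", "))
  n0 <- nrow(variants)
  keep1 <- !is.na(variants$damaging_score) &
    variants$damaging_score >= damaging_min
  v1 <- variants[keep1, , drop = FALSE]
  keep2 <- !is.na(v1$conservation) & v1$conservation >= conservation_min
  v2 <- v1[keep2, , drop = FALSE]
  present <- if (nrow(v2))
    Reduce(`|`, lapply(db_cols, function(cc) {
      flags <- v2[[cc]]
      if (any(is.na(flags))) stop("NA database flag in ", cc)
      flags
    }))
  else logical(0)
  v3 <- v2[!present, , drop = FALSE]
  ns <- c(n0, nrow(v1), nrow(v2), nrow(v3))
  trace <- new_filter_trace(c("damaging_score", "conservation",
                              "db_presence"),
                            ns[1:3], ns[1:3] - ns[2:4], ns[2:4])
  list(candidates = v3, trace = trace)
}
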