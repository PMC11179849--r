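#' Classify TE annotations as heterozygous, homozygous or partial
#'
#' Applies the reciprocal-overlap rule between TE annotations and the SV
#' deletion set: a TE is called heterozygous when its best-overlapping
#' deletion is spanned by the TE over more than 50 % of the deletion's
#' length and the deletion covers at least 80 % of the TE
#' (`frac_of_deletion > 0.5` strictly, `frac_of_te >= 0.8`). A TE with some
#' deletion overlap that fails those thresholds is `partial`; a TE with no
#' deletion overlap whose interval lies entirely within the aligned
#' regions is `homozygous`; anything else is `unresolved`. When several
#' deletions overlap one TE, the one with the most overlapping bp wins,
#' ties going to the leftmost.
#'
#' @param tes TE annotation tibble (`te_id`, `chrom`, `start`, `end`, ...).
#' @param deletions tibble of SV deletions: `chrom`, `start`, `end` and an
#'   id column (`variant_id` or `deletion_id`); e.g.
#'   `filter(variants, var_class == "SV", svtype == "DEL")` with
#'   `start = pos`, `end = pos + length`.
#' @param aligned aligned-region tibble from [aligned_regions()].
#' @param frac_deletion,frac_te the two reciprocal-overlap thresholds.
#' @return tibble: `te_id`, `label`, `overlap_bp`, `frac_of_deletion`,
#'   `frac_of_te`, `deletion_id`.
#' @export
classify_te_zygosity <- function(tes, deletions, aligned,
                                 frac_deletion = 0.5, frac_te = 0.8) {
  if (any(tes$end < tes$start) ||
      (nrow(deletions) && any(deletions$end < deletions$start)))
    stopf("negative-length interval")
  if (!"deletion_id" %in% names(deletions)) {
    deletions$deletion_id <- if ("variant_id" %in% names(deletions))
      deletions$variant_id else sprintf("del%05d", seq_len(nrow(deletions)))
  }
  te_gr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(tes$start + 1L, tes$end))
  del_gr <- GenomicRanges::GRanges(
    deletions$chrom, IRanges::IRanges(deletions$start + 1L, deletions$end))
  al_gr <- GenomicRanges::GRanges(
    aligned$chrom, IRanges::IRanges(aligned$start + 1L, aligned$end))

  hits <- GenomicRanges::findOverlaps(te_gr, del_gr)
  ov_w <- IRanges::width(IRanges::pintersect(
    te_gr[S4Vectors::queryHits(hits)], del_gr[S4Vectors::subjectHits(hits)]))
  ov <- tibble::tibble(te = S4Vectors::queryHits(hits),
                       del = S4Vectors::subjectHits(hits),
                       overlap = ov_w,
                       del_start = deletions$start[S4Vectors::subjectHits(hits)]) %>%
    dplyr::arrange(.data$te, dplyr::desc(.data$overlap), .data$del_start) %>%
    dplyr::distinct(.data$te, .keep_all = TRUE)

  # aligned coverage per TE (bp of the TE inside aligned regions)
  cov_hits <- GenomicRanges::findOverlaps(te_gr, al_gr)
  cov_w <- IRanges::width(IRanges::pintersect(
    te_gr[S4Vectors::queryHits(cov_hits)],
    al_gr[S4Vectors::subjectHits(cov_hits)]))
  cov_bp <- rep(0L, nrow(tes))
  if (length(cov_hits)) {
    agg <- rowsum(cov_w, S4Vectors::queryHits(cov_hits))
    cov_bp[as.integer(rownames(agg))] <- agg[, 1]
  }

  te_len <- tes$end - tes$start
  res <- tibble::tibble(te_id = tes$te_id, label = "unresolved",
                        overlap_bp = 0L, frac_of_deletion = NA_real_,
                        frac_of_te = NA_real_, deletion_id = NA_character_)
  if (nrow(ov)) {
    del_len <- deletions$end[ov$del] - deletions$start[ov$del]
    fd <- ov$overlap / del_len
    ft <- ov$overlap / te_len[ov$te]
    res$overlap_bp[ov$te] <- ov$overlap
    res$frac_of_deletion[ov$te] <- fd
    res$frac_of_te[ov$te] <- ft
    res$deletion_id[ov$te] <- deletions$deletion_id[ov$del]
    res$label[ov$te] <- ifelse(fd > frac_deletion & ft >= frac_te,
                               "heterozygous", "partial")
  }
  no_del <- res$label == "unresolved"
  res$label[no_del & cov_bp == te_len] <- "homozygous"
  res
}

# canonical right-shifted form of an insertion: while the first inserted
# base equals the next reference base, rotate rightwards. TSDs are direct
# repeats at the 3' end of the inserted material, so right-normalisation
# recovers the biological placement that left-aligned calls destroy.
right_align_insertion <- function(left, ins, right) {
  while (nchar(right) > 0 &&
         substr(ins, 1, 1) == substr(right, 1, 1)) {
    left <- paste0(left, substr(right, 1, 1))
    ins <- paste0(substr(ins, 2, nchar(ins)), substr(right, 1, 1))
    right <- substr(right, 2, nchar(right))
  }
  list(left = left, ins = ins)
}

#' Detect target-site duplications at SV insertion breakpoints
#'
#' For every insertion-type SV (or phase-0-specific deletion, whose
#' material is an insertion relative to phase-1), finds the largest
#' k <= `max_len` such that the k-mer immediately 5' of the breakpoint
#' equals the terminal k-mer of the inserted sequence (exact match).
#' Because the package stores left-normalised calls, each insertion is
#' first rotated to its rightmost equivalent placement; otherwise
#' left-alignment shifts the breakpoint through the duplicated site and
#' hides it. Matches of length < 2 are reported as not found.
#'
#' @param variants variant tibble; rows that are not sequence-bearing SVs
#'   are ignored.
#' @param p0 phase-0 genome (flank source; the 5' flank of the breakpoint
#'   is shared by both phases).
#' @param max_len largest TSD length searched.
#' @return tibble: `variant_id`, `tsd_length`, `tsd_sequence`, `found`.
#'   Breakpoints within `max_len` of a contig edge get `found = NA` with a
#'   warning.
#' @export
detect_tsd <- function(variants, p0, max_len = 20L) {
  if (max_len < 1) stopf("max_len must be >= 1")
  sv <- variants[variants$var_class == "SV" &
                   variants$svtype %in% c("INS", "DEL", "DUP_TANDEM",
                                          "DUP_INT") &
                   (nchar(variants$ref_allele) > 0 |
                      nchar(variants$alt_allele) > 0), ]
  res <- tibble::tibble(variant_id = sv$variant_id,
                        tsd_length = 0L, tsd_sequence = "", found = FALSE)
  n_edge <- 0L
  for (i in seq_len(nrow(sv))) {
    v <- sv[i, ]
    ins <- if (nchar(v$alt_allele) > 0) v$alt_allele else v$ref_allele
    n <- nchar(ins)
    chrom_len <- nchar(p0[[v$chrom]])
    if (v$pos < max_len || v$pos + n + max_len > chrom_len) {
      res$found[i] <- NA
      n_edge <- n_edge + 1L
      next
    }
    # for a DEL row the material sits in phase-0 at [pos, pos+n); its right
    # context starts after it. For an INS row the context starts at pos.
    is_del <- nchar(v$alt_allele) == 0
    right0 <- if (is_del) v$pos + n else v$pos
    left <- seq_sub(p0, v$chrom, max(v$pos - max_len - n, 0L), v$pos)
    right <- seq_sub(p0, v$chrom, right0,
                     min(right0 + n + max_len, chrom_len))
    ra <- right_align_insertion(left, ins, right)
    nl <- nchar(ra$left); ni <- nchar(ra$ins)
    kmax <- min(max_len, nl, ni)
    if (kmax < 2) next
    for (kk in seq(kmax, 2L)) {
      if (substr(ra$left, nl - kk + 1L, nl) ==
          substr(ra$ins, ni - kk + 1L, ni)) {
        res$tsd_length[i] <- kk
        res$tsd_sequence[i] <- substr(ra$ins, ni - kk + 1L, ni)
        res$found[i] <- TRUE
        break
      }
    }
  }
  if (n_edge)
    warning(sprintf("%d breakpoint(s) within %d bp of a contig edge: TSD not assessable",
                    n_edge, max_len))
  res
}

#' Distance from each TE to its nearest gene
#'
#' Distance is 0 for a TE overlapping a gene, otherwise the bp gap to the
#' nearest gene boundary. TEs on chromosomes without genes get `NA`.
#'
#' @param tes TE annotation tibble.
#' @param genes gene-model tibble.
#' @return `tes` with added `distance_to_gene` and `nearest_gene` columns.
#' @export
te_gene_distance <- function(tes, genes) {
  gs <- genes[genes$feature == "gene", ]
  te_gr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(tes$start + 1L, tes$end))
  g_gr <- GenomicRanges::GRanges(gs$chrom,
                                 IRanges::IRanges(gs$start + 1L, gs$end))
  hits <- GenomicRanges::distanceToNearest(te_gr, g_gr)
  dist <- rep(NA_integer_, nrow(tes))
  nearest <- rep(NA_character_, nrow(tes))
  qi <- S4Vectors::queryHits(hits)
  dist[qi] <- as.integer(S4Vectors::elementMetadata(hits)$distance)
  nearest[qi] <- gs$gene_id[S4Vectors::subjectHits(hits)]
  dplyr::mutate(tes, distance_to_gene = dist, nearest_gene = nearest)
}

#' Median TE-gene distance by zygosity label
#'
#' @param te_dist result of [te_gene_distance()], with a `label` or
#'   `zygosity` column.
#' @return tibble: `label`, `n`, `median_distance`.
#' @export
median_distance_by_zygosity <- function(te_dist) {
  lab <- if ("label" %in% names(te_dist)) te_dist$label else te_dist$zygosity
  tibble::tibble(label = lab, distance = te_dist$distance_to_gene) %>%
    dplyr::filter(!is.na(.data$distance)) %>%
    dplyr::group_by(.data$label) %>%
    dplyr::summarise(n = dplyr::n(),
                     median_distance = stats::median(.data$distance),
                     .groups = "drop")
}

#' Coverage density of features in fixed windows
#'
#' Fraction of each non-overlapping window covered by the union of the
#' features (overlaps merged before counting).
#'
#' @param features tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param window_bp window size in bp.
#' @return tibble of class `window_density`: `chrom`, `start`, `end`,
#'   `density` in `[0, 1]`; the final partial window is included.
#' @export
window_density <- function(features, chrom_lengths, window_bp = 1e5) {
  if (window_bp <= 0) stopf("window_bp must be > 0")
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    f <- features[features$chrom == ch, ]
    cov <- IRanges::coverage(
      IRanges::reduce(IRanges::IRanges(f$start + 1L, pmin(f$end, L))),
      width = L)
    starts <- seq(0L, L - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, L)
    vw <- IRanges::Views(cov, start = starts + 1L, end = ends)
    covered <- IRanges::viewSums(vw)
    out[[ch]] <- tibble::tibble(chrom = ch, start = starts, end = ends,
                                density = as.numeric(covered) /
                                  (ends - starts))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("window_density", class(res))
  res
}

#' Write a window-density track as BEDGRAPH
#'
#' @param density a [window_density()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(density, path) {
  readr::write_tsv(
    tibble::tibble(chrom = density$chrom, start = density$start,
                   end = density$end, value = round(density$density, 6)),
    path, col_names = FALSE)
  invisible(path)
}
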