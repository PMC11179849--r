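# Built-in anchor aligner: unique k-mer anchors, LIS chaining, gap closure.
# Intended for comparing two phases of the same genome (high identity);
# it is not a general-purpose aligner.

NUC_MAT <- NULL  # populated lazily (Biostrings matrix construction is slow)

nuc_mat <- function() {
  if (is.null(NUC_MAT)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
    utils::assignInMyNamespace("NUC_MAT", m)
  }
  NUC_MAT
}

# ops for one closed gap (ref piece ga vs query piece gb); plain
# list(op=, len=) vectors to keep the hot path allocation-light
align_gap_ops <- function(ga, gb) {
  la <- nchar(ga); lb <- nchar(gb)
  if (la == 0 && lb == 0) return(NULL)
  if (la == 0) return(list(op = "I", len = lb))
  if (lb == 0) return(list(op = "D", len = la))
  if (la == lb) {
    same <- charToRaw(ga) == charToRaw(gb)
    r <- rle(same)
    return(list(op = ifelse(r$values, "=", "X"),
                len = as.integer(r$lengths)))
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = gb, subject = ga, type = "global",
    substitutionMatrix = nuc_mat(), gapOpening = 6, gapExtension = 1)
  qs <- seq_char(as.character(Biostrings::alignedPattern(pa)))
  rs <- seq_char(as.character(Biostrings::alignedSubject(pa)))
  cls <- ifelse(rs == "-", "I", ifelse(qs == "-", "D",
                                       ifelse(qs == rs, "=", "X")))
  r <- rle(cls)
  list(op = r$values, len = as.integer(r$lengths))
}

# does this gap look like an inversion? (reverse-complement anchors beat
# forward anchors)
gap_is_inversion <- function(ga, gb, k) {
  if (nchar(ga) < 500 || nchar(gb) < 500) return(FALSE)
  ratio <- nchar(ga) / nchar(gb)
  if (ratio < 0.8 || ratio > 1.25) return(FALSE)
  fwd <- nrow(.kmer_anchors(ga, gb, k))
  rev <- nrow(.kmer_anchors(ga, revcomp(gb), k))
  rev > max(fwd * 2L, 2L)
}

#' Align two sequences (or genomes) with the built-in anchor aligner
#'
#' Finds k-mers that occur exactly once in each sequence, chains collinear
#' anchors with a longest-increasing-subsequence pass, and closes
#' inter-anchor gaps: equal-length gaps by direct comparison, unequal gaps
#' up to `max_gap` bp by global alignment, larger gaps as paired
#' deletion/insertion ops. Both orientations are tested; a gap whose two
#' sides align in reverse complement is emitted as a separate minus-strand
#' block (an inversion). Given named multi-sequence vectors, sequences are
#' paired by name.
#'
#' @param seq_a reference (phase-0) sequence(s): character vector, named if
#'   longer than one.
#' @param seq_b query (phase-1) sequence(s).
#' @param k anchor k-mer size (11-31).
#' @param max_gap largest gap closed by global alignment, bp.
#' @return alignment-block tibble (see [read_paf()]); zero rows when no
#'   unique anchors exist.
#' @export
anchor_align <- function(seq_a, seq_b, k = 15L, max_gap = 10000L) {
  if (k < 11) stopf("k must be >= 11")
  if (any(!nzchar(seq_a)) || any(!nzchar(seq_b)))
    stopf("sequences must be non-empty")
  if (length(seq_a) > 1 || length(seq_b) > 1) {
    if (is.null(names(seq_a)) || is.null(names(seq_b)))
      stopf("multi-sequence inputs must be named")
    shared <- intersect(names(seq_a), names(seq_b))
    return(dplyr::bind_rows(lapply(shared, function(ch)
      anchor_align_seq(seq_a[[ch]], seq_b[[ch]], k, max_gap, ch, ch))))
  }
  anchor_align_seq(seq_a[[1]], seq_b[[1]], k, max_gap,
                   names(seq_a) %||% "seq_a", names(seq_b) %||% "seq_b")
}

anchor_align_seq <- function(a, b, k, max_gap, ref_name, query_name) {
  la <- nchar(a); lb <- nchar(b)
  fwd <- .kmer_anchors(a, b, k)
  bneg <- NULL
  if (nrow(fwd) < 2) {  # try the other orientation
    bneg <- revcomp(b)
    rev <- .kmer_anchors(a, bneg, k)
    if (nrow(rev) > nrow(fwd)) {
      blocks <- anchor_chain_blocks(a, bneg, rev, k, max_gap,
                                    ref_name, query_name, lb, minus = TRUE)
      return(blocks)
    }
  }
  if (nrow(fwd) == 0) return(empty_blocks())
  anchor_chain_blocks(a, b, fwd, k, max_gap, ref_name, query_name, lb,
                      minus = FALSE)
}

# chain anchors and compose blocks; `b` is already orientation-adjusted,
# `minus` records whether it was reverse-complemented.
anchor_chain_blocks <- function(a, b, anchors, k, max_gap,
                                ref_name, query_name, qlen_orig,
                                minus = FALSE) {
  idx <- .chain_lis(anchors[, 2])
  runs <- .collapse_runs(anchors[idx, 1], anchors[idx, 2], k)

  blocks <- list()
  ops <- list()
  blk_a0 <- runs[1, 1]; blk_b0 <- runs[1, 3]
  cur_a <- blk_a0; cur_b <- blk_b0
  flush_block <- function(end_a, end_b) {
    if (!length(ops)) return(invisible(NULL))
    op <- unlist(lapply(ops, `[[`, "op"), use.names = FALSE)
    len <- unlist(lapply(ops, `[[`, "len"), use.names = FALSE)
    grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
    all_ops <- list(op = op[!duplicated(grp)],
                    len = as.integer(rowsum(len, grp)[, 1]))
    blocks[[length(blocks) + 1L]] <<- make_block(
      ref_name, nchar(a), blk_a0, end_a,
      query_name, qlen_orig, blk_b0, end_b,
      if (minus) "-" else "+", all_ops, qlen_orig, minus)
    ops <<- list()
  }
  for (t in seq_len(nrow(runs))) {
    r <- runs[t, ]
    ga <- substr(a, cur_a + 1L, r[1])
    gb <- substr(b, cur_b + 1L, r[3])
    if (gap_is_inversion(ga, gb, k)) {
      # close the current block, emit the inverted segment on its own
      flush_block(cur_a, cur_b)
      inv <- anchor_align_seq(ga, revcomp(gb), k, max_gap,
                              ref_name, query_name)
      if (nrow(inv)) {
        inv1 <- inv[1, ]
        inv_ops <- cigar_ops(inv1$cigar)
        # lift the inverted block onto the full sequences; its query span
        # within gb was reported on rc(gb), so mirror it back
        ia0 <- cur_a + inv1$ref_start; ia1 <- cur_a + inv1$ref_end
        gb_len <- nchar(gb)
        ib0 <- cur_b + gb_len - inv1$query_end
        ib1 <- cur_b + gb_len - inv1$query_start
        blocks[[length(blocks) + 1L]] <- make_block(
          ref_name, nchar(a), ia0, ia1, query_name, qlen_orig, ib0, ib1,
          if (minus) "+" else "-", inv_ops, qlen_orig, minus)
      }
      blk_a0 <- r[1]; blk_b0 <- r[3]
    } else {
      gap_ops <- NULL
      if (nchar(ga) > max_gap || nchar(gb) > max_gap) {
        gap_ops <- list(op = c("D", "I")[c(nchar(ga) > 0, nchar(gb) > 0)],
                        len = c(nchar(ga), nchar(gb))[c(nchar(ga) > 0,
                                                        nchar(gb) > 0)])
      } else {
        gap_ops <- align_gap_ops(ga, gb)
      }
      if (!is.null(gap_ops)) ops[[length(ops) + 1L]] <- gap_ops
    }
    ops[[length(ops) + 1L]] <- list(op = "=", len = r[2] - r[1])
    cur_a <- r[2]; cur_b <- r[4]
  }
  flush_block(cur_a, cur_b)
  res <- dplyr::bind_rows(blocks)
  dplyr::arrange(res, .data$ref_start)
}

# build one block row; if the query side was reverse-complemented, convert
# its coordinates back to the original strand
make_block <- function(ref_name, ref_len, a0, a1, query_name, qlen, b0, b1,
                       strand, ops, qlen_orig, query_was_rc) {
  if (query_was_rc) {
    tmp0 <- qlen_orig - b1; tmp1 <- qlen_orig - b0
    b0 <- tmp0; b1 <- tmp1
  }
  tibble::tibble(ref_name = ref_name, ref_len = as.integer(ref_len),
                 ref_start = as.integer(a0), ref_end = as.integer(a1),
                 query_name = query_name, query_len = as.integer(qlen),
                 query_start = as.integer(b0), query_end = as.integer(b1),
                 strand = strand, mapq = 60L,
                 cigar = cigar_string(ops))
}
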