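# Alignment blocks are tibbles with one row per aligned block:
#   ref_name, ref_len, ref_start, ref_end   (target, 0-based half-open)
#   query_name, query_len, query_start, query_end (original query strand)
#   strand ("+"/"-"), mapq, cigar (e.g. "120=1X40I980=")
# CIGAR ops: =/X/M consume both sequences, I consumes query, D consumes
# reference. For "-" blocks the CIGAR describes the reverse complement of
# the query interval.

empty_blocks <- function() {
  tibble::tibble(ref_name = character(), ref_len = integer(),
                 ref_start = integer(), ref_end = integer(),
                 query_name = character(), query_len = integer(),
                 query_start = integer(), query_end = integer(),
                 strand = character(), mapq = integer(), cigar = character())
}

#' Split a CIGAR string into operations
#'
#' @param cigar CIGAR string (ops from `M=XID`).
#' @return tibble with `op` and `len` columns, in order.
#' @export
cigar_ops <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  if (!nrow(m) || nchar(paste0(m[, 1], collapse = "")) != nchar(cigar))
    stopf("malformed CIGAR: %s", substr(cigar, 1, 50))
  tibble::tibble(op = m[, 3], len = as.integer(m[, 2]))
}

cigar_string <- function(ops) paste0(ops$len, ops$op, collapse = "")

# collapse runs of identical neighbouring ops
compact_ops <- function(ops) {
  if (!nrow(ops)) return(ops)
  grp <- cumsum(c(TRUE, ops$op[-1] != ops$op[-nrow(ops)]))
  dplyr::summarise(dplyr::group_by(tibble::tibble(op = ops$op, len = ops$len,
                                                  grp = grp), grp),
                   op = .data$op[1], len = sum(.data$len), .groups = "drop") %>%
    dplyr::select("op", "len")
}

ref_span_of <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "D")])
query_span_of <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "I")])

#' Read pairwise alignments from PAF
#'
#' Parses standard 12-column PAF with a `cg:Z:` CIGAR tag into the package's
#' alignment-block tibble. Records without a CIGAR tag are dropped with a
#' warning giving their count; a line with fewer than 12 fields raises an
#' error naming the line.
#'
#' @param path PAF file path.
#' @return alignment-block tibble (0-based half-open coordinates).
#' @export
read_paf <- function(path) {
  ln <- readr::read_lines(path, progress = FALSE)
  ln <- ln[nzchar(ln)]
  if (!length(ln)) return(empty_blocks())
  rows <- vector("list", length(ln))
  dropped <- 0L
  for (i in seq_along(ln)) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      stopf("malformed PAF line %d: expected >= 12 fields, got %d",
            i, length(f))
    tag <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (!length(tag)) { dropped <- dropped + 1L; next }
    rows[[i]] <- tibble::tibble(
      ref_name = f[6], ref_len = as.integer(f[7]),
      ref_start = as.integer(f[8]), ref_end = as.integer(f[9]),
      query_name = f[1], query_len = as.integer(f[2]),
      query_start = as.integer(f[3]), query_end = as.integer(f[4]),
      strand = f[5], mapq = as.integer(f[12]),
      cigar = sub("^cg:Z:", "", tag[1]))
  }
  if (dropped)
    warning(sprintf("%d PAF record(s) without a cg:Z: CIGAR tag dropped",
                    dropped))
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_blocks())
  out
}

#' Write alignment blocks as PAF
#'
#' @param blocks alignment-block tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_paf <- function(blocks, path) {
  lines <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    ops <- cigar_ops(b$cigar)
    nmatch <- sum(ops$len[ops$op %in% c("=", "M")])
    paste(b$query_name, b$query_len, b$query_start, b$query_end, b$strand,
          b$ref_name, b$ref_len, b$ref_start, b$ref_end,
          nmatch, sum(ops$len), b$mapq,
          paste0("cg:Z:", b$cigar), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Reference intervals covered by the alignment
#'
#' Returns the union of reference positions consumed by match ops (`=`,
#' `X`, `M`) of plus-strand blocks, keeping deletions shorter than
#' `min_unaligned` inside the covered region (a small heterozygous indel
#' does not interrupt alignment coverage, a structural deletion does).
#' Used for the homozygosity side of TE classification.
#'
#' @param blocks alignment-block tibble.
#' @param min_unaligned deletions at least this long break coverage.
#' @return tibble `chrom`, `start`, `end` (0-based half-open, merged).
#' @export
aligned_regions <- function(blocks, min_unaligned = SV_MIN_LEN) {
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (b$strand != "+") next
    ops <- cigar_ops(b$cigar)
    rp <- b$ref_start
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("=", "X", "M") || (op == "D" && len < min_unaligned)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = b$ref_name, start = rp, end = rp + len)
      }
      if (op %in% c("=", "X", "M", "D")) rp <- rp + len
    }
  }
  if (!length(out))
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  tb <- dplyr::bind_rows(out)
  res <- list()
  for (ch in unique(tb$chrom)) {
    ir <- IRanges::reduce(IRanges::IRanges(tb$start[tb$chrom == ch] + 1L,
                                           tb$end[tb$chrom == ch]))
    res[[ch]] <- tibble::tibble(chrom = ch,
                                start = IRanges::start(ir) - 1L,
                                end = IRanges::end(ir))
  }
  dplyr::bind_rows(res)
}
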