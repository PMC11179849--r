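#' Extract variants from alignment blocks
#'
#' Walks the CIGAR of every plus-strand block: mismatch columns become
#' SNPs; insertion/deletion runs of 1-39 bp become INDELs and runs of 40 bp
#' or more structural variants (adjacent I/D ops are merged before size
#' classification, so one biological event split at an anchor seam is not
#' counted twice). Minus-strand blocks flanked by plus-strand alignment
#' are reported once as inversions with reference-span length; a
#' minus-strand block covering a whole sequence is an orientation artefact
#' and is skipped. Indels and SVs are left-normalised against phase-0, and
#' SV insertions whose sequence matches the adjacent (tandem) or a distant
#' (interspersed) reference interval at >= 90 % identity over >= 90 % of
#' their length are refined to `DUP_TANDEM` / `DUP_INT`.
#'
#' An insertion relative to phase-0 is material present in P1
#' (`phase = "P1"`), a deletion is material present only in P0
#' (`phase = "P0"`); SNPs carry `phase = "both"` since neither allele is
#' privileged.
#'
#' @param blocks alignment-block tibble ([anchor_align()] or [read_paf()]).
#' @param p0,p1 named character vectors of phase sequences.
#' @param classify_dups refine SV insertions into duplication classes.
#' @return variant tibble (see [apply_variants()] for the representation).
#' @export
extract_variants <- function(blocks, p0, p1, classify_dups = TRUE) {
  if (!nrow(blocks)) return(empty_variants())
  check_chrom_match(p0, blocks$ref_name)
  out <- list()
  for (ch in unique(blocks$ref_name)) {
    bl <- blocks[blocks$ref_name == ch, ]
    bl <- bl[order(bl$ref_start), ]
    has_plus <- any(bl$strand == "+")
    for (i in seq_len(nrow(bl))) {
      b <- bl[i, ]
      if (b$strand == "-") {
        whole <- b$ref_start == 0 && b$ref_end == b$ref_len
        if (whole || !has_plus) next
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = ch, pos = b$ref_start, svtype = "INV",
          ref_allele = "", alt_allele = "", phase = "both",
          length = b$ref_end - b$ref_start)
        next
      }
      out[[length(out) + 1L]] <- walk_block(b, p0, p1)
    }
  }
  v <- dplyr::bind_rows(out)
  if (!nrow(v)) return(empty_variants())
  v$var_class <- ifelse(
    v$svtype == "INV", "SV",
    variant_class_of(ifelse(v$svtype == "none", 1L, nchar(v$ref_allele)),
                     ifelse(v$svtype == "none", 1L, nchar(v$alt_allele))))
  v$length <- as.integer(ifelse(v$svtype == "INV", v$length,
                                ifelse(v$svtype == "none", 1L,
                                       pmax(nchar(v$ref_allele),
                                            nchar(v$alt_allele)))))
  v <- normalize_variants(v, p0)
  if (classify_dups) v <- annotate_duplications(v, p0)
  finish_variants(v)
}

# CIGAR walk of one plus-strand block
walk_block <- function(b, p0, p1) {
  ops <- cigar_ops(b$cigar)
  if (ref_span_of(ops) != b$ref_end - b$ref_start)
    stopf("block %s:%d-%d: CIGAR reference span (%d) disagrees with block",
          b$ref_name, b$ref_start, b$ref_end, ref_span_of(ops))
  a <- p0[[b$ref_name]]; q <- p1[[b$query_name]]
  if (b$ref_end > nchar(a) || b$query_end > nchar(q))
    stopf("block extends past sequence end on %s", b$ref_name)
  rp <- b$ref_start; qp <- b$query_start
  rows <- list()
  # pending merged indel event
  pend <- NULL  # list(pos, ref, alt)
  flush_pend <- function() {
    if (is.null(pend)) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      chrom = b$ref_name, pos = pend$pos,
      svtype = if (nchar(pend$alt) > nchar(pend$ref)) "INS" else "DEL",
      ref_allele = pend$ref, alt_allele = pend$alt,
      phase = if (nchar(pend$alt) > nchar(pend$ref)) "P1" else "P0",
      length = 0L)
    pend <<- NULL
  }
  for (j in seq_len(nrow(ops))) {
    op <- ops$op[j]; len <- ops$len[j]
    if (op %in% c("=", "M", "X")) {
      flush_pend()
      if (op != "=") {
        ra <- substr(a, rp + 1L, rp + len)
        qa <- substr(q, qp + 1L, qp + len)
        mm <- mismatch_positions(ra, qa)
        if (length(mm))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            chrom = b$ref_name, pos = rp + mm - 1L, svtype = "none",
            ref_allele = seq_char(ra)[mm], alt_allele = seq_char(qa)[mm],
            phase = "both", length = 1L)
      }
      rp <- rp + len; qp <- qp + len
    } else if (op == "I") {
      ins <- substr(q, qp + 1L, qp + len)
      if (is.null(pend)) pend <- list(pos = rp, ref = "", alt = "")
      pend$alt <- paste0(pend$alt, ins)
      qp <- qp + len
    } else if (op == "D") {
      del <- substr(a, rp + 1L, rp + len)
      if (is.null(pend)) pend <- list(pos = rp, ref = "", alt = "")
      pend$ref <- paste0(pend$ref, del)
      rp <- rp + len
    } else {
      stopf("unsupported CIGAR op '%s'", op)
    }
  }
  flush_pend()
  dplyr::bind_rows(rows)
}

# identity of two equal-length strings
ident_frac <- function(x, y) {
  if (nchar(x) != nchar(y) || nchar(x) == 0) return(0)
  1 - .hamming(x, y) / nchar(x)
}

# refine SV insertions into tandem/interspersed duplication calls
annotate_duplications <- function(v, p0, min_ident = 0.9) {
  idx <- which(v$var_class == "SV" & v$svtype == "INS")
  for (i in idx) {
    ins <- v$alt_allele[i]
    n <- nchar(ins)
    chrom <- v$chrom[i]; pos <- v$pos[i]
    s <- p0[[chrom]]
    left <- substr(s, max(pos - n + 1L, 1L), pos)
    right <- substr(s, pos + 1L, pos + n)
    if (ident_frac(ins, left) >= min_ident ||
        ident_frac(ins, right) >= min_ident) {
      v$svtype[i] <- "DUP_TANDEM"
      next
    }
    # interspersed: seed with a central 21-mer, verify candidate loci
    if (n < 60) next
    mid <- n %/% 2L
    seed <- substr(ins, mid - 10L, mid + 10L)
    hits <- Biostrings::matchPattern(seed, Biostrings::DNAString(s))
    st <- Biostrings::start(hits)
    st <- st[abs(st - pos) > n]  # non-adjacent loci only
    for (h in utils::head(st, 5)) {
      c0 <- h - mid + 11L  # candidate start (1-based) aligning the seed
      cand <- substr(s, c0, c0 + n - 1L)
      if (ident_frac(ins, cand) >= min_ident) {
        v$svtype[i] <- "DUP_INT"
        break
      }
    }
  }
  v
}

#' Per-class variant density over a span
#'
#' @param variants variant tibble.
#' @param span_bp total bp of phased sequence considered.
#' @return tibble of class `density_report`: per variant class the count
#'   and the integer bp-per-variant, `floor(span / count)`; classes with
#'   zero variants are omitted.
#' @export
#' @examples
#' v <- tibble::tibble(var_class = rep(c("SNP", "INDEL"), c(10, 2)))
#' variant_density(v, 1e4)
variant_density <- function(variants, span_bp) {
  if (span_bp <= 0) stopf("span_bp must be > 0")
  d <- variants %>%
    dplyr::count(.data$var_class, name = "n") %>%
    dplyr::filter(.data$n > 0) %>%
    dplyr::mutate(bp_per_variant = as.integer(floor(span_bp / .data$n)))
  attr(d, "span_bp") <- span_bp
  class(d) <- c("density_report", class(d))
  d
}

validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "feature", "start", "end")
  if (!all(need %in% names(genes))) stopf("gene models lack required columns")
  bad <- genes$end < genes$start
  if (any(bad)) stopf("gene model with end < start")
  cds <- genes[genes$feature == "CDS", ]
  ex <- genes[genes$feature == "exon", ]
  for (g in unique(cds$gene_id)) {
    ci <- IRanges::IRanges(cds$start[cds$gene_id == g] + 1L,
                           cds$end[cds$gene_id == g])
    ei <- IRanges::reduce(IRanges::IRanges(ex$start[ex$gene_id == g] + 1L,
                                           ex$end[ex$gene_id == g]))
    if (sum(IRanges::width(IRanges::setdiff(ci, ei))) > 0)
      stopf("gene %s has CDS outside its exons", g)
  }
  invisible(genes)
}

# strand-aware regulatory windows
gene_flank_ranges <- function(gs, width, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  five <- (gs$strand == "+") == (side == "upstream")
  start1 <- ifelse(five, gs$start + 1L - width, gs$end + 1L)
  end1 <- ifelse(five, gs$start, gs$end + width)
  GenomicRanges::GRanges(gs$chrom, IRanges::IRanges(pmax(start1, 1L), end1))
}

#' Assign variants to genomic feature context
#'
#' Each variant is assigned one region by its phase-0 start position, with
#' priority CDS > intron > upstream > downstream > intergenic
#' (upstream/downstream windows are `flank_bp` wide, strand-aware).
#'
#' @param variants variant tibble.
#' @param genes gene-model tibble.
#' @param flank_bp regulatory window width in bp.
#' @return tibble: `var_class`, `region`, `n`, `pct` (percent within class,
#'   two decimals).
#' @export
feature_context <- function(variants, genes, flank_bp = 1000L) {
  validate_gene_models(genes)
  if (!nrow(variants))
    return(tibble::tibble(var_class = character(), region = character(),
                          n = integer(), pct = numeric()))
  pts <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos + 1L,
                                                 variants$pos + 1L))
  gs <- genes[genes$feature == "gene", ]
  cds <- genes[genes$feature == "CDS", ]
  ex <- genes[genes$feature == "exon", ]
  gr_of <- function(tb) GenomicRanges::GRanges(
    tb$chrom, IRanges::IRanges(tb$start + 1L, tb$end))
  span_r <- gr_of(gs)
  intron_r <- GenomicRanges::setdiff(span_r, gr_of(ex))
  regions <- list(
    CDS = gr_of(cds),
    intron = intron_r,
    upstream = gene_flank_ranges(gs, flank_bp, "upstream"),
    downstream = gene_flank_ranges(gs, flank_bp, "downstream"))
  region <- rep("intergenic", nrow(variants))
  for (nm in rev(names(regions)))  # apply in reverse priority, CDS wins last
    region[IRanges::overlapsAny(pts, regions[[nm]])] <- nm
  tibble::tibble(var_class = variants$var_class, region = region) %>%
    dplyr::count(.data$var_class, .data$region, name = "n") %>%
    dplyr::group_by(.data$var_class) %>%
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 2)) %>%
    dplyr::ungroup()
}
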