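# Gene architecture used by the simulator: three coding exons, two introns.
GENE_EXON_LENS <- c(150L, 300L, 150L)
GENE_INTRON_LENS <- c(120L, 180L)
GENE_SPAN <- sum(GENE_EXON_LENS) + sum(GENE_INTRON_LENS)
GENE_MARGIN <- 1200L  # clearance between a gene and its bin edges

# A random open reading frame: ATG, non-stop codons, one stop.
random_coding <- function(n_codons) {
  stopifnot(n_codons >= 2)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  stops <- names(gc)[gc == "*"]
  body <- sample(sense, n_codons - 2, replace = TRUE)
  paste(c("ATG", body, sample(stops, 1)), collapse = "")
}

# Age one consensus copy forward in time: for LTR elements the two LTRs
# drift independently (their divergence is what dating later reads out);
# the internal region and non-LTR elements drift as a single lineage.
aged_te_copy <- function(lib_row, age, mu) {
  s <- lib_row$sequence
  d <- mu * age
  if (lib_row$order == "LTR") {
    ll <- lib_row$ltr_len
    len <- lib_row$length
    ltr5 <- mutate_jc(substr(s, 1, ll), d)
    ltr3 <- mutate_jc(substr(s, len - ll + 1, len), d)
    internal <- mutate_jc(substr(s, ll + 1, len - ll), d)
    paste0(ltr5, internal, ltr3)
  } else {
    mutate_jc(s, d)
  }
}

te_annotation_row <- function(te_id, chrom, pos, lib_row, age, zygosity) {
  ll <- lib_row$ltr_len
  len <- lib_row$length
  tibble::tibble(
    te_id = te_id, chrom = chrom,
    start = pos, end = pos + len,
    order = lib_row$order, superfamily = lib_row$superfamily,
    intact = TRUE,
    ltr5_start = if (ll > 0) pos else NA_integer_,
    ltr5_end = if (ll > 0) pos + ll else NA_integer_,
    ltr3_start = if (ll > 0) pos + len - ll else NA_integer_,
    ltr3_end = if (ll > 0) pos + len else NA_integer_,
    consensus_id = lib_row$consensus_id,
    age = age, zygosity = zygosity
  )
}

#' Generate a reference (phase-0) genome with genes and resident TE copies
#'
#' Builds uniform-composition chromosomes, places one three-exon
#' protein-coding gene per `gene_spacing` bp (a painted open reading frame,
#' so codon-level effect prediction behaves sensibly) and one pre-existing
#' homozygous transposable-element copy per `te_spacing` bp of intergenic
#' space. Resident LTR retrotransposon copies are aged by forward
#' Jukes-Cantor simulation: each long terminal repeat accumulates
#' substitutions independently at `mu` per site per year for a uniform age
#' drawn from `ltr_age_range_hom`, and the element is flanked by its
#' target-site duplication where the order has one configured.
#'
#' @param params a [sim_params()] object.
#' @return list of class `sim_reference` with elements `genome` (named
#'   character vector of chromosome sequences), `genes` (gene-model tibble
#'   with `gene`, `exon` and `CDS` feature rows, 0-based half-open),
#'   `tes` (TE annotation tibble with LTR sub-intervals, true ages and
#'   zygosity `"homozygous"`) and `te_library`.
#' @export
#' @examples
#' ref <- generate_reference(sim_params(genome_length = 2e5, seed = 3))
#' names(ref$genome)
generate_reference <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  lib <- params$te_library
  if (is.null(lib)) lib <- default_te_library()
  if (params$gene_spacing < GENE_SPAN + 2 * GENE_MARGIN)
    stopf("gene_spacing too small to host a %d-bp gene model", GENE_SPAN)
  max_te_len <- max(lib$length) + max(c(params$tsd_len_by_order, 0L))
  if (params$te_spacing < max_te_len + 200L)
    stopf("te_spacing too small for the longest library element (%d bp)",
          max_te_len)

  with_seed(params$seed, {
    chroms <- sprintf("chr%d", seq_len(params$n_chromosomes))
    genome <- stats::setNames(
      vapply(chroms, function(x) random_dna(params$genome_length), character(1)),
      chroms)

    genes_l <- list(); tes_l <- list()
    gid <- 0L; tid <- 0L
    for (chrom in chroms) {
      L <- params$genome_length
      # genes: one per bin, painted ORF
      n_bins <- L %/% params$gene_spacing
      gene_spans <- IRanges::IRanges()
      for (b in seq_len(n_bins)) {
        gid <- gid + 1L
        bin0 <- (b - 1L) * params$gene_spacing
        gstart <- bin0 + sample.int(params$gene_spacing - GENE_SPAN -
                                      2L * GENE_MARGIN, 1) + GENE_MARGIN
        strand <- sample(c("+", "-"), 1)
        model <- build_gene_model(sprintf("gene%04d", gid), chrom, gstart, strand)
        genome[[chrom]] <- paint_gene(genome[[chrom]], model)
        genes_l[[length(genes_l) + 1L]] <- model
        gene_spans <- c(gene_spans,
                        IRanges::IRanges(gstart + 1L, gstart + GENE_SPAN))
      }
      # resident homozygous TE copies in intergenic space
      n_te_bins <- L %/% params$te_spacing
      for (b in seq_len(n_te_bins)) {
        tid <- tid + 1L
        bin0 <- (b - 1L) * params$te_spacing
        row <- lib[((tid - 1L) %% nrow(lib)) + 1L, ]
        tsd <- unname(params$tsd_len_by_order[row$order])
        if (is.na(tsd)) tsd <- 0L
        need <- row$length + tsd
        pos <- NA_integer_
        for (try in 1:1000) {
          cand <- bin0 + sample.int(max(params$te_spacing - need, 1L), 1)
          if (cand + need > L) next
          hit <- IRanges::countOverlaps(
            IRanges::IRanges(cand + 1L - 200L, cand + need + 200L), gene_spans)
          if (hit == 0) { pos <- cand; break }
        }
        if (is.na(pos))
          stopf("could not place TE copy %d: genome too crowded", tid)
        age <- stats::runif(1, params$ltr_age_range_hom[1],
                            params$ltr_age_range_hom[2])
        copy <- aged_te_copy(row, age, params$mu)
        substr(genome[[chrom]], pos + 1L, pos + row$length) <- copy
        if (tsd > 0) {  # duplicate the target site downstream of the element
          site <- substr(genome[[chrom]], pos + 1L - tsd, pos)
          substr(genome[[chrom]], pos + row$length + 1L,
                 pos + row$length + tsd) <- site
        }
        tes_l[[length(tes_l) + 1L]] <-
          te_annotation_row(sprintf("te%05d", tid), chrom, pos, row, age,
                            "homozygous")
      }
    }
    structure(list(genome = genome,
                   genes = dplyr::bind_rows(genes_l),
                   tes = dplyr::bind_rows(tes_l),
                   te_library = lib),
              class = "sim_reference")
  })
}

# Gene-model tibble for one gene: feature rows gene/exon/CDS, frames in
# transcript order; all exons coding.
build_gene_model <- function(gene_id, chrom, gstart, strand) {
  starts <- integer(3); ends <- integer(3)
  cur <- gstart
  for (i in 1:3) {
    starts[i] <- cur
    ends[i] <- cur + GENE_EXON_LENS[i]
    if (i < 3) cur <- ends[i] + GENE_INTRON_LENS[i]
  }
  order_tx <- if (strand == "+") 1:3 else 3:1
  frames <- integer(3)
  cum <- 0L
  for (i in order_tx) { frames[i] <- cum %% 3L; cum <- cum + GENE_EXON_LENS[i] }
  dplyr::bind_rows(
    tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                   feature = "gene", start = gstart, end = ends[3],
                   frame = NA_integer_),
    tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                   feature = "exon", start = starts, end = ends,
                   frame = NA_integer_),
    tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                   feature = "CDS", start = starts, end = ends, frame = frames)
  )
}

# Overwrite the CDS intervals of one gene with a fresh open reading frame.
paint_gene <- function(chrom_seq, model) {
  cds <- model[model$feature == "CDS", ]
  cds <- cds[order(cds$start), ]
  total <- sum(cds$end - cds$start)
  coding <- random_coding(total %/% 3L)
  strand <- cds$strand[1]
  if (strand == "-") coding_genomic <- revcomp(coding) else coding_genomic <- coding
  # genomic-order concatenation of CDS content equals coding (+) or its
  # reverse complement (-); split it across the CDS pieces in genomic order
  offset <- 0L
  for (i in seq_len(nrow(cds))) {
    w <- cds$end[i] - cds$start[i]
    piece <- substr(coding_genomic, offset + 1L, offset + w)
    substr(chrom_seq, cds$start[i] + 1L, cds$end[i]) <- piece
    offset <- offset + w
  }
  chrom_seq
}
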