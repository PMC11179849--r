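# File formats. Sequence and interval IO lean on Biostrings/rtracklayer;
# the VCF dialect written here (symbolic SV alleles with the full variant
# sequence in INFO/SEQ) is produced and consumed by this package.

#' Read/write genomes as FASTA
#'
#' @param path file path.
#' @return `read_genome_fasta()`: named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_genome_fasta
#' @param genome named character vector of chromosome sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

# ---- gene models ----------------------------------------------------------

#' Read and write gene models as GFF3
#'
#' Gene models are tibbles with one row per feature (`gene`, `exon`, `CDS`),
#' 0-based half-open coordinates, and a `frame` column for CDS rows
#' (cumulative coding length mod 3 at the feature's transcript start).
#'
#' @param genes gene-model tibble.
#' @param path file path.
#' @return `read_gene_models_gff3()` returns the gene-model tibble.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  gr$type <- genes$feature
  gr$ID <- ifelse(genes$feature == "gene", genes$gene_id,
                  sprintf("%s.%s.%d", genes$gene_id, genes$feature,
                          seq_len(nrow(genes))))
  gr$Parent <- ifelse(genes$feature == "gene", NA_character_, genes$gene_id)
  gr$phase <- ifelse(genes$feature == "CDS",
                     (3L - genes$frame) %% 3L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- as.character(S4Vectors::elementMetadata(gr)$Parent)
  parent[parent == "character(0)"] <- NA_character_
  id <- as.character(gr$ID)
  gene_id <- ifelse(is.na(parent) | parent == "NA", id, parent)
  phase <- suppressWarnings(as.integer(as.character(gr$phase)))
  tibble::tibble(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    frame = ifelse(is.na(phase), NA_integer_, (3L - phase) %% 3L)
  ) %>%
    dplyr::arrange(.data$chrom, .data$gene_id, .data$feature, .data$start)
}

# ---- TE annotations -------------------------------------------------------

#' Read and write TE annotations as GFF3
#'
#' One `transposable_element` feature per copy, with `long_terminal_repeat`
#' children for intact LTR retrotransposons. Order, superfamily, intactness,
#' consensus id and (for simulated data) truth age and zygosity travel as
#' GFF3 attributes.
#'
#' @param tes TE annotation tibble (see [generate_reference()]).
#' @param path file path.
#' @return `read_te_gff3()` returns the TE annotation tibble.
#' @export
write_te_gff3 <- function(tes, path) {
  main <- GenomicRanges::GRanges(
    tes$chrom, IRanges::IRanges(tes$start + 1L, tes$end), strand = "+")
  main$type <- "transposable_element"
  main$ID <- tes$te_id
  main$te_order <- tes$order
  main$superfamily <- tes$superfamily
  main$intact <- as.character(tes$intact)
  main$consensus_id <- tes$consensus_id
  if (!is.null(tes$age)) main$age <- sprintf("%.6g", tes$age)
  if (!is.null(tes$zygosity)) main$zygosity <- tes$zygosity
  has_ltr <- !is.na(tes$ltr5_start)
  if (any(has_ltr)) {
    lt <- tes[has_ltr, ]
    ltr <- GenomicRanges::GRanges(
      rep(lt$chrom, 2),
      IRanges::IRanges(c(lt$ltr5_start, lt$ltr3_start) + 1L,
                       c(lt$ltr5_end, lt$ltr3_end)),
      strand = "+")
    ltr$type <- "long_terminal_repeat"
    ltr$ID <- c(sprintf("%s.ltr5", lt$te_id), sprintf("%s.ltr3", lt$te_id))
    ltr$Parent <- rep(lt$te_id, 2)
    main <- c(main, ltr)
  }
  rtracklayer::export(main, path, format = "gff3")
  invisible(path)
}

#' @rdname write_te_gff3
#' @export
read_te_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_main <- as.character(gr$type) == "transposable_element"
  main <- gr[is_main]
  tb <- tibble::tibble(
    te_id = as.character(main$ID),
    chrom = as.character(GenomicRanges::seqnames(main)),
    start = GenomicRanges::start(main) - 1L,
    end = GenomicRanges::end(main),
    order = as.character(main$te_order),
    superfamily = as.character(main$superfamily),
    intact = as.logical(main$intact),
    ltr5_start = NA_integer_, ltr5_end = NA_integer_,
    ltr3_start = NA_integer_, ltr3_end = NA_integer_,
    consensus_id = as.character(main$consensus_id))
  if (!is.null(main$age)) tb$age <- as.numeric(main$age)
  if (!is.null(main$zygosity)) tb$zygosity <- as.character(main$zygosity)
  ltr <- gr[!is_main]
  if (length(ltr)) {
    parent <- as.character(S4Vectors::elementMetadata(ltr)$Parent)
    for (i in seq_along(ltr)) {
      j <- match(parent[i], tb$te_id)
      if (is.na(j)) next
      s <- GenomicRanges::start(ltr)[i] - 1L
      e <- GenomicRanges::end(ltr)[i]
      if (grepl("ltr5$", as.character(ltr$ID[i]))) {
        tb$ltr5_start[j] <- s; tb$ltr5_end[j] <- e
      } else {
        tb$ltr3_start[j] <- s; tb$ltr3_end[j] <- e
      }
    }
  }
  dplyr::arrange(tb, .data$chrom, .data$start)
}

# ---- variants as VCF ------------------------------------------------------

#' Write a variant table as VCF 4.2
#'
#' SNPs and indels are written with explicit, anchored alleles; structural
#' variants (>= 40 bp) as symbolic `<INS>`/`<DEL>`/`<INV>` records with
#' `SVTYPE`, `SVLEN` and `END`, the full variant sequence in `INFO/SEQ`, and
#' the phase of presence in `INFO/PHASE`. Coordinates convert from the
#' package's 0-based representation to 1-based VCF positions.
#'
#' @param variants variant tibble.
#' @param path output path.
#' @param genome phase-0 genome (for anchor bases and contig headers).
#' @return the path, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome) {
  check_chrom_match(genome, variants$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class: SNP, INDEL or SV\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length, negative for deletions\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position on phase-0\">",
    "##INFO=<ID=SEQ,Number=1,Type=String,Description=\"Inserted or deleted sequence\">",
    "##INFO=<ID=PHASE,Number=1,Type=String,Description=\"Phase carrying the variant material\">",
    "##INFO=<ID=TEID,Number=1,Type=String,Description=\"Matching TE annotation id\">",
    "##INFO=<ID=CONS,Number=1,Type=String,Description=\"TE consensus id\">",
    "##INFO=<ID=AGE,Number=1,Type=Float,Description=\"Planted insertion age in years\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- c(sprintf("CLASS=%s", v$var_class),
              sprintf("PHASE=%s", v$phase))
    if (v$var_class == "SNP") {
      pos1 <- v$pos + 1L
      ref <- v$ref_allele; alt <- v$alt_allele
    } else if (v$var_class == "INDEL") {
      anchor <- seq_sub(genome, v$chrom, v$pos - 1L, v$pos)
      pos1 <- v$pos  # 1-based position of the anchor base
      if (nchar(v$ref_allele) > 0) {
        ref <- paste0(anchor, v$ref_allele); alt <- anchor
      } else {
        ref <- anchor; alt <- paste0(anchor, v$alt_allele)
      }
    } else {
      anchor <- seq_sub(genome, v$chrom, v$pos - 1L, v$pos)
      pos1 <- v$pos
      ref <- anchor
      alt <- sprintf("<%s>", ifelse(v$svtype %in% c("DUP_TANDEM", "DUP_INT"),
                                    "DUP", v$svtype))
      svlen <- if (v$svtype == "DEL") -v$length else v$length
      endp <- if (v$svtype %in% c("DEL", "INV")) v$pos + v$length else v$pos
      seqs <- if (nchar(v$ref_allele)) v$ref_allele else v$alt_allele
      info <- c(info, sprintf("SVTYPE=%s", v$svtype),
                sprintf("SVLEN=%d", svlen), sprintf("END=%d", endp))
      if (nchar(seqs)) info <- c(info, sprintf("SEQ=%s", seqs))
    }
    if ("te_id" %in% names(v) && !is.na(v$te_id))
      info <- c(info, sprintf("TEID=%s", v$te_id))
    if ("consensus_id" %in% names(v) && !is.na(v$consensus_id))
      info <- c(info, sprintf("CONS=%s", v$consensus_id))
    if ("age" %in% names(v) && !is.na(v$age))
      info <- c(info, sprintf("AGE=%.8g", v$age))
    rows[i] <- paste(v$chrom, pos1, v$variant_id, ref, alt, ".", "PASS",
                     paste(info, collapse = ";"), sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
  m
}

#' Read a VCF written by [write_variants_vcf()] back into a variant table
#'
#' @param path VCF path.
#' @return variant tibble in the package's 0-based representation.
#' @export
read_variants_vcf <- function(path) {
  ln <- readr::read_lines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) return(empty_variants())
  f <- stringr::str_split_fixed(ln, "\t", 8)
  chrom <- f[, 1]; pos1 <- as.integer(f[, 2]); id <- f[, 3]
  ref <- f[, 4]; alt <- f[, 5]; info <- f[, 8]
  cls <- info_field(info, "CLASS")
  phase <- info_field(info, "PHASE")
  svtype <- info_field(info, "SVTYPE")
  seqs <- info_field(info, "SEQ")
  te_id <- info_field(info, "TEID")
  cons <- info_field(info, "CONS")
  age <- as.numeric(info_field(info, "AGE"))
  out <- vector("list", length(ln))
  for (i in seq_along(ln)) {
    if (cls[i] == "SNP") {
      out[[i]] <- list(pos = pos1[i] - 1L, svtype = "none",
                       ref_allele = ref[i], alt_allele = alt[i], length = 1L)
    } else if (cls[i] == "INDEL") {
      if (nchar(ref[i]) > nchar(alt[i])) {
        ra <- substring(ref[i], 2); aa <- ""
      } else {
        ra <- ""; aa <- substring(alt[i], 2)
      }
      out[[i]] <- list(pos = pos1[i], svtype = ifelse(nzchar(ra), "DEL", "INS"),
                       ref_allele = ra, alt_allele = aa,
                       length = max(nchar(ra), nchar(aa)))
    } else {
      st <- svtype[i]
      sq <- ifelse(is.na(seqs[i]), "", seqs[i])
      svlen <- abs(as.integer(info_field(info[i], "SVLEN")))
      out[[i]] <- list(pos = pos1[i],
                       svtype = st,
                       ref_allele = ifelse(st == "DEL", sq, ""),
                       alt_allele = ifelse(st %in% c("DEL", "INV"), "", sq),
                       length = svlen)
    }
  }
  tb <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  res <- tibble::tibble(variant_id = id, chrom = chrom, pos = tb$pos,
                        var_class = cls, svtype = tb$svtype,
                        length = as.integer(tb$length),
                        ref_allele = tb$ref_allele, alt_allele = tb$alt_allele,
                        phase = phase)
  if (any(!is.na(te_id))) res$te_id <- te_id
  if (any(!is.na(cons))) res$consensus_id <- cons
  if (any(!is.na(age))) res$age <- age
  res
}

# ---- zygosity BED ---------------------------------------------------------

#' Read and write TE zygosity calls as BED6+1
#'
#' Columns: chrom, 0-based start, end, TE id, score 0, strand `+`, zygosity.
#'
#' @param tes tibble with `chrom`, `start`, `end`, `te_id`, `zygosity`.
#' @param path file path.
#' @return `read_te_zygosity_bed()` returns a tibble.
#' @export
write_te_zygosity_bed <- function(tes, path) {
  readr::write_tsv(
    tibble::tibble(chrom = tes$chrom, start = tes$start, end = tes$end,
                   name = tes$te_id, score = 0L, strand = "+",
                   zygosity = tes$zygosity),
    path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_te_zygosity_bed
#' @export
read_te_zygosity_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "te_id", "score",
                                "strand", "zygosity"),
                  col_types = "ciicicc", progress = FALSE) %>%
    dplyr::select("chrom", "start", "end", "te_id", "zygosity")
}

# ---- allele counts --------------------------------------------------------

#' Read and write allele-count tables
#'
#' Tab-separated with header: gene_id, organ, replicate, count_p0, count_p1.
#'
#' @param counts allele-count tibble.
#' @param path file path.
#' @return `read_allele_counts()` returns the tibble.
#' @export
write_allele_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  readr::read_tsv(path, col_types = "cccii", progress = FALSE)
}

# ---- fixture bundle -------------------------------------------------------

#' Write a complete synthetic-diploid fixture to a directory
#'
#' Emits both phase FASTAs, gene and TE GFF3s, the truth VCF, the TE
#' zygosity truth BED and an allele-count TSV (simulated here if not
#' supplied). Every file round-trips through the package's own readers.
#'
#' @param sim a [plant_variants()] result.
#' @param dir output directory (created if needed).
#' @param counts optional allele-count tibble; simulated from the truth set
#'   when `NULL`.
#' @return tibble listing the files written.
#' @export
write_fixture <- function(sim, dir, counts = NULL) {
  stopifnot(inherits(sim, "diploid_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stopf("cannot create directory '%s'", dir)
  }
  if (is.null(counts)) counts <- simulate_allele_counts(sim$truth, sim$params)
  paths <- c(p0 = "p0.fa", p1 = "p1.fa", genes = "genes.gff3",
             tes = "tes.gff3", variants = "truth_variants.vcf",
             zygosity = "te_zygosity.bed", counts = "allele_counts.tsv")
  paths <- vapply(paths, function(p) file.path(dir, p), character(1))
  write_genome_fasta(sim$p0, paths[["p0"]])
  write_genome_fasta(sim$p1, paths[["p1"]])
  write_gene_models_gff3(sim$genes, paths[["genes"]])
  write_te_gff3(sim$tes, paths[["tes"]])
  write_variants_vcf(sim$truth$variants, paths[["variants"]], sim$p0)
  write_te_zygosity_bed(sim$tes, paths[["zygosity"]])
  write_allele_counts(counts, paths[["counts"]])
  tibble::tibble(name = names(paths), path = unname(paths))
}
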