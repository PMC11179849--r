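# Shared variant-table machinery.
#
# A variant tibble has one row per difference between phase-0 and phase-1,
# in phase-0 coordinates (0-based):
#   chrom, pos, var_class ("SNP"/"INDEL"/"SV"), svtype ("INS"/"DEL"/"INV"/
#   "DUP_TANDEM"/"DUP_INT"/"none"), length, ref_allele (phase-0 material),
#   alt_allele (phase-1 material), phase ("P0"/"P1"/"both").
# An INS row holds material present only in phase-1 (alt_allele, ref empty);
# a DEL row holds material present only in phase-0 (ref_allele, alt empty).

SV_MIN_LEN <- 40L

variant_class_of <- function(ref_len, alt_len) {
  d <- pmax(ref_len, alt_len)
  dplyr::case_when(
    ref_len == 1L & alt_len == 1L ~ "SNP",
    d >= SV_MIN_LEN ~ "SV",
    TRUE ~ "INDEL"
  )
}

empty_variants <- function() {
  tibble::tibble(variant_id = character(), chrom = character(),
                 pos = integer(), var_class = character(),
                 svtype = character(), length = integer(),
                 ref_allele = character(), alt_allele = character(),
                 phase = character())
}

finish_variants <- function(v) {
  if (!nrow(v)) return(empty_variants())
  v <- dplyr::arrange(v, .data$chrom, .data$pos)
  v$variant_id <- sprintf("var%06d", seq_len(nrow(v)))
  dplyr::relocate(v, "variant_id")
}

#' Apply a variant table to a phase-0 genome
#'
#' Replays the edit script of a variant tibble onto phase-0 sequences,
#' producing the phase-1 sequences it encodes. This is the conservation
#' check of the whole representation: for a simulated pair,
#' `apply_variants(p0, truth)` must equal phase-1 exactly, and the same
#' holds for variants extracted from an alignment.
#'
#' @param genome named character vector of phase-0 chromosome sequences.
#' @param variants variant tibble in phase-0 coordinates; rows must not
#'   overlap. `INV` rows are skipped (orientation, not sequence content).
#' @return named character vector of edited (phase-1) sequences.
#' @export
apply_variants <- function(genome, variants) {
  check_chrom_match(genome, variants$chrom)
  for (chrom in unique(variants$chrom)) {
    v <- variants[variants$chrom == chrom & variants$svtype != "INV", ]
    v <- v[order(v$pos), ]
    s <- genome[[chrom]]
    pieces <- character(2L * nrow(v) + 1L)
    cursor <- 0L
    for (i in seq_len(nrow(v))) {
      p <- v$pos[i]
      if (p < cursor) stopf("overlapping variants at %s:%d", chrom, p)
      pieces[2L * i - 1L] <- substr(s, cursor + 1L, p)
      pieces[2L * i] <- v$alt_allele[i]
      cursor <- p + nchar(v$ref_allele[i])
    }
    pieces[2L * nrow(v) + 1L] <- substr(s, cursor + 1L, nchar(s))
    genome[[chrom]] <- paste(pieces, collapse = "")
  }
  genome
}

# Left-align indel/SV rows against the phase-0 sequence so that equivalent
# placements of the same event collapse to one canonical row. Pure
# insertions rotate their inserted string; pure deletions slide their
# interval. Mixed rows (both alleles non-empty) are left untouched.
normalize_variants <- function(variants, genome) {
  if (!nrow(variants)) return(variants)
  check_chrom_match(genome, variants$chrom)
  for (i in seq_len(nrow(variants))) {
    if (variants$var_class[i] == "SNP" || variants$svtype[i] == "INV") next
    ref <- variants$ref_allele[i]; alt <- variants$alt_allele[i]
    if (nchar(ref) > 0 && nchar(alt) > 0) next
    chrom <- variants$chrom[i]; pos <- variants$pos[i]
    s <- genome[[chrom]]
    if (nchar(alt) > 0) {           # insertion: rotate while shiftable
      ins <- alt
      n <- nchar(ins)
      while (pos > 0 &&
             substr(s, pos, pos) == substr(ins, n, n)) {
        ins <- paste0(substr(ins, n, n), substr(ins, 1, n - 1))
        pos <- pos - 1L
      }
      variants$alt_allele[i] <- ins
    } else {                        # deletion: slide interval left
      n <- nchar(ref)
      while (pos > 0 &&
             substr(s, pos, pos) == substr(s, pos + n, pos + n)) {
        pos <- pos - 1L
      }
      variants$ref_allele[i] <- substr(s, pos + 1L, pos + n)
    }
    variants$pos[i] <- pos
  }
  variants
}
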