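EFFECT_IMPACT <- c(
  frameshift_variant = "HIGH", stop_gained = "HIGH", stop_lost = "HIGH",
  gene_deleted = "HIGH",
  inframe_insertion = "MODERATE", inframe_deletion = "MODERATE",
  missense_variant = "MODERATE",
  synonymous_variant = "LOW",
  intron_variant = "MODIFIER", upstream_variant = "MODIFIER",
  downstream_variant = "MODIFIER", intergenic_variant = "MODIFIER")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# CDS coordinate map of one gene: genomic 0-based positions in transcript
# order (5' -> 3' of the mRNA).
cds_map <- function(genes, gene_id) {
  cds <- genes[genes$gene_id == gene_id & genes$feature == "CDS", ]
  cds <- cds[order(cds$start), ]
  pos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    seq(cds$start[i], cds$end[i] - 1L)))
  if (cds$strand[1] == "-") pos <- rev(pos)
  pos
}

classify_cds_snp <- function(v, map, strand, genome, warn_env) {
  ti <- match(v$pos, map)
  codon_i <- (ti - 1L) %/% 3L
  cpos <- map[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  bases <- vapply(cpos, function(p) seq_sub(genome, v$chrom, p, p + 1L),
                  character(1))
  alt_bases <- bases
  alt_bases[match(v$pos, cpos)] <- v$alt_allele
  if (strand == "-") {
    bases <- unname(COMPLEMENT[bases])
    alt_bases <- unname(COMPLEMENT[alt_bases])
  }
  ref_aa <- translate_codons(paste(bases, collapse = ""))
  alt_aa <- translate_codons(paste(alt_bases, collapse = ""))
  last_codon <- codon_i == (length(map) %/% 3L) - 1L
  if (ref_aa == "*" && !last_codon && !warn_env$warned) {
    warning("reference CDS contains an internal stop codon; classification proceeds")
    warn_env$warned <- TRUE
  }
  if (ref_aa == alt_aa) "synonymous_variant"
  else if (alt_aa == "*") "stop_gained"
  else if (ref_aa == "*" && last_codon) "stop_lost"
  else "missense_variant"
}

#' Predict the coding impact of variants on gene models
#'
#' snpEff-style classification. Every variant is paired with each gene
#' whose span (extended by `flank_bp` on both sides) it touches; the
#' touched region of highest severity (CDS > intron > upstream >
#' downstream) decides the term. CDS SNPs are translated in frame and
#' compared codon-wise (synonymous / missense / stop_gained / stop_lost);
#' CDS indels are frameshift when their net length change is not a
#' multiple of 3, otherwise inframe; a structural deletion containing a
#' whole gene is `gene_deleted`. Variants touching no gene are
#' `intergenic_variant`. Impacts: frameshift/stop/gene_deleted HIGH,
#' missense/inframe MODERATE, synonymous LOW, non-coding regions MODIFIER.
#'
#' @param variants variant tibble.
#' @param genes gene-model tibble.
#' @param genome phase-0 genome (codon lookup).
#' @param flank_bp upstream/downstream window, bp.
#' @return effect-call tibble: `variant_id`, `var_class`, `gene_id`,
#'   `region`, `effect`, `impact`.
#' @export
classify_effects <- function(variants, genes, genome, flank_bp = 1000L) {
  validate_gene_models(genes)
  if (!nrow(variants))
    return(tibble::tibble(variant_id = character(), var_class = character(),
                          gene_id = character(), region = character(),
                          effect = character(), impact = character()))
  gs <- genes[genes$feature == "gene", ]
  v_width <- pmax(nchar(variants$ref_allele), 1L)
  v_gr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos + 1L,
                                     variants$pos + v_width))
  g_ext <- GenomicRanges::GRanges(
    gs$chrom, IRanges::IRanges(pmax(gs$start + 1L - flank_bp, 1L),
                               gs$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(v_gr, g_ext)

  maps <- new.env()  # per-gene CDS map cache
  warn_env <- new.env(); warn_env$warned <- FALSE
  rows <- vector("list", length(hits) + nrow(variants))
  k <- 0L
  paired <- rep(FALSE, nrow(variants))
  for (h in seq_along(hits)) {
    vi <- S4Vectors::queryHits(hits)[h]
    gi <- S4Vectors::subjectHits(hits)[h]
    v <- variants[vi, ]
    g <- gs[gi, ]
    paired[vi] <- TRUE
    gid <- g$gene_id
    gm <- genes[genes$gene_id == gid, ]
    vs <- v$pos; ve <- v$pos + max(nchar(v$ref_allele), 1L)
    ov <- function(s, e) vs < e & ve > s
    cds <- gm[gm$feature == "CDS", ]
    in_cds <- any(ov(cds$start, cds$end))
    region <- if (in_cds) "CDS"
      else if (ov(g$start, g$end)) "intron"
      else {
        five_side <- if (g$strand == "+") vs < g$start else vs >= g$end
        if (five_side) "upstream" else "downstream"
      }
    effect <- NULL
    if (v$var_class == "SV" && v$svtype %in% c("DEL") &&
        vs <= g$start && ve >= g$end) {
      effect <- "gene_deleted"; region <- "CDS"
    } else if (region == "CDS") {
      if (v$var_class == "SNP") {
        if (!exists(gid, envir = maps, inherits = FALSE))
          assign(gid, cds_map(genes, gid), envir = maps)
        effect <- classify_cds_snp(v, get(gid, envir = maps), g$strand,
                                   genome, warn_env)
      } else {
        net <- abs(nchar(v$ref_allele) - nchar(v$alt_allele))
        ins <- nchar(v$alt_allele) > nchar(v$ref_allele)
        effect <- if (net %% 3L != 0L) "frameshift_variant"
          else if (ins) "inframe_insertion" else "inframe_deletion"
      }
    } else {
      effect <- paste0(region, "_variant")
    }
    k <- k + 1L
    rows[[k]] <- tibble::tibble(
      variant_id = v$variant_id, var_class = v$var_class, gene_id = gid,
      region = region, effect = effect,
      impact = unname(EFFECT_IMPACT[effect]))
  }
  if (any(!paired)) {
    vv <- variants[!paired, ]
    k <- k + 1L
    rows[[k]] <- tibble::tibble(
      variant_id = vv$variant_id, var_class = vv$var_class,
      gene_id = NA_character_, region = "intergenic",
      effect = "intergenic_variant", impact = "MODIFIER")
  }
  dplyr::bind_rows(rows[seq_len(k)])
}

#' Genes wholly contained in structural deletions (presence-absence genes)
#'
#' A gene whose full span lies inside a single SV deletion is absent from
#' the phase lacking that sequence.
#'
#' @param genes gene-model tibble.
#' @param deletions deletion tibble: `chrom`, `start`, `end` and an id
#'   column (as in [classify_te_zygosity()]).
#' @return tibble: `gene_id`, `deletion_id`.
#' @export
find_pav_genes <- function(genes, deletions) {
  gs <- genes[genes$feature == "gene", ]
  if (!nrow(deletions) || !nrow(gs))
    return(tibble::tibble(gene_id = character(), deletion_id = character()))
  if (!"deletion_id" %in% names(deletions)) {
    deletions$deletion_id <- if ("variant_id" %in% names(deletions))
      deletions$variant_id else sprintf("del%05d", seq_len(nrow(deletions)))
  }
  g_gr <- GenomicRanges::GRanges(gs$chrom,
                                 IRanges::IRanges(gs$start + 1L, gs$end))
  d_gr <- GenomicRanges::GRanges(
    deletions$chrom, IRanges::IRanges(deletions$start + 1L, deletions$end))
  hits <- GenomicRanges::findOverlaps(g_gr, d_gr, type = "within")
  tibble::tibble(
    gene_id = gs$gene_id[S4Vectors::queryHits(hits)],
    deletion_id = deletions$deletion_id[S4Vectors::subjectHits(hits)]) %>%
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
}

#' Summarise effect calls by variant class and impact
#'
#' @param effect_calls a [classify_effects()] result.
#' @return object of class `impact_summary`: `by_class` tibble
#'   (`var_class`, `impact`, `n`, `pct` to two decimals, within-class) and
#'   `n_genes_high`, the number of distinct genes with at least one HIGH
#'   call.
#' @export
impact_summary <- function(effect_calls) {
  if (!nrow(effect_calls)) stopf("no effect calls")
  by_class <- effect_calls %>%
    dplyr::count(.data$var_class, .data$impact, name = "n") %>%
    dplyr::group_by(.data$var_class) %>%
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 2)) %>%
    dplyr::ungroup()
  high_genes <- effect_calls %>%
    dplyr::filter(.data$impact == "HIGH", !is.na(.data$gene_id)) %>%
    dplyr::distinct(.data$gene_id)
  structure(list(by_class = by_class, n_genes_high = nrow(high_genes)),
            class = "impact_summary")
}

#' @export
print.impact_summary <- function(x, ...) {
  cat("Variant impact summary (percent within class)\n")
  print(x$by_class)
  cat(sprintf("genes with >= 1 HIGH-impact call: %d\n", x$n_genes_high))
  invisible(x)
}

#' @rdname impact_summary
#' @param x an `impact_summary` object.
#' @param ... unused.
#' @method tidy impact_summary
#' @export
tidy.impact_summary <- function(x, ...) x$by_class

#' @rdname impact_summary
#' @method glance impact_summary
#' @export
glance.impact_summary <- function(x, ...) {
  high <- x$by_class[x$by_class$impact == "HIGH", ]
  tibble::tibble(n_calls = sum(x$by_class$n),
                 n_high = sum(high$n),
                 n_genes_high = x$n_genes_high)
}
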