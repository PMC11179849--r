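# Allele-specific expression: SNP selection, allele counting and the
# per-gene, per-organ beta-binomial test.

#' Select informative coding SNPs for allele-specific read counting
#'
#' Keeps SNPs that fall inside a CDS interval and have no indel edge
#' closer than `min_indel_dist` bp (coordinate difference to the nearest
#' indel breakpoint; a SNP inside an indel interval has distance 0). Each
#' kept SNP is mapped to its gene; SNPs in overlapping genes yield one row
#' per gene, flagged `multi_gene`.
#'
#' @param variants variant tibble (SNPs and indels are taken from it).
#' @param genes gene-model tibble.
#' @param min_indel_dist exclusion radius around indels, bp; the boundary
#'   is exclusive (`distance >= min_indel_dist` is kept).
#' @return tibble: `chrom`, `pos`, `gene_id`, `p0_base`, `p1_base`,
#'   `dist_nearest_indel`, `multi_gene`.
#' @export
select_informative_snps <- function(variants, genes, min_indel_dist = 50L) {
  snps <- variants[variants$var_class == "SNP", ]
  indels <- variants[variants$var_class == "INDEL", ]
  if (!nrow(snps))
    return(tibble::tibble(chrom = character(), pos = integer(),
                          gene_id = character(), p0_base = character(),
                          p1_base = character(),
                          dist_nearest_indel = numeric(),
                          multi_gene = logical()))
  dist <- rep(Inf, nrow(snps))
  for (ch in unique(snps$chrom)) {
    si <- which(snps$chrom == ch)
    ind <- indels[indels$chrom == ch, ]
    if (!nrow(ind)) next
    w <- pmax(nchar(ind$ref_allele), 1L)
    edges <- sort(unique(c(ind$pos, ind$pos + w - 1L)))
    lo <- findInterval(snps$pos[si], edges)
    d_lo <- ifelse(lo == 0L, Inf, snps$pos[si] - edges[pmax(lo, 1L)])
    d_hi <- ifelse(lo == length(edges), Inf,
                   edges[pmin(lo + 1L, length(edges))] - snps$pos[si])
    d <- pmin(d_lo, d_hi)
    inside <- IRanges::overlapsAny(
      IRanges::IRanges(snps$pos[si] + 1L, snps$pos[si] + 1L),
      IRanges::IRanges(ind$pos + 1L, ind$pos + w))
    d[inside] <- 0
    dist[si] <- d
  }
  keep <- dist >= min_indel_dist
  snps <- snps[keep, ]; dist <- dist[keep]
  if (!nrow(snps))
    return(tibble::tibble(chrom = character(), pos = integer(),
                          gene_id = character(), p0_base = character(),
                          p1_base = character(),
                          dist_nearest_indel = numeric(),
                          multi_gene = logical()))
  cds <- genes[genes$feature == "CDS", ]
  s_gr <- GenomicRanges::GRanges(snps$chrom,
                                 IRanges::IRanges(snps$pos + 1L, snps$pos + 1L))
  c_gr <- GenomicRanges::GRanges(cds$chrom,
                                 IRanges::IRanges(cds$start + 1L, cds$end))
  hits <- GenomicRanges::findOverlaps(s_gr, c_gr)
  tb <- tibble::tibble(si = S4Vectors::queryHits(hits),
                       gene_id = cds$gene_id[S4Vectors::subjectHits(hits)]) %>%
    dplyr::distinct()
  n_genes <- tb %>% dplyr::count(.data$si)
  multi <- stats::setNames(n_genes$n > 1, n_genes$si)
  tibble::tibble(chrom = snps$chrom[tb$si], pos = snps$pos[tb$si],
                 gene_id = tb$gene_id,
                 p0_base = snps$ref_allele[tb$si],
                 p1_base = snps$alt_allele[tb$si],
                 dist_nearest_indel = dist[tb$si],
                 multi_gene = unname(multi[as.character(tb$si)])) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Aggregate per-site pileup counts into per-gene allele counts
#'
#' Reads matching a SNP's phase-0 base count towards P0, phase-1 base
#' towards P1; any other base is discarded. Counts are summed over each
#' gene's informative SNPs. A SNP with no coverage contributes (0, 0).
#'
#' @param pileups tibble: `chrom`, `pos` (0-based), `base`, `count`,
#'   `organ`, `replicate`.
#' @param informative_snps a [select_informative_snps()] result.
#' @return allele-count tibble: `gene_id`, `organ`, `replicate`,
#'   `count_p0`, `count_p1`.
#' @export
count_alleles <- function(pileups, informative_snps) {
  cells <- dplyr::distinct(pileups, .data$organ, .data$replicate)
  joined <- dplyr::inner_join(pileups, informative_snps,
                              by = c("chrom", "pos"),
                              relationship = "many-to-many")
  per_gene <- joined %>%
    dplyr::group_by(.data$gene_id, .data$organ, .data$replicate) %>%
    dplyr::summarise(
      count_p0 = sum(.data$count[.data$base == .data$p0_base]),
      count_p1 = sum(.data$count[.data$base == .data$p1_base]),
      .groups = "drop")
  tidyr::expand_grid(gene_id = unique(informative_snps$gene_id), cells) %>%
    dplyr::left_join(per_gene, by = c("gene_id", "organ", "replicate")) %>%
    dplyr::mutate(count_p0 = dplyr::coalesce(.data$count_p0, 0L),
                  count_p1 = dplyr::coalesce(.data$count_p1, 0L)) %>%
    dplyr::arrange(.data$gene_id, .data$organ, .data$replicate)
}

# beta-binomial pmf with mean pi and intra-class correlation rho
dbetabinom <- function(x, n, pi = 0.5, rho = 0) {
  if (rho <= 0) return(stats::dbinom(x, n, pi))
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  exp(lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b))
}

# two-sided exact test (minimum-likelihood method): total probability of
# outcomes no more likely than the observed one
betabinom_test <- function(x, n, pi = 0.5, rho = 0) {
  if (n == 0) return(NA_real_)
  all_p <- dbetabinom(0:n, n, pi, rho)
  obs <- all_p[x + 1]
  min(1, sum(all_p[all_p <= obs * (1 + 1e-7)]))
}

# method-of-moments intra-class correlation across genes: compares the
# replicate-level variance around each gene's own pooled proportion with
# its binomial expectation
estimate_rho <- function(x, n, gene) {
  ok <- n > 0
  x <- x[ok]; n <- n[ok]; gene <- gene[ok]
  if (!length(x)) return(0)
  tot_x <- rowsum(x, gene); tot_n <- rowsum(n, gene)
  pi_g <- (tot_x / tot_n)[match(gene, rownames(tot_x))]
  use <- pi_g > 0 & pi_g < 1
  if (!any(use)) return(0)
  x <- x[use]; n <- n[use]; pi_g <- pi_g[use]
  num <- sum((x - n * pi_g)^2 - n * pi_g * (1 - pi_g))
  den <- sum(n * (n - 1) * pi_g * (1 - pi_g))
  if (den <= 0) return(0)
  max(0, num / den)
}

#' Test allele-specific expression per gene and organ
#'
#' For each gene and organ, replicate counts are pooled and the phase-0
#' proportion tested against 0.5 with an exact two-sided beta-binomial
#' test. The beta-binomial intra-class correlation rho is estimated per
#' organ by method of moments across genes (floored at 0; with rho = 0 the
#' test reduces to an exact binomial test), absorbing replicate-level
#' overdispersion. P-values are Benjamini-Hochberg adjusted across genes
#' within each organ; `is_ase` flags q <= `fdr`. Gene-organ cells with no
#' reads are untestable and get `NA`s.
#'
#' @param records allele-count tibble (`gene_id`, `organ`, `replicate`,
#'   `count_p0`, `count_p1`).
#' @param fdr FDR threshold for the `is_ase` flag.
#' @param null_ratio the phase-0 proportion under the null.
#' @return object of class `ase_test`; see [tidy.ase_test()].
#' @export
test_ase <- function(records, fdr = 0.05, null_ratio = 0.5) {
  need <- c("gene_id", "organ", "replicate", "count_p0", "count_p1")
  if (!all(need %in% names(records))) stopf("records lack required columns")
  res <- list(); rho_tb <- list()
  for (org in unique(records$organ)) {
    r <- records[records$organ == org, ]
    tot <- r$count_p0 + r$count_p1
    if (all(tot == 0))
      warning(sprintf("organ %s has no reads at all: untestable", org))
    rho <- estimate_rho(r$count_p0, tot, r$gene_id)
    pooled <- r %>%
      dplyr::group_by(.data$gene_id) %>%
      dplyr::summarise(n_p0 = sum(.data$count_p0),
                       n_p1 = sum(.data$count_p1), .groups = "drop")
    pooled$p_value <- vapply(seq_len(nrow(pooled)), function(i)
      betabinom_test(pooled$n_p0[i], pooled$n_p0[i] + pooled$n_p1[i],
                     null_ratio, rho), numeric(1))
    pooled$q_value <- stats::p.adjust(pooled$p_value, method = "BH")
    res[[org]] <- dplyr::mutate(
      pooled, organ = org,
      log2_ratio = log2((.data$n_p0 + 1) / (.data$n_p1 + 1)),
      is_ase = .data$q_value <= fdr)
    rho_tb[[org]] <- tibble::tibble(organ = org, rho = rho)
  }
  results <- dplyr::bind_rows(res) %>%
    dplyr::select("gene_id", "organ", "n_p0", "n_p1", "log2_ratio",
                  "p_value", "q_value", "is_ase") %>%
    dplyr::arrange(.data$gene_id, .data$organ)
  structure(list(results = results, rho = dplyr::bind_rows(rho_tb),
                 fdr = fdr, null_ratio = null_ratio),
            class = "ase_test")
}

#' Percentage of expressed genes with allele-specific expression
#'
#' Truncated (not rounded) to one decimal, the convention used for
#' reporting ASE fractions.
#'
#' @param n_ase number of ASE genes.
#' @param n_expressed number of expressed genes with informative SNPs.
#' @return percentage with one decimal.
#' @export
#' @examples
#' ase_fraction(579, 6182)  # 9.3
ase_fraction <- function(n_ase, n_expressed) {
  if (n_expressed <= 0) stopf("n_expressed must be > 0")
  if (n_ase > n_expressed) stopf("n_ase cannot exceed n_expressed")
  floor(1000 * n_ase / n_expressed + 1e-9) / 10
}

#' Tidiers and plots for ASE test results
#'
#' @param x,object an `ase_test` object.
#' @param ... unused.
#' @return `tidy()`: the per-gene, per-organ result tibble; `glance()`:
#'   one-row summary with the number of tested and ASE genes and the
#'   truncated ASE percentage.
#' @method tidy ase_test
#' @export
tidy.ase_test <- function(x, ...) x$results

#' @rdname tidy.ase_test
#' @method glance ase_test
#' @export
glance.ase_test <- function(x, ...) {
  r <- x$results
  expressed <- r %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(expr = any(.data$n_p0 + .data$n_p1 > 0),
                     ase = any(.data$is_ase %in% TRUE), .groups = "drop")
  n_exp <- sum(expressed$expr)
  n_ase <- sum(expressed$ase & expressed$expr)
  tibble::tibble(
    n_genes = nrow(expressed), n_expressed = n_exp, n_ase = n_ase,
    pct_ase = if (n_exp > 0) ase_fraction(n_ase, n_exp) else NA_real_,
    n_organs = length(unique(r$organ)), fdr = x$fdr)
}

#' @rdname tidy.ase_test
#' @method autoplot ase_test
#' @export
autoplot.ase_test <- function(object, ...) {
  r <- object$results[!is.na(object$results$p_value), ]
  ggplot2::ggplot(r, ggplot2::aes(x = .data$log2_ratio,
                                  y = -log10(pmax(.data$q_value, 1e-300)),
                                  colour = .data$is_ase)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~organ) +
    ggplot2::labs(x = "log2(P0/P1)", y = "-log10 q",
                  colour = "ASE") +
    ggplot2::theme_minimal()
}

#' @export
print.ase_test <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "ASE beta-binomial test: %d genes x %d organs; %d expressed, %d ASE (%.1f%%) at FDR %.2f\n",
    g$n_genes, g$n_organs, g$n_expressed, g$n_ase,
    ifelse(is.na(g$pct_ase), 0, g$pct_ase), x$fdr))
  invisible(x)
}
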