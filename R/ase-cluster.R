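# Allelic-profile clustering and the SV / TE association tests.

#' Cluster allelic expression profiles of ASE genes
#'
#' Genes flagged ASE in at least one organ and with at least `min_reads`
#' total reads (P0 + P1) in every replicate of every organ are summarised
#' as a gene x organ matrix of mean phase-0 proportions and clustered
#' agglomeratively (Ward linkage on Euclidean distances); the tree is cut
#' at `k` clusters.
#'
#' @param ase an [test_ase()] result (or its `tidy()` tibble).
#' @param records the allele-count tibble the test was run on.
#' @param min_reads per-replicate minimum total reads.
#' @param k number of clusters to cut.
#' @return object of class `ase_clusters`: `assignments` (`gene_id`,
#'   `cluster`), `profiles` (`gene_id`, `organ`, `mean_p0_prop`) and the
#'   parameters.
#' @export
cluster_ase_profiles <- function(ase, records, min_reads = 10L, k = 4L) {
  res <- if (inherits(ase, "ase_test")) ase$results else ase
  ase_genes <- unique(res$gene_id[res$is_ase %in% TRUE])
  depth_ok <- records %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(ok = all(.data$count_p0 + .data$count_p1 >= min_reads),
                     .groups = "drop")
  eligible <- intersect(ase_genes, depth_ok$gene_id[depth_ok$ok])
  if (length(eligible) < k)
    stopf("only %d gene(s) eligible for clustering; choose k < %d",
          length(eligible), max(length(eligible), 1L))
  prof <- records %>%
    dplyr::filter(.data$gene_id %in% eligible) %>%
    dplyr::group_by(.data$gene_id, .data$organ) %>%
    dplyr::summarise(mean_p0_prop = mean(
      .data$count_p0 / (.data$count_p0 + .data$count_p1)), .groups = "drop")
  mat <- prof %>%
    tidyr::pivot_wider(names_from = "organ", values_from = "mean_p0_prop") %>%
    tibble::column_to_rownames("gene_id") %>%
    as.matrix()
  hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  structure(list(
    assignments = tibble::tibble(gene_id = names(cl),
                                 cluster = unname(cl)),
    profiles = prof, k = k, min_reads = min_reads, hclust = hc),
    class = "ase_clusters")
}

#' @export
print.ase_clusters <- function(x, ...) {
  cat(sprintf("ASE profile clustering: %d genes in %d clusters\n",
              nrow(x$assignments), x$k))
  print(dplyr::count(x$assignments, .data$cluster))
  invisible(x)
}

#' Tidiers and plots for ASE profile clusters
#'
#' @param x,object an `ase_clusters` object.
#' @param ... unused.
#' @method tidy ase_clusters
#' @export
tidy.ase_clusters <- function(x, ...) {
  dplyr::left_join(x$assignments, x$profiles, by = "gene_id")
}

#' @rdname tidy.ase_clusters
#' @method glance ase_clusters
#' @export
glance.ase_clusters <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$assignments), k = x$k,
                 min_reads = x$min_reads)
}

#' @rdname tidy.ase_clusters
#' @method autoplot ase_clusters
#' @export
autoplot.ase_clusters <- function(object, ...) {
  df <- tidy(object)
  ord <- object$assignments %>%
    dplyr::arrange(.data$cluster)
  df$gene_id <- factor(df$gene_id, levels = ord$gene_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$organ, y = .data$gene_id,
                                   fill = .data$mean_p0_prop)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0.5, limits = c(0, 1)) +
    ggplot2::labs(fill = "P0 fraction", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Flag genes with a heterozygous SV nearby
#'
#' A gene is `sv_near` when its span, extended by `window_bp` on both
#' sides, overlaps a heterozygous SV interval (deletions by their span,
#' insertions by their breakpoint).
#'
#' @param genes gene-model tibble.
#' @param svs SV tibble (`chrom`, `pos`, `length`, `svtype`).
#' @param window_bp extension, bp.
#' @return tibble: `gene_id`, `sv_near`.
#' @export
flag_sv_near <- function(genes, svs, window_bp = 1000L) {
  gs <- genes[genes$feature == "gene", ]
  if (!nrow(svs))
    return(tibble::tibble(gene_id = gs$gene_id, sv_near = FALSE))
  w <- ifelse(svs$svtype == "INS", 1L, pmax(svs$length, 1L))
  sv_gr <- GenomicRanges::GRanges(svs$chrom,
                                  IRanges::IRanges(svs$pos + 1L, svs$pos + w))
  g_gr <- GenomicRanges::GRanges(
    gs$chrom, IRanges::IRanges(pmax(gs$start + 1L - window_bp, 1L),
                               gs$end + window_bp))
  tibble::tibble(gene_id = gs$gene_id,
                 sv_near = IRanges::overlapsAny(g_gr, sv_gr))
}

#' Association between ASE and nearby heterozygous SVs
#'
#' Builds the 2x2 table (ASE / non-ASE) x (SV near / absent) and applies a
#' two-sided Fisher exact test.
#'
#' @param gene_status tibble with one row per tested gene: `gene_id`,
#'   `is_ase` (logical), `sv_near` (logical). Assemble with
#'   [flag_sv_near()] and the `tidy()` output of [test_ase()].
#' @return object of class `ase_enrichment`: the contingency table, both
#'   proportions (percent of genes with an SV nearby) and the Fisher
#'   p-value. An empty ASE set is flagged untestable (`p_value = NA`).
#' @export
sv_ase_enrichment <- function(gene_status) {
  stopifnot(all(c("gene_id", "is_ase", "sv_near") %in% names(gene_status)))
  tab <- table(factor(gene_status$is_ase, levels = c(TRUE, FALSE)),
               factor(gene_status$sv_near, levels = c(TRUE, FALSE)),
               dnn = c("ase", "sv_near"))
  untestable <- sum(tab["TRUE", ]) == 0 || sum(tab["FALSE", ]) == 0
  p <- if (untestable) NA_real_ else stats::fisher.test(tab)$p.value
  prop <- function(r) 100 * tab[r, "TRUE"] / sum(tab[r, ])
  structure(list(table = tab,
                 pct_ase_with_sv = prop("TRUE"),
                 pct_non_ase_with_sv = prop("FALSE"),
                 p_value = p, untestable = untestable),
            class = "ase_enrichment")
}

#' @export
print.ase_enrichment <- function(x, ...) {
  cat(sprintf(
    "heterozygous SV near gene: %.1f%% of ASE genes vs %.1f%% of non-ASE genes\n",
    x$pct_ase_with_sv, x$pct_non_ase_with_sv))
  cat(sprintf("Fisher two-sided p: %s\n",
              ifelse(is.na(x$p_value), "untestable",
                     format(x$p_value, digits = 4))))
  invisible(x)
}

#' Tidiers for SV-ASE enrichment
#'
#' @param x an `ase_enrichment` object.
#' @param ... unused.
#' @method tidy ase_enrichment
#' @export
tidy.ase_enrichment <- function(x, ...) {
  as.data.frame(x$table) %>%
    tibble::as_tibble() %>%
    stats::setNames(c("ase", "sv_near", "n"))
}

#' @rdname tidy.ase_enrichment
#' @method glance ase_enrichment
#' @export
glance.ase_enrichment <- function(x, ...) {
  tibble::tibble(pct_ase_with_sv = x$pct_ase_with_sv,
                 pct_non_ase_with_sv = x$pct_non_ase_with_sv,
                 p_value = x$p_value)
}

#' Partition genes by upstream TE insertion zygosity
#'
#' A gene is grouped by the zygosity of TE insertions overlapping its
#' upstream window (`heterozygous` wins over `homozygous` when both are
#' present).
#'
#' @param genes gene-model tibble.
#' @param te_calls TE tibble with `chrom`, `start`, `end` and a zygosity
#'   column (`label` or `zygosity`).
#' @param window_bp upstream window, bp (strand-aware).
#' @return tibble: `gene_id`, `group` in `{none, homozygous, heterozygous}`.
#' @export
assign_te_upstream_group <- function(genes, te_calls, window_bp = 1000L) {
  gs <- genes[genes$feature == "gene", ]
  lab <- if ("label" %in% names(te_calls)) te_calls$label else te_calls$zygosity
  up <- gene_flank_ranges(gs, window_bp, "upstream")
  te_gr <- GenomicRanges::GRanges(
    te_calls$chrom, IRanges::IRanges(te_calls$start + 1L, te_calls$end))
  hits <- GenomicRanges::findOverlaps(up, te_gr)
  grp <- rep("none", nrow(gs))
  for (h in seq_along(hits)) {
    gi <- S4Vectors::queryHits(hits)[h]
    z <- lab[S4Vectors::subjectHits(hits)[h]]
    if (z == "heterozygous") grp[gi] <- "heterozygous"
    else if (z == "homozygous" && grp[gi] == "none") grp[gi] <- "homozygous"
  }
  tibble::tibble(gene_id = gs$gene_id, group = grp)
}

#' Log-scale expression from allele-count records
#'
#' Total counts (P0 + P1) per gene and organ, averaged over replicates,
#' library-size scaled to counts-per-million within organ and transformed
#' as log2(1 + CPM).
#'
#' @param records allele-count tibble.
#' @return tibble: `gene_id`, `organ`, `log_expr`.
#' @export
expression_from_counts <- function(records) {
  records %>%
    dplyr::mutate(total = .data$count_p0 + .data$count_p1) %>%
    dplyr::group_by(.data$organ, .data$replicate) %>%
    dplyr::mutate(cpm = 1e6 * .data$total / sum(.data$total)) %>%
    dplyr::group_by(.data$gene_id, .data$organ) %>%
    dplyr::summarise(log_expr = log2(1 + mean(.data$cpm)), .groups = "drop")
}

#' Compare gene expression across TE-insertion groups
#'
#' Genes are partitioned into no-TE, homozygous-TE and heterozygous-TE
#' groups (upstream TE presence); group medians and two-sided Wilcoxon
#' rank-sum p-values (no-TE vs homozygous, no-TE vs heterozygous) are
#' reported. A comparison with a group of fewer than 3 genes is
#' unavailable (`NA`).
#'
#' @param expr tibble with `gene_id` and `log_expr` (any log-like scale;
#'   the test is rank-based).
#' @param te_groups an [assign_te_upstream_group()] result.
#' @return object of class `te_expression`: `medians` tibble and `tests`
#'   tibble.
#' @export
te_expression_association <- function(expr, te_groups) {
  df <- dplyr::inner_join(expr, te_groups, by = "gene_id")
  med <- df %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(n = dplyr::n(),
                     median_expr = stats::median(.data$log_expr),
                     .groups = "drop")
  cmp <- function(g) {
    a <- df$log_expr[df$group == "none"]
    b <- df$log_expr[df$group == g]
    if (length(a) < 3 || length(b) < 3) return(NA_real_)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  tests <- tibble::tibble(
    comparison = c("none_vs_homozygous", "none_vs_heterozygous"),
    p_value = c(cmp("homozygous"), cmp("heterozygous")))
  structure(list(medians = med, tests = tests), class = "te_expression")
}

#' @export
print.te_expression <- function(x, ...) {
  cat("Gene expression by upstream TE zygosity\n")
  print(x$medians)
  print(x$tests)
  invisible(x)
}

#' Tidiers for TE-expression association
#'
#' @param x a `te_expression` object.
#' @param ... unused.
#' @method tidy te_expression
#' @export
tidy.te_expression <- function(x, ...) x$medians

#' @rdname tidy.te_expression
#' @method glance te_expression
#' @export
glance.te_expression <- function(x, ...) {
  tibble::tibble(p_none_vs_hom = x$tests$p_value[1],
                 p_none_vs_het = x$tests$p_value[2])
}
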