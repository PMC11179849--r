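#' Simulate allele-specific read counts per gene, organ and replicate
#'
#' For every gene x organ x replicate cell the total read count is drawn
#' negative-binomially (mean `mean_depth`, variance
#' `mu + nb_dispersion * mu^2`) and split between the two alleles
#' binomially with the gene's true phase-0 fraction from the truth set.
#' Deterministic for a fixed `params$seed`.
#'
#' @param truth the `truth` element of a [plant_variants()] result (or any
#'   list with a `gene_ratios` tibble: `gene_id`, `organ`, `ratio`).
#' @param params a [sim_params()] object.
#' @return allele-count tibble: `gene_id`, `organ`, `replicate`,
#'   `count_p0`, `count_p1`.
#' @export
simulate_allele_counts <- function(truth, params) {
  stopifnot(inherits(params, "sim_params"))
  gr <- truth$gene_ratios
  if (is.null(gr) || !nrow(gr)) stopf("truth has no gene_allelic ratios")
  if (params$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  with_seed(params$seed + 2L, {
    tab <- tidyr::expand_grid(
      gr, replicate = sprintf("rep%d", seq_len(params$n_replicates)))
    n <- nrow(tab)
    total <- stats::rnbinom(n, mu = params$mean_depth,
                            size = 1 / params$nb_dispersion)
    p0 <- stats::rbinom(n, total, tab$ratio)
    tibble::tibble(gene_id = tab$gene_id, organ = tab$organ,
                   replicate = tab$replicate,
                   count_p0 = p0, count_p1 = total - p0)
  })
}
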