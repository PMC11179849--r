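#' Parameters for the synthetic diploid generator
#'
#' Bundles every knob of the simulator into a validated list. The defaults
#' emulate a highly heterozygous woody-perennial genome: roughly one SNP per
#' 350 bp, one short indel (< 40 bp) per 921 bp and one structural variant
#' (>= 40 bp) per 15 432 bp of phased sequence, with about a third of the
#' structural variants caused by heterozygous transposable-element insertions
#' that carry a 5-nt target-site duplication when the element is an LTR
#' retrotransposon.
#'
#' @param genome_length bp per chromosome.
#' @param n_chromosomes number of chromosomes.
#' @param snp_rate per-bp SNP probability between the phases.
#' @param indel_rate per-bp short-indel probability (lengths 1-39 bp).
#' @param sv_rate per-bp structural-variant probability (lengths >= 40 bp).
#' @param te_sv_fraction fraction of structural variants realised as
#'   heterozygous TE insertions.
#' @param n_te_insertions optional explicit number of planted TE insertion
#'   events; overrides the rate-derived count when not `NULL`.
#' @param het_te_fraction fraction of planted TE insertion events that are
#'   heterozygous (present in one phase only).
#' @param te_library TE consensus records, see [default_te_library()].
#' @param tsd_len_by_order named integer map from TE order to target-site
#'   duplication length; LTR retrotransposons duplicate 5 nt. Orders absent
#'   from the map get no TSD.
#' @param ltr_age_range_het,ltr_age_range_hom insertion-age ranges (years)
#'   for heterozygous and homozygous LTR retrotransposon copies.
#' @param mu substitution rate (substitutions/site/year) used both to age
#'   planted elements forward in time and as the default for dating.
#' @param gene_spacing one multi-exon gene is placed per this many bp.
#' @param te_spacing one pre-existing homozygous TE copy is placed per this
#'   many bp of intergenic space.
#' @param n_organs,n_replicates design of the simulated expression data.
#' @param mean_depth expected reads per gene, organ and replicate.
#' @param nb_dispersion negative-binomial overdispersion of the per-gene
#'   totals (variance = mu + dispersion * mu^2); must be > 0.
#' @param ase_effect_fraction fraction of genes given a non-0.5 allelic ratio.
#' @param ase_effect_ratio the allelic ratio (phase-0 fraction) given to
#'   effect genes; the favoured allele is chosen at random per gene.
#' @param min_separation minimum bp between planted events, so that truth
#'   coordinates stay unambiguous after normalisation.
#' @param seed integer seed driving every stochastic draw of the run.
#'
#' @return A validated list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(genome_length = 2e5, seed = 7)
#' p$snp_rate
sim_params <- function(genome_length = 1e6,
                       n_chromosomes = 1,
                       snp_rate = 1 / 350,
                       indel_rate = 1 / 921,
                       sv_rate = 1 / 15432,
                       te_sv_fraction = 0.32,
                       n_te_insertions = NULL,
                       het_te_fraction = 0.5,
                       te_library = NULL,
                       tsd_len_by_order = c(LTR = 5L),
                       ltr_age_range_het = c(0, 5e6),
                       ltr_age_range_hom = c(2e6, 12e6),
                       mu = 1.3e-8,
                       gene_spacing = 5e4,
                       te_spacing = 2e4,
                       n_organs = 3,
                       n_replicates = 3,
                       mean_depth = 100,
                       nb_dispersion = 0.1,
                       ase_effect_fraction = 0.1,
                       ase_effect_ratio = 0.8,
                       min_separation = 50,
                       seed = 1L) {
  p <- list(
    genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    snp_rate = snp_rate, indel_rate = indel_rate, sv_rate = sv_rate,
    te_sv_fraction = te_sv_fraction,
    n_te_insertions = if (is.null(n_te_insertions)) NULL else as.integer(n_te_insertions),
    het_te_fraction = het_te_fraction,
    te_library = te_library,
    tsd_len_by_order = tsd_len_by_order,
    ltr_age_range_het = ltr_age_range_het,
    ltr_age_range_hom = ltr_age_range_hom,
    mu = mu,
    gene_spacing = as.integer(gene_spacing),
    te_spacing = as.integer(te_spacing),
    n_organs = as.integer(n_organs),
    n_replicates = as.integer(n_replicates),
    mean_depth = mean_depth,
    nb_dispersion = nb_dispersion,
    ase_effect_fraction = ase_effect_fraction,
    ase_effect_ratio = ase_effect_ratio,
    min_separation = as.integer(min_separation),
    seed = as.integer(seed)
  )
  rates <- c(p$snp_rate, p$indel_rate, p$sv_rate, p$te_sv_fraction,
             p$het_te_fraction, p$ase_effect_fraction)
  if (any(rates < 0 | rates > 1)) stopf("all rates must lie in [0, 1]")
  if (any(p$tsd_len_by_order < 0)) stopf("TSD lengths must be >= 0")
  if (p$mu <= 0) stopf("mu must be > 0")
  if (p$n_organs < 1 || p$n_replicates < 1)
    stopf("organ and replicate counts must be >= 1")
  if (p$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (p$genome_length < 10 * p$gene_spacing && p$genome_length < 1e5)
    NULL  # small genomes allowed; sizing is checked against annotations later
  if (p$ase_effect_ratio <= 0 || p$ase_effect_ratio >= 1)
    stopf("ase_effect_ratio must lie in (0, 1)")
  structure(p, class = "sim_params")
}

#' Built-in transposable-element consensus library
#'
#' Generates a small synthetic consensus library: two LTR retrotransposons
#' (a Gypsy- and a Copia-like element whose two long terminal repeats are
#' identical at insertion time), a CACTA-like terminal-inverted-repeat
#' element and a MITE. Sequences are random DNA drawn from the supplied seed,
#' so the library is deterministic per seed and carries no real genome
#' content.
#'
#' @param seed integer seed for the consensus sequences.
#' @param orders subset of orders to include.
#' @return tibble with one row per consensus: `consensus_id`, `order`,
#'   `superfamily`, `length`, `ltr_len` (0 for non-LTR orders) and `sequence`.
#' @export
default_te_library <- function(seed = 99L, orders = c("LTR", "TIR", "MITE")) {
  with_seed(seed, {
    make_ltr <- function(id, superfamily, ltr_len, internal_len) {
      ltr <- random_dna(ltr_len)
      tibble::tibble(
        consensus_id = id, order = "LTR", superfamily = superfamily,
        length = 2L * ltr_len + internal_len, ltr_len = as.integer(ltr_len),
        sequence = paste0(ltr, random_dna(internal_len), ltr)
      )
    }
    lib <- dplyr::bind_rows(
      make_ltr("GYPSY1", "Gypsy", 400L, 2200L),
      make_ltr("COPIA1", "Copia", 300L, 1400L),
      tibble::tibble(consensus_id = "CACTA1", order = "TIR",
                     superfamily = "CACTA", length = 1500L, ltr_len = 0L,
                     sequence = random_dna(1500)),
      tibble::tibble(consensus_id = "MITE1", order = "MITE",
                     superfamily = "Tourist", length = 300L, ltr_len = 0L,
                     sequence = random_dna(300))
    )
    dplyr::filter(lib, .data$order %in% orders)
  })
}
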