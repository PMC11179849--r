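# End-to-end orchestration: simulate (or load) -> align -> call variants ->
# classify TEs -> effects -> ASE, with one config and a checksum manifest.

#' Build a pipeline run configuration
#'
#' All numeric thresholds of the pipeline live here, with the defaults
#' used throughout the package: 40 bp SV boundary, 50 bp SNP-indel
#' exclusion, 1 kb regulatory windows, reciprocal-overlap fractions
#' (0.5, 0.8), TSD search up to 20 nt, FDR 5 %, 10-read clustering filter,
#' 100 kb density windows.
#'
#' @param simulate named list of [sim_params()] arguments (the simulated
#'   route), or `NULL` when `inputs` are given.
#' @param inputs named list of file paths (`p0`, `p1`, `genes`, `tes`,
#'   `counts`, optional `paf`), or `NULL` when simulating.
#' @param stages stages to run, in dependency order.
#' @param sv_min_len,indel_snp_distance,upstream_window,overlap_fracs,tsd_max,fdr,min_reads,window_density_bp,mu,anchor_k
#'   pipeline thresholds.
#' @param seed run seed; drives simulation and any stochastic step.
#' @param out_dir output directory.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       stages = c("simulate", "align", "callvars",
                                  "te_classify", "effects", "ase"),
                       sv_min_len = 40L, indel_snp_distance = 50L,
                       upstream_window = 1000L, overlap_fracs = c(0.5, 0.8),
                       tsd_max = 20L, fdr = 0.05, min_reads = 10L,
                       window_density_bp = 1e5, mu = 1.3e-8,
                       anchor_k = 15L, seed = 1L, out_dir = tempfile("run")) {
  if (is.null(simulate) && is.null(inputs))
    stopf("either simulation parameters or input paths are required")
  if (!is.null(inputs)) stages <- setdiff(stages, "simulate")
  thr <- c(sv_min_len, indel_snp_distance, upstream_window, overlap_fracs,
           tsd_max, fdr, min_reads, window_density_bp, mu, anchor_k)
  if (any(thr <= 0)) stopf("all thresholds must be positive")
  structure(list(simulate = simulate, inputs = inputs, stages = stages,
                 sv_min_len = as.integer(sv_min_len),
                 indel_snp_distance = as.integer(indel_snp_distance),
                 upstream_window = as.integer(upstream_window),
                 overlap_fracs = overlap_fracs,
                 tsd_max = as.integer(tsd_max), fdr = fdr,
                 min_reads = as.integer(min_reads),
                 window_density_bp = window_density_bp, mu = mu,
                 anchor_k = as.integer(anchor_k),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read/write a run configuration as YAML
#'
#' @param config a [run_config()] object.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order, writes each stage's
#' outputs under `config$out_dir` and returns a manifest with an MD5
#' checksum per file; a rerun with an identical config and seed is
#' byte-identical. Per-stage counters (variants by class, TE labels,
#' genes tested/ASE) are emitted as messages and returned.
#'
#' @param config a [run_config()] object.
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_run`: `manifest` tibble (`file`, `md5`,
#'   `stage`), `counters`, and the in-memory stage `results`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(); counters <- list(); res <- list()
  reg <- function(files, stage) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files)), stage = stage)
  }
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stopf("stage '%s' requires '%s' from an earlier stage", stage, what)
    res[[what]]
  }

  if ("simulate" %in% config$stages) {
    params <- do.call(sim_params, c(config$simulate %||% list(),
                                    list(seed = config$seed)))
    ref <- generate_reference(params)
    sim <- plant_variants(ref, params)
    counts <- simulate_allele_counts(sim$truth, params)
    fx_dir <- file.path(config$out_dir, "fixture")
    files <- write_fixture(sim, fx_dir, counts)
    reg(files$path, "simulate")
    res$p0 <- sim$p0; res$p1 <- sim$p1; res$genes <- sim$genes
    res$tes <- sim$tes; res$counts <- counts; res$sim <- sim
    say("simulate: %d truth variants, %d genes, %d TEs",
        nrow(sim$truth$variants), length(unique(sim$genes$gene_id)),
        nrow(sim$tes))
    counters$truth_variants <- nrow(sim$truth$variants)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    res$p0 <- read_genome_fasta(inp$p0)
    res$p1 <- read_genome_fasta(inp$p1)
    res$genes <- read_gene_models_gff3(inp$genes)
    if (!is.null(inp$tes)) res$tes <- read_te_gff3(inp$tes)
    if (!is.null(inp$counts)) res$counts <- read_allele_counts(inp$counts)
    if (!is.null(inp$paf)) res$blocks <- read_paf(inp$paf)
  }

  if ("align" %in% config$stages && is.null(res$blocks)) {
    p0 <- need("p0", "align"); p1 <- need("p1", "align")
    res$blocks <- anchor_align(p0, p1, k = config$anchor_k)
    paf <- file.path(config$out_dir, "alignment.paf")
    write_paf(res$blocks, paf)
    reg(paf, "align")
    say("align: %d block(s)", nrow(res$blocks))
  }

  if ("callvars" %in% config$stages) {
    blocks <- need("blocks", "callvars")
    res$variants <- extract_variants(blocks, res$p0, res$p1)
    vcf <- file.path(config$out_dir, "variants.vcf")
    write_variants_vcf(res$variants, vcf, res$p0)
    dens <- variant_density(res$variants, sum(nchar(res$p0)))
    fc <- feature_context(res$variants, res$genes,
                          flank_bp = config$upstream_window)
    d_path <- file.path(config$out_dir, "variant_density.tsv")
    f_path <- file.path(config$out_dir, "feature_context.tsv")
    readr::write_tsv(dens, d_path); readr::write_tsv(fc, f_path)
    reg(c(vcf, d_path, f_path), "callvars")
    counters$variants_by_class <- table(res$variants$var_class)
    say("callvars: %s", paste(sprintf("%s=%d",
                                      names(counters$variants_by_class),
                                      counters$variants_by_class),
                              collapse = " "))
  }

  if ("te_classify" %in% config$stages) {
    v <- need("variants", "te_classify"); tes <- need("tes", "te_classify")
    dels <- v[v$var_class == "SV" & v$svtype == "DEL", ]
    dels <- dplyr::transmute(dels, deletion_id = .data$variant_id,
                             chrom = .data$chrom, start = .data$pos,
                             end = .data$pos + .data$length)
    al <- aligned_regions(res$blocks, min_unaligned = config$sv_min_len)
    zyg <- classify_te_zygosity(tes, dels, al,
                                frac_deletion = config$overlap_fracs[1],
                                frac_te = config$overlap_fracs[2])
    res$zygosity <- zyg
    aged <- ltr_age_table(tes, res$p0, mu = config$mu)
    res$ages <- aged
    z_path <- file.path(config$out_dir, "te_zygosity.tsv")
    a_path <- file.path(config$out_dir, "ltr_ages.tsv")
    readr::write_tsv(zyg, z_path)
    readr::write_tsv(
      dplyr::select(aged, "te_id", "order", "superfamily",
                    "divergence", "age_estimate"), a_path)
    dens <- window_density(tes, nchar(res$p0),
                           window_bp = config$window_density_bp)
    bg <- file.path(config$out_dir, "te_density.bedgraph")
    write_bedgraph(dens, bg)
    reg(c(z_path, a_path, bg), "te_classify")
    counters$te_labels <- table(zyg$label)
    say("te_classify: %s", paste(sprintf("%s=%d", names(counters$te_labels),
                                         counters$te_labels),
                                 collapse = " "))
  }

  if ("effects" %in% config$stages) {
    v <- need("variants", "effects")
    calls <- classify_effects(v, res$genes, res$p0,
                              flank_bp = config$upstream_window)
    res$effects <- calls
    res$impact <- impact_summary(calls)
    e_path <- file.path(config$out_dir, "effects.tsv")
    s_path <- file.path(config$out_dir, "impact_summary.tsv")
    readr::write_tsv(calls, e_path)
    readr::write_tsv(res$impact$by_class, s_path)
    reg(c(e_path, s_path), "effects")
    say("effects: %d calls, %d genes with HIGH impact",
        nrow(calls), res$impact$n_genes_high)
    counters$genes_high_impact <- res$impact$n_genes_high
  }

  if ("ase" %in% config$stages) {
    counts <- need("counts", "ase"); v <- need("variants", "ase")
    info <- select_informative_snps(v, res$genes,
                                    min_indel_dist = config$indel_snp_distance)
    records <- counts[counts$gene_id %in% unique(info$gene_id), ]
    ase <- test_ase(records, fdr = config$fdr)
    res$informative_snps <- info
    res$ase <- ase
    g <- glance(ase)
    t_path <- file.path(config$out_dir, "ase_results.tsv")
    readr::write_tsv(tidy(ase), t_path)
    files <- t_path
    cl <- tryCatch(cluster_ase_profiles(ase, records,
                                        min_reads = config$min_reads),
                   error = function(e) NULL)
    if (!is.null(cl)) {
      res$clusters <- cl
      c_path <- file.path(config$out_dir, "ase_clusters.tsv")
      readr::write_tsv(tidy(cl), c_path)
      files <- c(files, c_path)
    }
    svs <- v[v$var_class == "SV" & v$svtype != "INV", ]
    status <- tidy(ase) %>%
      dplyr::group_by(.data$gene_id) %>%
      dplyr::summarise(is_ase = any(.data$is_ase %in% TRUE),
                       .groups = "drop") %>%
      dplyr::inner_join(flag_sv_near(res$genes, svs,
                                     window_bp = config$upstream_window),
                        by = "gene_id")
    enr <- tryCatch(sv_ase_enrichment(status), error = function(e) NULL)
    if (!is.null(enr)) {
      res$enrichment <- enr
      en_path <- file.path(config$out_dir, "sv_ase_enrichment.tsv")
      readr::write_tsv(glance(enr), en_path)
      files <- c(files, en_path)
    }
    reg(files, "ase")
    counters$genes_tested <- g$n_expressed
    counters$genes_ase <- g$n_ase
    say("ase: %d expressed genes, %d ASE (%.1f%%)",
        g$n_expressed, g$n_ase, ifelse(is.na(g$pct_ase), 0, g$pct_ase))
  }

  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  reg(cfg_path, "config")
  structure(list(manifest = dplyr::bind_rows(manifest),
                 counters = counters, results = res, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run: %d files in %s\n",
              nrow(x$manifest), x$config$out_dir))
  print(x$manifest)
  invisible(x)
}
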