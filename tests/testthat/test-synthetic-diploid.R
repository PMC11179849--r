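# Synthetic diploid generator: construction counts, rate calibration,
# conservation and file round-trips.

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(snp_rate = 1.2), "rates")
  expect_error(sim_params(mu = 0), "mu")
  expect_error(sim_params(n_organs = 0), "organ")
  expect_error(sim_params(nb_dispersion = 0), "dispersion")
  expect_error(generate_reference(sim_params(gene_spacing = 1000)),
               "gene_spacing")
})

test_that("reference construction places the requested annotations", {
  p <- sim_params(genome_length = 1e6, gene_spacing = 5e4,
                  te_spacing = 2e4, seed = 3)
  ref <- generate_reference(p)
  expect_equal(length(unique(ref$genes$gene_id)), 20)  # 1 Mb / 50 kb
  expect_equal(nrow(ref$tes), 50)                      # 1 Mb / 20 kb
  expect_equal(nchar(ref$genome[["chr1"]]), 1e6)
  # deterministic per seed, down to the emitted files
  ref2 <- generate_reference(p)
  expect_identical(ref$genome, ref2$genome)
  expect_identical(ref$genes, ref2$genes)
  d1 <- tempfile(); d2 <- tempfile()
  s <- sim_params(genome_length = 2e5, seed = 8)
  f1 <- write_fixture(plant_variants(generate_reference(s), s), d1)
  f2 <- write_fixture(plant_variants(generate_reference(s), s), d2)
  expect_identical(unname(tools::md5sum(f1$path)),
                   unname(tools::md5sum(f2$path)))
})

test_that("all-zero rates yield identical phases and an empty truth set", {
  p <- sim_params(genome_length = 1e5, snp_rate = 0, indel_rate = 0,
                  sv_rate = 0, seed = 2)
  ref <- generate_reference(p)
  sim <- plant_variants(ref, p)
  expect_identical(sim$p0, ref$genome)
  expect_identical(sim$p1, sim$p0)
  expect_equal(nrow(sim$truth$variants), 0)
})

test_that("realised variant densities match the requested rates", {
  p <- sim_params(genome_length = 2e6, seed = 11)
  sim <- plant_variants(generate_reference(p), p)
  tv <- sim$truth$variants
  for (cls in c("SNP", "INDEL")) {
    rate <- switch(cls, SNP = p$snp_rate, INDEL = p$indel_rate)
    lambda <- 2e6 * rate
    n <- sum(tv$var_class == cls)
    expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  }
  # SVs include the TE insertion events folded into the SV rate
  lam_sv <- 2e6 * p$sv_rate
  expect_lt(abs(sum(tv$var_class == "SV") - lam_sv), 3 * sqrt(lam_sv) + 1)
})

test_that("planted heterozygous LTR-RT insertions carry their 5-nt TSD", {
  lib <- default_te_library(orders = "LTR")
  p <- sim_params(genome_length = 2e5, te_library = lib,
                  n_te_insertions = 4, het_te_fraction = 1,
                  snp_rate = 0, indel_rate = 0, sv_rate = 0, seed = 21)
  sim <- plant_variants(generate_reference(p), p)
  tv <- sim$truth$variants
  expect_equal(nrow(tv), 4)
  expect_true(all(tv$var_class == "SV"))
  # inserted material = element length + TSD length
  expect_true(all(tv$length %in% (lib$length + 5L)))
  # the phase carrying the insertion is longer by exactly that much
  len_diff <- sum(nchar(sim$p0)) - sum(nchar(sim$p1))
  expect_equal(len_diff,
               sum(tv$length[tv$phase == "P0"]) -
                 sum(tv$length[tv$phase == "P1"]))
})

test_that("the truth edit script reproduces phase-1 from phase-0 exactly", {
  s <- small_sim()
  expect_identical(apply_variants(s$sim$p0, s$sim$truth$variants),
                   s$sim$p1)
})

test_that("simulated allele counts are calibrated binomial splits", {
  organs <- "organ1"
  truth <- list(gene_ratios = tidyr::expand_grid(
    gene_id = sprintf("g%03d", 1:100), organ = organs) |>
      dplyr::mutate(ratio = 0.5))
  p <- sim_params(mean_depth = 1000, n_organs = 1, n_replicates = 1,
                  seed = 5)
  cc <- simulate_allele_counts(truth, p)
  frac <- sum(cc$count_p0) / sum(cc$count_p0 + cc$count_p1)
  expect_gt(frac, 0.48); expect_lt(frac, 0.52)

  truth$gene_ratios$ratio <- 1.0
  cc1 <- simulate_allele_counts(truth, p)
  expect_true(all(cc1$count_p1 == 0))

  truth$gene_ratios$ratio <- 0.9
  p3 <- sim_params(mean_depth = 200, n_organs = 1, n_replicates = 3, seed = 6)
  cc9 <- simulate_allele_counts(truth, p3)
  n <- sum(cc9$count_p0 + cc9$count_p1)
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(sum(cc9$count_p0) / n - 0.9), 3 * se)
})

test_that("fixtures round-trip through the package's readers", {
  s <- small_sim()
  d <- tempfile()
  files <- write_fixture(s$sim, d)
  expect_setequal(basename(files$path),
                  c("p0.fa", "p1.fa", "genes.gff3", "tes.gff3",
                    "truth_variants.vcf", "te_zygosity.bed",
                    "allele_counts.tsv"))
  expect_identical(read_genome_fasta(file.path(d, "p0.fa")), s$sim$p0)

  tv <- s$sim$truth$variants
  v2 <- read_variants_vcf(file.path(d, "truth_variants.vcf"))
  expect_equal(v2$pos, tv$pos)
  expect_equal(v2$var_class, tv$var_class)
  expect_equal(v2$ref_allele, tv$ref_allele)
  expect_equal(v2$alt_allele, tv$alt_allele)
  expect_equal(v2$phase, tv$phase)

  gm <- read_gene_models_gff3(file.path(d, "genes.gff3"))
  expect_setequal(unique(gm$gene_id), unique(s$sim$genes$gene_id))
  expect_setequal(variant_key(v2), variant_key(tv))

  bed <- read_te_zygosity_bed(file.path(d, "te_zygosity.bed"))
  expect_equal(sum(bed$zygosity == "heterozygous"),
               sum(s$sim$tes$zygosity == "heterozygous"))

  # GFF3 contract on the raw file: 1-based, end >= start, strand +/-
  raw <- readr::read_tsv(file.path(d, "genes.gff3"), comment = "#",
                         col_names = FALSE, show_col_types = FALSE)
  expect_true(all(raw$X4 >= 1))
  expect_true(all(raw$X5 >= raw$X4))
  expect_true(all(raw$X7 %in% c("+", "-")))
})

test_that("the truth VCF agrees with an independent VCF parser", {
  skip_if_not_installed("vcfR")
  s <- small_sim()
  d <- tempfile()
  write_fixture(s$sim, d)
  vr <- suppressWarnings(
    vcfR::read.vcfR(file.path(d, "truth_variants.vcf"), verbose = FALSE))
  fix <- vcfR::getFIX(vr)
  tv <- s$sim$truth$variants
  expect_equal(nrow(fix), nrow(tv))
  snps <- tv$var_class == "SNP"
  expect_equal(as.integer(fix[snps, "POS"]), tv$pos[snps] + 1L)
  expect_equal(unname(fix[snps, "REF"]), tv$ref_allele[snps])
})
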