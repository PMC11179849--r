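# Informative-SNP selection, allele counting, the beta-binomial ASE test,
# clustering and the association tests.

test_that("informative SNPs are coding and clear of indels by >= 50 bp", {
  genes <- toy_gene(start = 1000L, cds_len = 300L)
  mk_snp <- function(pos, id) snp_variant(pos, "A", "G", id = id)
  snps <- dplyr::bind_rows(mk_snp(1100, "s1"), mk_snp(1200, "s2"),
                           mk_snp(1250, "s3"), mk_snp(50, "nc"))
  # an indel edge 49 bp away excludes a SNP; one exactly 50 bp away keeps it
  indels <- dplyr::bind_rows(
    indel_variant(1149L, alt = "TTT", id = "i1"),   # 1149 - 1100 = 49
    indel_variant(1300L, alt = "TT", id = "i2"))    # 1300 - 1250 = 50
  v <- dplyr::bind_rows(snps, indels)
  info <- select_informative_snps(v, genes)
  expect_setequal(info$pos, c(1200, 1250))
  expect_false(1100 %in% info$pos)

  # without indels, every coding SNP is kept; non-coding never
  info2 <- select_informative_snps(snps, genes)
  expect_setequal(info2$pos, c(1100, 1200, 1250))
  expect_equal(info2$p0_base, rep("A", 3))

  # manual-rule toy: 5 SNPs, 2 indels
  snps5 <- dplyr::bind_rows(lapply(seq(1010, 1290, 70), function(p)
    mk_snp(p, sprintf("m%d", p))))
  ind2 <- dplyr::bind_rows(indel_variant(1035L, ref = "AC", id = "j1"),
                           indel_variant(1260L, alt = "G", id = "j2"))
  keep <- vapply(snps5$pos, function(p)
    min(abs(p - c(1035, 1036, 1260))) >= 50, logical(1))
  info3 <- select_informative_snps(dplyr::bind_rows(snps5, ind2), genes)
  expect_setequal(info3$pos, snps5$pos[keep])
})

test_that("allele counting follows the two phased bases and is additive", {
  info <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
                         gene_id = "g1", p0_base = c("A", "C"),
                         p1_base = c("G", "T"),
                         dist_nearest_indel = Inf, multi_gene = FALSE)
  pile <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 100L, 100L, 200L, 200L),
    base = c("A", "G", "T", "C", "T"),
    count = c(7L, 3L, 2L, 5L, 5L),
    organ = "organ1", replicate = "rep1")
  rec <- count_alleles(pile, info)
  expect_equal(rec$count_p0, 12L)  # 7 + 5; the T at the first site dropped
  expect_equal(rec$count_p1, 8L)   # 3 + 5
  # a covered gene without pileup rows contributes (0, 0)
  info2 <- dplyr::bind_rows(info,
                            dplyr::mutate(info[1, ], pos = 300L,
                                          gene_id = "g2"))
  rec2 <- count_alleles(pile, info2)
  expect_equal(rec2$count_p0[rec2$gene_id == "g2"], 0L)
})

test_that("the beta-binomial test reduces to the exact binomial when rho = 0", {
  # balanced counts: no evidence of ASE
  bal <- counts_tbl("g1", "organ1", c("rep1", "rep2", "rep3"),
                    c(50, 50, 50), c(50, 50, 50))
  r <- tidy(test_ase(bal))
  expect_gt(r$p_value, 0.99)
  expect_false(r$is_ase)

  # (90, 10) x 3 replicates pools to 270 vs 30
  skew <- counts_tbl("g1", "organ1", c("rep1", "rep2", "rep3"),
                     c(90, 90, 90), c(10, 10, 10))
  r2 <- tidy(test_ase(skew))
  expect_lt(r2$p_value, 1e-6)
  # independent oracle: exact binomial minimum-likelihood two-sided sum
  probs <- dbinom(0:300, 300, 0.5)
  oracle <- sum(probs[probs <= dbinom(270, 300, 0.5) * (1 + 1e-7)])
  expect_equal(r2$p_value, oracle, tolerance = 1e-10)
})

test_that("replicate overdispersion inflates rho and tempers p-values", {
  set.seed(5)
  genes <- sprintf("g%03d", 1:200)
  over <- dplyr::bind_rows(lapply(genes, function(g) {
    pr <- rbeta(3, 10, 10)  # replicate-level wobble around 0.5
    counts_tbl(g, "organ1", c("rep1", "rep2", "rep3"),
               rbinom(3, 100, pr), 100 - rbinom(3, 100, pr))
  }))
  fit <- test_ase(over)
  expect_gt(fit$rho$rho, 0)
  clean <- dplyr::bind_rows(lapply(genes, function(g)
    counts_tbl(g, "organ1", c("rep1", "rep2", "rep3"),
               rbinom(3, 100, 0.5), rbinom(3, 100, 0.5))))
  expect_lt(test_ase(clean)$rho$rho, fit$rho$rho)
})

test_that("BH q-values are monotone and is_ase nests across FDR cuts", {
  set.seed(7)
  rec <- dplyr::bind_rows(lapply(sprintf("g%02d", 1:40), function(g) {
    pr <- sample(c(0.5, 0.75), 1)
    counts_tbl(g, "organ1", "rep1", rbinom(1, 120, pr),
               120 - rbinom(1, 120, pr))
  }))
  r <- tidy(test_ase(rec))
  o <- order(r$p_value)
  expect_true(all(diff(r$q_value[o]) >= -1e-12))
  expect_true(all(r$q_value >= r$p_value - 1e-12))
  strict <- tidy(test_ase(rec, fdr = 0.01))
  expect_true(all(strict$gene_id[strict$is_ase] %in% r$gene_id[r$is_ase]))
})

test_that("ASE percentage is truncated, not rounded", {
  expect_equal(ase_fraction(579, 6182), 9.3)
  expect_equal(ase_fraction(0, 100), 0)
  expect_equal(ase_fraction(1, 3), 33.3)
  expect_error(ase_fraction(5, 0), "n_expressed")
  expect_error(ase_fraction(5, 4), "exceed")
})

test_that("profile clustering separates planted allele-biased groups", {
  organs <- sprintf("organ%d", 1:3)
  mk <- function(gene, ratio) dplyr::bind_rows(lapply(organs, function(o)
    counts_tbl(gene, o, c("rep1", "rep2", "rep3"),
               round(100 * ratio), round(100 * (1 - ratio)))))
  rec <- dplyr::bind_rows(
    lapply(sprintf("p0only%02d", 1:10), mk, ratio = 0.95),
    lapply(sprintf("p1only%02d", 1:10), mk, ratio = 0.05))
  fit <- test_ase(rec)
  cl <- cluster_ase_profiles(fit, rec, min_reads = 10, k = 2)
  ass <- cl$assignments
  grp <- substr(ass$gene_id, 1, 2)
  expect_equal(length(unique(ass$cluster[grp == "p0"])), 1)
  expect_equal(length(unique(ass$cluster[grp == "p1"])), 1)
  expect_false(ass$cluster[grp == "p0"][1] == ass$cluster[grp == "p1"][1])

  # the read filter applies to every replicate's total
  rec_low <- dplyr::bind_rows(rec,
                              counts_tbl("shallow", organs[1],
                                         c("rep1", "rep2", "rep3"),
                                         c(5, 200, 200), c(3, 0, 0)))
  fit2 <- test_ase(rec_low)
  cl2 <- cluster_ase_profiles(fit2, rec_low, min_reads = 10, k = 2)
  expect_false("shallow" %in% cl2$assignments$gene_id)
  # (5, 200) passes the total filter; a replicate totalling 8 fails
  expect_error(cluster_ase_profiles(fit, rec, k = 50), "eligible")
})

test_that("SV enrichment reproduces the Fisher table arithmetic", {
  null_tab <- tibble::tibble(
    gene_id = sprintf("g%d", 1:20),
    is_ase = rep(c(TRUE, FALSE), each = 10),
    sv_near = rep(c(TRUE, FALSE, TRUE, FALSE), each = 5))
  e0 <- sv_ase_enrichment(null_tab)
  expect_equal(e0$p_value, 1)

  # counts reconstructed from the published percentages (579/5603 genes)
  status <- tibble::tibble(
    gene_id = sprintf("g%05d", 1:6182),
    is_ase = rep(c(TRUE, FALSE), c(579, 5603)),
    sv_near = c(rep(c(TRUE, FALSE), c(199, 380)),
                rep(c(TRUE, FALSE), c(1569, 4034))))
  e <- sv_ase_enrichment(status)
  expect_equal(round(e$pct_ase_with_sv, 1), 34.4)
  expect_equal(round(e$pct_non_ase_with_sv, 1), 28.0)
  expect_lt(e$p_value, 0.05)
  # dual route: central hypergeometric tail sum
  m <- 199 + 1569; n_ <- 380 + 4034; k <- 579
  dens <- dhyper(0:k, m, n_, k)
  oracle <- sum(dens[dens <= dhyper(199, m, n_, k) * (1 + 1e-7)])
  expect_equal(e$p_value, oracle, tolerance = 1e-8)

  # extreme 10/0 vs 0/10 table
  xt <- tibble::tibble(gene_id = sprintf("g%d", 1:20),
                       is_ase = rep(c(TRUE, FALSE), each = 10),
                       sv_near = rep(c(TRUE, FALSE), each = 10))
  ex <- sv_ase_enrichment(xt)
  expect_equal(ex$p_value, 2 / choose(20, 10) * choose(10, 10) * choose(10, 0),
               tolerance = 1e-6)
  expect_lt(abs(ex$p_value - 1.082e-5), 2e-7)
})

test_that("flag_sv_near uses the 1-kb gene neighbourhood", {
  genes <- dplyr::bind_rows(toy_gene(start = 5000L, gene_id = "near"),
                            toy_gene(start = 20000L, gene_id = "far"))
  svs <- tibble::tibble(chrom = "chr1", pos = 4500L, length = 100L,
                        svtype = "DEL")
  fl <- flag_sv_near(genes, svs)
  expect_true(fl$sv_near[fl$gene_id == "near"])
  expect_false(fl$sv_near[fl$gene_id == "far"])
})

test_that("TE-expression association is rank-based with group guards", {
  expr_same <- tibble::tibble(gene_id = sprintf("g%d", 1:30),
                              log_expr = rep(c(1, 2, 3), 10))
  grp_same <- tibble::tibble(gene_id = sprintf("g%d", 1:30),
                             group = rep(c("none", "homozygous",
                                           "heterozygous"), each = 10))
  # identical distributions in all groups
  expr_same$log_expr <- rep(c(1, 2, 3, 4, 5), 6)
  grp_same$group <- rep(c("none", "homozygous", "heterozygous"), 10)
  t0 <- te_expression_association(expr_same, grp_same)
  expect_true(all(t0$tests$p_value > 0.9))

  set.seed(44)
  n <- 200
  mk <- function(g, shift) tibble::tibble(
    gene_id = sprintf("%s%03d", g, 1:n), group = NA,
    log_expr = rnorm(n, 5 + shift, 1))
  expr <- dplyr::bind_rows(mk("n", 0), mk("h", -1), mk("e", 0.5))
  grp <- tibble::tibble(gene_id = expr$gene_id,
                        group = rep(c("none", "homozygous", "heterozygous"),
                                    each = n))
  tt <- te_expression_association(expr[, c("gene_id", "log_expr")], grp)
  med <- setNames(tt$medians$median_expr, tt$medians$group)
  expect_lt(med[["homozygous"]], med[["none"]])
  expect_lt(med[["none"]], med[["heterozygous"]])
  expect_true(all(tt$tests$p_value < 0.05))

  # a two-gene group is unavailable
  small <- te_expression_association(
    expr[c(1:10, 201:202), c("gene_id", "log_expr")],
    grp[c(1:10, 201:202), ])
  expect_true(is.na(small$tests$p_value[1]))
})

test_that("gene grouping by upstream TE prefers heterozygous labels", {
  genes <- toy_gene(start = 5000L)
  tes <- tibble::tibble(chrom = "chr1", start = c(4300L, 4500L),
                        end = c(4450L, 4800L),
                        label = c("homozygous", "heterozygous"))
  g <- assign_te_upstream_group(genes, tes)
  expect_equal(g$group, "heterozygous")
  g2 <- assign_te_upstream_group(genes, tes[1, ])
  expect_equal(g2$group, "homozygous")
  g3 <- assign_te_upstream_group(genes, tes[0, ])
  expect_equal(g3$group, "none")
})
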