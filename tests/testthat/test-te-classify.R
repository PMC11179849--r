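# Reciprocal-overlap zygosity, TSD detection, LTR dating, distances and
# window densities.


test_that("reciprocal-overlap thresholds follow the published rule", {
  aligned <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L)
  te <- tibble::tibble(te_id = "t1", chrom = "chr1", start = 0L, end = 1000L)
  # exact coincidence
  d <- tibble::tibble(deletion_id = "d1", chrom = "chr1",
                      start = 0L, end = 1000L)
  z <- classify_te_zygosity(te, d, aligned)
  expect_equal(z$label, "heterozygous")
  expect_equal(z$frac_of_deletion, 1)
  expect_equal(z$frac_of_te, 1)
  # 1000-bp TE, 1200-bp deletion, 900-bp overlap: 0.75 > 0.5, 0.90 >= 0.8
  d2 <- tibble::tibble(deletion_id = "d2", chrom = "chr1",
                       start = 100L, end = 1300L)
  expect_equal(classify_te_zygosity(te, d2, aligned)$label, "heterozygous")
  # 799-bp overlap of a 1000/1000 pair: 0.799 < 0.8 -> partial
  d3 <- tibble::tibble(deletion_id = "d3", chrom = "chr1",
                       start = 201L, end = 1201L)
  z3 <- classify_te_zygosity(te, d3, aligned)
  expect_equal(z3$label, "partial")
  expect_equal(z3$overlap_bp, 799L)
  # no deletion, full alignment coverage -> homozygous
  z4 <- classify_te_zygosity(te, d3[0, ], aligned)
  expect_equal(z4$label, "homozygous")
  # no deletion, clipped coverage -> unresolved
  z5 <- classify_te_zygosity(te, d3[0, ],
                             tibble::tibble(chrom = "chr1", start = 10L,
                                            end = 10000L))
  expect_equal(z5$label, "unresolved")
  expect_error(
    classify_te_zygosity(dplyr::mutate(te, end = -5L), d, aligned),
    "negative")
})

test_that("classification matches a per-base oracle on random configurations", {
  set.seed(77)
  aligned <- tibble::tibble(chrom = "chr1",
                            start = c(0L, 6000L), end = c(5000L, 10000L))
  for (rep in 1:200) {
    te <- tibble::tibble(te_id = "t", chrom = "chr1",
                         start = sample(0:8000, 1))
    te$end <- te$start + sample(200:2000, 1)
    nd <- sample(0:3, 1)
    dels <- tibble::tibble(
      deletion_id = sprintf("d%d", seq_len(nd)), chrom = "chr1",
      start = sample(0:8000, nd, replace = TRUE))
    dels$end <- dels$start + sample(100:2500, nd, replace = TRUE)
    got <- classify_te_zygosity(te, dels, aligned)$label
    expect_equal(got, oracle_zygosity(te, dels, aligned),
                 info = sprintf("rep %d", rep))
  }
})

test_that("zygosity truth is recovered on the simulated fixture", {
  s <- small_sim()
  v <- small_calls()
  dels <- dplyr::filter(v, .data$var_class == "SV", .data$svtype == "DEL")
  dels <- dplyr::transmute(dels, deletion_id = variant_id, chrom,
                           start = pos, end = pos + length)
  z <- classify_te_zygosity(s$sim$tes, dels,
                            aligned_regions(small_alignment()))
  expect_equal(z$label, s$sim$tes$zygosity)
})

test_that("TSD detection finds engineered duplications and rejects noise", {
  set.seed(31)
  g <- random_genome(3000, seed = 31)
  # engineered: inserted sequence ends with the 5 bases left of the cut
  p <- 1500L
  site <- substr(g[[1]], p - 4, p)
  te <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  v <- indel_variant(p, alt = paste0(te, site), id = "eng")
  r <- detect_tsd(v, g)
  expect_true(r$found)
  expect_gte(r$tsd_length, 5L)
  expect_equal(substr(r$tsd_sequence, nchar(r$tsd_sequence) - 4,
                      nchar(r$tsd_sequence)), site)

  # a random insertion has no engineered duplication
  set.seed(32)
  v2 <- indel_variant(800L, alt = paste(sample(c("A", "C", "G", "T"), 60,
                                               TRUE), collapse = ""),
                      id = "rand")
  r2 <- detect_tsd(v2, g)
  # chance 2-mers can occur; an engineered-length match cannot
  expect_lt(r2$tsd_length, 5L)

  # breakpoint at the contig edge is flagged, not crashed
  v3 <- indel_variant(3L, alt = paste0(te, site), id = "edge")
  expect_warning(r3 <- detect_tsd(v3, g), "contig edge")
  expect_true(is.na(r3$found))
})

test_that("TSD survives left-normalisation of the call", {
  g <- random_genome(3000, seed = 33)
  p <- 1200L
  site <- substr(g[[1]], p - 4, p)
  set.seed(34)
  te <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  v <- indel_variant(p, alt = paste0(te, site))
  vn <- diploscan:::normalize_variants(v, g)
  expect_lt(vn$pos, p)  # the left shift that motivates right-realignment
  r <- detect_tsd(vn, g)
  expect_true(r$found)
  expect_gte(r$tsd_length, 5L)
})

test_that("Jukes-Cantor LTR dating matches the closed form", {
  # identical sequences: zero divergence and age
  same <- paste(rep("ACGT", 75), collapse = "")
  r0 <- ltr_insertion_age(same, same)
  expect_equal(r0$divergence, 0)
  expect_equal(r0$age, 0)

  # 100 bp with 2 mismatches: p = 0.02, d = -(3/4)ln(1 - 4p/3)
  a <- paste(rep("A", 100), collapse = "")
  b <- paste0(paste(rep("A", 98), collapse = ""), "CC")
  r <- ltr_insertion_age(a, b, mu = 1.3e-8)
  expect_equal(r$p_mismatch, 0.02)
  expect_equal(r$divergence, -0.75 * log(1 - 4 * 0.02 / 3), tolerance = 1e-12)
  expect_equal(r$age, 7.797e5, tolerance = 1e-3)

  # saturation boundary
  half <- paste(rep("A", 100), collapse = "")
  sat <- paste0(paste(rep("C", 75), collapse = ""),
                paste(rep("A", 25), collapse = ""))
  expect_error(ltr_insertion_age(half, sat), "saturated")

  # monotonic in mismatch count
  ds <- vapply(c(1, 5, 10, 20), function(m) {
    bb <- paste0(paste(rep("C", m), collapse = ""),
                 paste(rep("A", 100 - m), collapse = ""))
    ltr_insertion_age(a, bb)$divergence
  }, numeric(1))
  expect_true(all(diff(ds) > 0))

  # K2P on a transition-only pair exceeds the JC estimate slightly
  g <- paste0("G", substr(a, 2, 100))
  expect_gt(ltr_insertion_age(a, g, model = "K2P")$divergence, 0)
})

test_that("forward-simulated LTR pairs are dated with bounded error", {
  set.seed(55)
  mu <- 1.3e-8
  lib <- default_te_library(orders = "LTR")
  for (age in c(1e6, 5e6)) {
    ests <- replicate(40, {
      ltr <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
      l5 <- diploscan:::mutate_jc(ltr, mu * age)
      l3 <- diploscan:::mutate_jc(ltr, mu * age)
      ltr_insertion_age(l5, l3, mu = mu)$age
    })
    expect_lt(abs(mean(ests) - age) / age, 0.2)
  }
})

test_that("age comparison reports group statistics and exact rank-sum p", {
  same <- c(1, 2, 3, 4, 5)
  cmp0 <- compare_age_by_zygosity(same, same)
  expect_equal(cmp0$p_value, 1)

  cmp <- compare_age_by_zygosity(c(1, 2, 3), c(10, 11, 12))
  expect_equal(cmp$p_value, 0.1)  # 2 / choose(6, 3)
  g <- glance(cmp)
  expect_equal(g$mean_het, 2)
  expect_equal(g$mean_hom, 11)

  # seeded separated distributions
  set.seed(66)
  het <- runif(100, 0, 5); hom <- runif(100, 2, 12)
  cmp2 <- compare_age_by_zygosity(het, hom)
  expect_lt(cmp2$groups$mean_age[1], cmp2$groups$mean_age[2])
  expect_lt(cmp2$p_value, 0.05)

  expect_true(is.na(compare_age_by_zygosity(c(1, 2), c(3, 4, 5))$p_value))
  expect_error(compare_age_by_zygosity(numeric(0), 1), "non-empty")
})

test_that("TE-gene distances equal the exhaustive pairwise minimum", {
  genes <- dplyr::bind_rows(toy_gene(start = 8000L, gene_id = "gA"),
                            toy_gene(start = 20000L, gene_id = "gB"))
  tes <- tibble::tibble(
    te_id = sprintf("t%d", 1:5), chrom = "chr1",
    start = c(5000L, 8010L, 12000L, 19000L, 30000L),
    end = c(6000L, 8020L, 12500L, 19500L, 30400L))
  d <- te_gene_distance(tes, genes)
  expect_equal(d$distance_to_gene[2], 0L)        # overlaps gA
  expect_equal(d$distance_to_gene[1], 2000L)     # 5000-6000 vs 8000-
  gs <- genes[genes$feature == "gene", ]
  brute <- vapply(seq_len(nrow(tes)), function(i) {
    min(vapply(seq_len(nrow(gs)), function(j) {
      if (tes$start[i] < gs$end[j] && tes$end[i] > gs$start[j]) return(0L)
      as.integer(max(gs$start[j] - tes$end[i], tes$start[i] - gs$end[j]))
    }, integer(1)))
  }, integer(1))
  expect_equal(d$distance_to_gene, brute)
  med <- median_distance_by_zygosity(
    dplyr::mutate(d, label = c("het", "het", "hom", "hom", "hom")))
  expect_equal(med$n, c(2L, 3L))
})

test_that("window densities are coverage fractions with merged overlaps", {
  lens <- c(chr1 = 300000L)
  f1 <- tibble::tibble(chrom = "chr1", start = 20000L, end = 30000L)
  d1 <- window_density(f1, lens, window_bp = 1e5)
  expect_equal(d1$density, c(0.1, 0, 0))

  f2 <- tibble::tibble(chrom = "chr1", start = c(0L, 25000L),
                       end = c(50000L, 75000L))
  d2 <- window_density(f2, lens, window_bp = 1e5)
  expect_equal(d2$density[1], 0.75)

  # per-base counting oracle on a random feature set
  set.seed(88)
  f3 <- tibble::tibble(chrom = "chr1", start = sample(0:290000, 40))
  f3$end <- pmin(f3$start + sample(1000:20000, 40, replace = TRUE), 300000L)
  d3 <- window_density(f3, lens, window_bp = 1e5)
  covered <- logical(300000)
  for (i in seq_len(nrow(f3)))
    covered[(f3$start[i] + 1):f3$end[i]] <- TRUE
  oracle <- vapply(seq_len(nrow(d3)), function(i)
    mean(covered[(d3$start[i] + 1):d3$end[i]]), numeric(1))
  expect_equal(d3$density, oracle)
})
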