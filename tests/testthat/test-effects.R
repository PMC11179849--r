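# Coding-impact classification against a printed 30-bp toy CDS.
# CDS (plus strand, [100, 130)): ATG GCG TGG AAA CCC GGG TTT ACG GAT TAA

test_that("CDS SNPs are classified by codon comparison", {
  g <- toy_cds_genome("+")
  genes <- toy_gene()
  # GCG -> GCA: third codon position of codon 2 (genomic 105), Ala -> Ala
  syn <- classify_effects(snp_variant(105, "G", "A"), genes, g)
  expect_equal(syn$effect, "synonymous_variant")
  expect_equal(syn$impact, "LOW")
  # TGG -> TGA (genomic 108): Trp -> stop
  stopg <- classify_effects(snp_variant(108, "G", "A"), genes, g)
  expect_equal(stopg$effect, "stop_gained")
  expect_equal(stopg$impact, "HIGH")
  # TGG -> CGG (genomic 106): Trp -> Arg
  mis <- classify_effects(snp_variant(106, "T", "C"), genes, g)
  expect_equal(mis$effect, "missense_variant")
  expect_equal(mis$impact, "MODERATE")
  # final TAA -> CAA: stop lost
  sl <- classify_effects(snp_variant(127, "T", "C"), genes, g)
  expect_equal(sl$effect, "stop_lost")
  expect_equal(sl$impact, "HIGH")
})

test_that("synonymous and missense calls honour translation invariants", {
  g <- toy_cds_genome("+")
  genes <- toy_gene()
  cds0 <- substr(g[[1]], 101, 130)
  translate <- function(s) paste(
    vapply(seq(1, nchar(s) - 2, 3),
           function(i) Biostrings::GENETIC_CODE[[substr(s, i, i + 2)]],
           character(1)), collapse = "")
  for (case in list(list(pos = 105, alt = "A", effect = "synonymous_variant"),
                    list(pos = 106, alt = "C", effect = "missense_variant"),
                    list(pos = 108, alt = "A", effect = "stop_gained"))) {
    v <- snp_variant(case$pos, substr(g[[1]], case$pos + 1, case$pos + 1),
                     case$alt)
    call <- classify_effects(v, genes, g)
    expect_equal(call$effect, case$effect)
    alt_cds <- cds0
    substr(alt_cds, case$pos - 99, case$pos - 99) <- case$alt
    p_ref <- translate(cds0); p_alt <- translate(alt_cds)
    if (case$effect == "synonymous_variant") expect_equal(p_alt, p_ref)
    if (case$effect == "missense_variant")
      expect_equal(sum(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]]), 1)
    if (case$effect == "stop_gained")
      expect_lt(regexpr("\\*", p_alt), regexpr("\\*", p_ref))
  }
})

test_that("minus-strand genes translate through the reverse complement", {
  g <- toy_cds_genome("-")
  genes <- toy_gene(strand = "-")
  # CDS base 105 on the genome corresponds to a third-position Ala site on
  # the minus strand: genomic coordinate 130 - (105 - 100) - 1 = 124,
  # genomic base is the complement of G, i.e. C; mutate to complement of A
  pos <- 124L
  ref_b <- substr(g[[1]], pos + 1, pos + 1)
  syn <- classify_effects(snp_variant(pos, ref_b, "T"), genes, g)
  expect_equal(syn$effect, "synonymous_variant")
})

test_that("CDS indels split into frameshift and inframe by length mod 3", {
  g <- toy_cds_genome("+")
  genes <- toy_gene()
  del4 <- classify_effects(
    indel_variant(110L, ref = substr(g[[1]], 111, 114)), genes, g)
  expect_equal(del4$effect, "frameshift_variant")
  expect_equal(del4$impact, "HIGH")
  del3 <- classify_effects(
    indel_variant(110L, ref = substr(g[[1]], 111, 113)), genes, g)
  expect_equal(del3$effect, "inframe_deletion")
  expect_equal(del3$impact, "MODERATE")
  ins2 <- classify_effects(indel_variant(110L, alt = "AC"), genes, g)
  expect_equal(ins2$effect, "frameshift_variant")
  ins3 <- classify_effects(indel_variant(110L, alt = "ACG"), genes, g)
  expect_equal(ins3$effect, "inframe_insertion")
  # exhaustive: frameshift xor inframe decided solely by length mod 3
  for (len in 1:9) {
    set.seed(len)
    v <- indel_variant(112L, alt = paste(sample(c("A", "C", "G", "T"), len,
                                                TRUE), collapse = ""))
    eff <- classify_effects(v, genes, g)$effect
    expect_equal(eff, ifelse(len %% 3 == 0, "inframe_insertion",
                             "frameshift_variant"))
  }
})

test_that("regulatory and intergenic regions map to MODIFIER terms", {
  g <- toy_cds_genome("+")
  genes <- toy_gene()
  up <- classify_effects(snp_variant(50, "A", "C"), genes, g)
  expect_equal(up$effect, "upstream_variant")
  down <- classify_effects(snp_variant(200, "A", "C"), genes, g)
  expect_equal(down$effect, "downstream_variant")
  # beyond the 1-kb window there is no gene pairing at all
  g2 <- c(chr1 = paste0(g[[1]], paste(rep("A", 2000), collapse = "")))
  far <- classify_effects(snp_variant(2000, "A", "C"), genes, g2)
  expect_equal(far$effect, "intergenic_variant")
  expect_true(is.na(far$gene_id))
  expect_equal(unique(c(up$impact, down$impact, far$impact)), "MODIFIER")
})

test_that("whole-gene deletions are PAV genes with HIGH impact", {
  genes <- dplyr::bind_rows(
    toy_gene(start = 100L, gene_id = "inside"),
    toy_gene(start = 2000L, gene_id = "straddle"),
    toy_gene(start = 5000L, gene_id = "outside"))
  dels <- tibble::tibble(deletion_id = c("d1", "d2"), chrom = "chr1",
                         start = c(0L, 1990L), end = c(1000L, 2010L))
  pav <- find_pav_genes(genes, dels)
  expect_equal(pav$gene_id, "inside")
  # partial overlap is excluded
  expect_false("straddle" %in% pav$gene_id)

  # brute-force containment on random instances
  set.seed(12)
  for (i in 1:50) {
    gs <- toy_gene(start = sample(0:5000, 1), gene_id = "g")
    d <- tibble::tibble(deletion_id = "d", chrom = "chr1",
                        start = sample(0:5000, 1))
    d$end <- d$start + sample(10:2000, 1)
    span <- range(gs$start, gs$end)
    expected <- d$start <= span[1] && d$end >= span[2]
    expect_equal(nrow(find_pav_genes(gs, d)) == 1, expected)
  }

  # classify_effects reports the contained gene as deleted
  g <- toy_cds_genome("+")
  sv <- tibble::tibble(variant_id = "sv1", chrom = "chr1", pos = 50L,
                       var_class = "SV", svtype = "DEL", length = 150L,
                       ref_allele = substr(g[[1]], 51, 200),
                       alt_allele = "", phase = "P0")
  calls <- classify_effects(sv, toy_gene(), g)
  expect_equal(calls$effect, "gene_deleted")
  expect_equal(calls$impact, "HIGH")
})

test_that("impact summaries give within-class percentages", {
  calls <- tibble::tibble(
    variant_id = sprintf("v%03d", 1:120),
    var_class = rep(c("SNP", "INDEL"), c(100, 20)),
    gene_id = c(rep("g1", 60), rep(NA, 60)),
    region = "CDS",
    effect = "missense_variant",
    impact = c(rep("HIGH", 1), rep("LOW", 99), rep("HIGH", 5),
               rep("MODIFIER", 15)))
  s <- impact_summary(calls)
  tb <- s$by_class
  expect_equal(tb$pct[tb$var_class == "SNP" & tb$impact == "HIGH"], 1.00)
  expect_equal(tb$pct[tb$var_class == "INDEL" & tb$impact == "HIGH"], 25.00)
  expect_equal(s$n_genes_high, 1L)
  expect_false("SV" %in% tb$var_class)  # empty class omitted, no 0-division
  expect_error(impact_summary(calls[0, ]), "no effect calls")
})
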