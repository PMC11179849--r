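# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env()

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a modest diploid simulation exercised by several test files
small_sim <- function() {
  cached("small_sim", {
    p <- sim_params(genome_length = 3e5, n_chromosomes = 1, seed = 42)
    list(params = p, sim = plant_variants(generate_reference(p), p))
  })
}

small_alignment <- function() {
  cached("small_alignment", {
    s <- small_sim()
    anchor_align(s$sim$p0, s$sim$p1)
  })
}

small_calls <- function() {
  cached("small_calls", {
    s <- small_sim()
    extract_variants(small_alignment(), s$sim$p0, s$sim$p1)
  })
}

variant_key <- function(v) {
  paste(v$chrom, v$pos, v$var_class, v$ref_allele, v$alt_allele)
}

random_genome <- function(len, seed, name = "chr1") {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, TRUE),
                        collapse = ""), name)
}

# hand-built single-gene model: three 9/12/9-bp coding exons would be too
# small for codon tests, so use one 30-bp CDS exon unless asked otherwise
toy_gene <- function(chrom = "chr1", start = 100L, strand = "+",
                     cds_len = 30L, gene_id = "g1") {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    feature = c("gene", "exon", "CDS"),
    start = start, end = start + cds_len,
    frame = c(NA_integer_, NA_integer_, 0L))
}

# a genome carrying the printed toy CDS at [100, 130) of chr1
# CDS: ATG GCG TGG AAA CCC GGG TTT ACG TAA (9 codons, 27 bp) padded
toy_cds_seq <- "ATGGCGTGGAAACCCGGGTTTACGGATTAA"  # 30 bp, ends with stop TAA

toy_cds_genome <- function(strand = "+") {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  cds <- if (strand == "+") toy_cds_seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toy_cds_seq)))
  substr(s, 101, 130) <- cds
  c(chr1 = s)
}

snp_variant <- function(pos, ref, alt, chrom = "chr1", id = "v1") {
  tibble::tibble(variant_id = id, chrom = chrom, pos = as.integer(pos),
                 var_class = "SNP", svtype = "none", length = 1L,
                 ref_allele = ref, alt_allele = alt, phase = "both")
}

indel_variant <- function(pos, ref = "", alt = "", chrom = "chr1",
                          id = "v1") {
  len <- max(nchar(ref), nchar(alt))
  tibble::tibble(variant_id = id, chrom = chrom, pos = as.integer(pos),
                 var_class = ifelse(len >= 40, "SV", "INDEL"),
                 svtype = ifelse(nchar(alt) > nchar(ref), "INS", "DEL"),
                 length = as.integer(len),
                 ref_allele = ref, alt_allele = alt,
                 phase = ifelse(nchar(alt) > nchar(ref), "P1", "P0"))
}

counts_tbl <- function(gene_id, organ, replicate, p0, p1) {
  tibble::tibble(gene_id = gene_id, organ = organ, replicate = replicate,
                 count_p0 = as.integer(p0), count_p1 = as.integer(p1))
}
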