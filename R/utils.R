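# Internal sequence and coordinate helpers. Genomes are named character
# vectors (one element per chromosome); coordinates are 0-based half-open.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# substring in 0-based half-open coordinates
seq_sub <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1, end)
}

seq_char <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Evaluate code under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Forward Jukes-Cantor simulation: each site substituted with probability
# 3/4 * (1 - exp(-4/3 d)), d = expected substitutions/site on this lineage.
mutate_jc <- function(seq, d) {
  if (d <= 0) return(seq)
  ch <- seq_char(seq)
  q <- 0.75 * (1 - exp(-4 / 3 * d))
  hit <- which(stats::runif(length(ch)) < q & ch %in% BASES)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

# per-position mismatch logical of two equal-length strings
mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_chrom_match <- function(genome, chroms) {
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stopf("chromosome(s) not in genome: %s", paste(missing, collapse = ", "))
}

translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}
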