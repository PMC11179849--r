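#' Date an LTR retrotransposon insertion from its two LTRs
#'
#' The two long terminal repeats of an LTR retrotransposon are identical
#' at insertion and diverge afterwards, so their distance clocks the
#' insertion. Sequences of unequal length are globally aligned first and
#' gapped columns excluded; the raw mismatch proportion p over the
#' remaining sites is corrected with the Jukes-Cantor model,
#' d = -3/4 ln(1 - 4p/3) (optionally Kimura two-parameter), and the age is
#' d / (2 mu): each LTR accumulates substitutions independently.
#'
#' @param ltr5_seq,ltr3_seq character vectors of LTR sequences (recycled
#'   pairwise).
#' @param mu substitution rate, substitutions/site/year.
#' @param model `"JC"` (default) or `"K2P"`.
#' @return tibble: `n_sites`, `p_mismatch`, `divergence`, `age`, `mu`.
#' @export
#' @examples
#' ltr_insertion_age("ACGTACGTAC", "ACGTACGTAC", mu = 1.3e-8)
ltr_insertion_age <- function(ltr5_seq, ltr3_seq, mu = 1.3e-8,
                              model = c("JC", "K2P")) {
  model <- match.arg(model)
  if (mu <= 0) stopf("mu must be > 0")
  n <- max(length(ltr5_seq), length(ltr3_seq))
  ltr5_seq <- rep_len(ltr5_seq, n); ltr3_seq <- rep_len(ltr3_seq, n)
  rows <- lapply(seq_len(n), function(i) {
    a <- ltr5_seq[i]; b <- ltr3_seq[i]
    if (!nzchar(a) || !nzchar(b)) stopf("empty LTR sequence")
    if (nchar(a) != nchar(b)) {
      pa <- Biostrings::pairwiseAlignment(
        pattern = b, subject = a, type = "global",
        substitutionMatrix = nuc_mat(), gapOpening = 6, gapExtension = 1)
      a <- as.character(Biostrings::alignedSubject(pa))
      b <- as.character(Biostrings::alignedPattern(pa))
    }
    av <- seq_char(a); bv <- seq_char(b)
    keep <- av != "-" & bv != "-"
    if (!any(keep)) stopf("empty LTR alignment")
    av <- av[keep]; bv <- bv[keep]
    p <- mean(av != bv)
    if (model == "JC") {
      if (p >= 0.75)
        stopf("LTR divergence saturated (mismatch proportion %.3f >= 0.75)", p)
      d <- -0.75 * log(1 - 4 * p / 3)
    } else {
      ts_set <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
      diff <- av != bv
      pair <- paste0(av[diff], bv[diff])
      P <- sum(!is.na(ts_set[pair])) / length(av)   # transitions
      Q <- (sum(diff) / length(av)) - P             # transversions
      if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
        stopf("LTR divergence saturated under K2P")
      d <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    }
    tibble::tibble(n_sites = length(av), p_mismatch = p, divergence = d,
                   age = d / (2 * mu), mu = mu)
  })
  dplyr::bind_rows(rows)
}

#' Date every intact LTR retrotransposon in a TE annotation table
#'
#' Extracts both LTR intervals from the genome and applies
#' [ltr_insertion_age()]; elements whose divergence is saturated or that
#' lack LTR coordinates get `NA` ages.
#'
#' @param tes TE annotation tibble with `ltr5_*`/`ltr3_*` columns.
#' @param genome phase-0 genome.
#' @param mu substitution rate.
#' @param model divergence model, see [ltr_insertion_age()].
#' @return `tes` with added `divergence` and `age_estimate` columns.
#' @export
ltr_age_table <- function(tes, genome, mu = 1.3e-8, model = "JC") {
  div <- rep(NA_real_, nrow(tes)); age_est <- rep(NA_real_, nrow(tes))
  for (i in seq_len(nrow(tes))) {
    if (is.na(tes$ltr5_start[i]) || is.na(tes$ltr3_start[i])) next
    l5 <- seq_sub(genome, tes$chrom[i], tes$ltr5_start[i], tes$ltr5_end[i])
    l3 <- seq_sub(genome, tes$chrom[i], tes$ltr3_start[i], tes$ltr3_end[i])
    est <- tryCatch(ltr_insertion_age(l5, l3, mu = mu, model = model),
                    error = function(e) NULL)
    if (!is.null(est)) { div[i] <- est$divergence; age_est[i] <- est$age }
  }
  tes$divergence <- div
  tes$age_estimate <- age_est
  tes
}

#' Compare LTR insertion ages between zygosity groups
#'
#' Two-sided Wilcoxon rank-sum test of heterozygous versus homozygous
#' insertion ages, with group means and medians. The p-value is reported
#' as `NA` when either group has fewer than 3 ages.
#'
#' @param ages_het,ages_hom numeric vectors of ages (years).
#' @return object of class `age_comparison`; see [tidy.age_comparison()].
#' @export
compare_age_by_zygosity <- function(ages_het, ages_hom) {
  ages_het <- ages_het[!is.na(ages_het)]
  ages_hom <- ages_hom[!is.na(ages_hom)]
  if (!length(ages_het) || !length(ages_hom))
    stopf("both groups must be non-empty")
  p <- NA_real_
  if (length(ages_het) >= 3 && length(ages_hom) >= 3) {
    p <- suppressWarnings(
      stats::wilcox.test(ages_het, ages_hom, alternative = "two.sided")$p.value)
  }
  structure(list(
    groups = tibble::tibble(
      label = c("heterozygous", "homozygous"),
      n = c(length(ages_het), length(ages_hom)),
      mean_age = c(mean(ages_het), mean(ages_hom)),
      median_age = c(stats::median(ages_het), stats::median(ages_hom))),
    p_value = p,
    ages = list(heterozygous = ages_het, homozygous = ages_hom)),
    class = "age_comparison")
}

#' @export
print.age_comparison <- function(x, ...) {
  cat("LTR insertion-age comparison (Wilcoxon rank-sum)\n")
  print(x$groups)
  cat(sprintf("two-sided p-value: %s\n",
              ifelse(is.na(x$p_value), "unavailable (group n < 3)",
                     format(x$p_value, digits = 4))))
  invisible(x)
}

#' Tidiers for age comparisons
#'
#' @param x an `age_comparison` object.
#' @param ... unused.
#' @return `tidy()`: per-group summary tibble; `glance()`: one-row tibble
#'   with the test outcome.
#' @method tidy age_comparison
#' @export
tidy.age_comparison <- function(x, ...) x$groups

#' @rdname tidy.age_comparison
#' @method glance age_comparison
#' @export
glance.age_comparison <- function(x, ...) {
  tibble::tibble(mean_het = x$groups$mean_age[1],
                 mean_hom = x$groups$mean_age[2],
                 p_value = x$p_value,
                 n_het = x$groups$n[1], n_hom = x$groups$n[2])
}

#' @rdname tidy.age_comparison
#' @param object an `age_comparison` object.
#' @method autoplot age_comparison
#' @export
autoplot.age_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(names(object$ages), function(g)
    tibble::tibble(label = g, age = object$ages[[g]])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age / 1e6,
                                   fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "insertion age (My)", y = "density",
                  fill = "zygosity") +
    ggplot2::theme_minimal()
}
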