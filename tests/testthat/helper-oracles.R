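# brute-force per-base oracle for the reciprocal-overlap rule
oracle_zygosity <- function(te, dels, aligned, fd = 0.5, ft = 0.8) {
  te_bases <- seq(te$start, te$end - 1L)
  best <- NULL
  for (i in seq_len(nrow(dels))) {
    ov <- length(intersect(te_bases, seq(dels$start[i], dels$end[i] - 1L)))
    if (ov == 0) next
    if (is.null(best) || ov > best$ov ||
        (ov == best$ov && dels$start[i] < dels$start[best$i]))
      best <- list(i = i, ov = ov)
  }
  if (!is.null(best)) {
    dl <- dels$end[best$i] - dels$start[best$i]
    if (best$ov / dl > fd && best$ov / (te$end - te$start) >= ft)
      return("heterozygous")
    return("partial")
  }
  cov <- unique(unlist(Map(seq, aligned$start, aligned$end - 1L)))
  if (all(te_bases %in% cov)) "homozygous" else "unresolved"
}
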