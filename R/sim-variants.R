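# Batch rejection placement: draw candidate footprints, drop those hitting
# static exclusion zones or already-claimed space, then greedily keep a
# non-overlapping subset (buffered by min_separation); redraw any deficit.
# Positions are uniform over chromosomes weighted by length.
draw_positions <- function(n, footprint_fun, genome, exclude_by_chrom,
                           occupied_env, buffer, edge = 200L,
                           max_rounds = 1000L) {
  empty <- tibble::tibble(chrom = character(), pos = integer(), fp = integer())
  if (n == 0) return(empty)
  lens <- nchar(genome)
  out <- list()
  got <- 0L
  for (round in seq_len(max_rounds)) {
    need <- n - got
    if (need <= 0) break
    m <- max(need * 2L, 10L)
    chrom <- sample(names(genome), m, replace = TRUE, prob = lens)
    fp <- as.integer(footprint_fun(m))
    width <- lens[chrom] - fp - 2L * edge
    ok <- width > 0
    pos <- rep(NA_integer_, m)
    pos[ok] <- as.integer(edge + floor(stats::runif(sum(ok)) * width[ok]))
    cand <- tibble::tibble(chrom = chrom, pos = pos, fp = fp)[ok, ]
    for (ch in unique(cand$chrom)) {
      if (need <= 0) break
      idx <- which(cand$chrom == ch)
      ir <- IRanges::IRanges(cand$pos[idx] + 1L - buffer,
                             cand$pos[idx] + cand$fp[idx] + buffer)
      bad <- IRanges::countOverlaps(ir, occupied_env$occ[[ch]]) > 0
      excl <- exclude_by_chrom[[ch]]
      if (!is.null(excl) && length(excl))
        bad <- bad | IRanges::countOverlaps(ir, excl) > 0
      keep <- idx[!bad]
      if (length(keep) > 1) {  # self-overlaps within the batch: greedy scan
        o <- keep[order(cand$pos[keep])]
        last_end <- -.Machine$integer.max
        sel <- logical(length(o))
        for (j in seq_along(o)) {
          s <- cand$pos[o[j]] - buffer
          e <- cand$pos[o[j]] + cand$fp[o[j]] + buffer
          if (s > last_end) { sel[j] <- TRUE; last_end <- e }
        }
        keep <- o[sel]
      }
      if (length(keep)) {
        take <- keep[seq_len(min(length(keep), need))]
        acc <- cand[take, , drop = FALSE]
        out[[length(out) + 1L]] <- acc
        occupied_env$occ[[ch]] <- c(
          occupied_env$occ[[ch]],
          IRanges::IRanges(acc$pos + 1L - buffer, acc$pos + acc$fp + buffer))
        got <- got + nrow(acc)
        need <- n - got
      }
    }
    if (got >= n) {
      res <- dplyr::bind_rows(out)
      return(res[seq_len(n), ])
    }
  }
  stopf("event placement failed after %d rounds: genome too crowded",
        max_rounds)
}

per_chrom_ranges <- function(chroms, starts1, ends, genome) {
  lapply(stats::setNames(names(genome), names(genome)), function(ch) {
    i <- chroms == ch
    IRanges::IRanges(starts1[i], ends[i])
  })
}

# short-indel length distribution: geometric, capped at 39 bp
rindel_len <- function(n) pmin(1L + stats::rgeom(n, 0.3), SV_MIN_LEN - 1L)

# generic SV length: log-uniform between 40 bp and 8 kb
rsv_len <- function(n) {
  as.integer(round(10^stats::runif(n, log10(SV_MIN_LEN), log10(8000))))
}

#' Plant variation between the two phases of a synthetic diploid
#'
#' Derives phase-0 and phase-1 from a reference: phase-0 is the reference
#' plus newly inserted transposable-element copies (heterozygous
#' phase-0-specific ones and planted homozygous ones, each flanked by its
#' target-site duplication); phase-1 is then edited with SNPs, short indels
#' (1-39 bp), generic structural variants (>= 40 bp), fresh
#' phase-1-specific TE insertions, and precise deletions of every
#' phase-0-specific element (element plus one TSD copy, i.e. the biological
#' empty allele). Event counts are Poisson draws at the configured per-bp
#' rates; events are placed without overlap by rejection sampling, and the
#' truth table is left-normalised so breakpoint-exact recovery is
#' well-defined.
#'
#' @param reference a [generate_reference()] result.
#' @param params the same [sim_params()] object.
#' @return list of class `diploid_sim`: `p0`/`p1` (named sequence vectors),
#'   `genes` and `tes` (annotations lifted to final phase-0 coordinates;
#'   `tes` carries truth zygosity and age), `truth` (list with `variants`
#'   tibble and `gene_ratios` tibble), plus the `params`.
#' @export
plant_variants <- function(reference, params) {
  stopifnot(inherits(reference, "sim_reference"),
            inherits(params, "sim_params"))
  lib <- reference$te_library
  genome <- reference$genome
  total_len <- sum(nchar(genome))

  with_seed(params$seed + 1L, {
    n_snp <- stats::rpois(1, total_len * params$snp_rate)
    n_indel <- stats::rpois(1, total_len * params$indel_rate)
    n_sv <- stats::rpois(1, total_len * params$sv_rate)
    if (!is.null(params$n_te_insertions)) {
      n_te_events <- params$n_te_insertions
      n_het_te <- round(n_te_events * params$het_te_fraction)
    } else {
      n_het_te <- round(n_sv * params$te_sv_fraction)
      n_te_events <- if (params$het_te_fraction > 0)
        round(n_het_te / params$het_te_fraction) else n_het_te
    }
    n_hom_te <- n_te_events - n_het_te
    n_te_p0 <- ceiling(n_het_te / 2)
    n_te_p1 <- n_het_te - n_te_p0
    n_generic <- max(n_sv - n_het_te, 0L)

    # static exclusion zones on the original reference
    gs <- reference$genes[reference$genes$feature == "gene", ]
    gene_zone <- per_chrom_ranges(gs$chrom, gs$start + 1L - 20L,
                                  gs$end + 20L, genome)
    te_zone <- per_chrom_ranges(
      reference$tes$chrom,
      reference$tes$start + 1L - params$min_separation,
      reference$tes$end + params$min_separation, genome)
    both_zone <- lapply(stats::setNames(names(genome), names(genome)),
                        function(ch) c(gene_zone[[ch]], te_zone[[ch]]))

    occ <- new.env()
    occ$occ <- lapply(stats::setNames(names(genome), names(genome)),
                      function(ch) IRanges::IRanges())
    buffer <- params$min_separation
    max_tsd <- max(c(params$tsd_len_by_order, 0L))
    fp_te <- as.integer(max(lib$length) + max_tsd)

    te_events <- list()
    for (kind in c("te_p0", "te_hom", "te_p1")) {
      n_k <- switch(kind, te_p0 = n_te_p0, te_hom = n_hom_te, te_p1 = n_te_p1)
      if (n_k == 0) next
      pl <- draw_positions(n_k, function(m) rep(fp_te, m),
                           genome, both_zone, occ, buffer)
      age_range <- if (kind == "te_hom") params$ltr_age_range_hom else
        params$ltr_age_range_het
      te_events[[kind]] <- dplyr::mutate(
        pl, type = kind,
        lib_i = sample.int(nrow(lib), nrow(pl), replace = TRUE),
        age = stats::runif(nrow(pl), age_range[1], age_range[2]))
    }
    te_events <- dplyr::bind_rows(te_events)
    if (!nrow(te_events))
      te_events <- tibble::tibble(chrom = character(), pos = integer(),
                                  fp = integer(), type = character(),
                                  lib_i = integer(), age = numeric())

    sv_ins <- draw_positions(floor(n_generic / 2), function(m) rep(1L, m),
                             genome, te_zone, occ, buffer)
    n_svd <- n_generic - floor(n_generic / 2)
    sv_del <- draw_positions(n_svd, function(m) rsv_len(m),
                             genome, te_zone, occ, buffer)
    ind_ins <- draw_positions(floor(n_indel / 2), function(m) rep(1L, m),
                              genome, te_zone, occ, buffer)
    ind_del <- draw_positions(n_indel - floor(n_indel / 2),
                              function(m) rindel_len(m),
                              genome, te_zone, occ, buffer)
    snps <- draw_positions(n_snp, function(m) rep(1L, m),
                           genome, te_zone, occ, buffer)

    # ---- pass 1: phase-0 = reference + TE insertions (phase-0-specific and
    # planted homozygous copies), tracking offsets for coordinate remapping
    p0 <- genome
    pass1 <- te_events[te_events$type %in% c("te_p0", "te_hom"), , drop = FALSE]
    p0_te_rows <- list(); p0_del_events <- list()
    offsets <- list()  # per chrom: orig insertion points + cumulative shifts
    tid <- nrow(reference$tes)
    for (ch in names(genome)) {
      ev <- pass1[pass1$chrom == ch, , drop = FALSE]
      ev <- ev[order(ev$pos), , drop = FALSE]
      shift <- 0L
      s <- genome[[ch]]
      pieces <- character(0); cursor <- 0L
      orig_pos <- integer(0); shifts <- integer(0)
      for (i in seq_len(nrow(ev))) {
        row <- lib[ev$lib_i[i], ]
        tsd <- unname(params$tsd_len_by_order[row$order])
        if (is.na(tsd)) tsd <- 0L
        p <- ev$pos[i]
        site <- if (tsd > 0) substr(s, p + 1L - tsd, p) else ""
        elem <- aged_te_copy(row, ev$age[i], params$mu)
        ins <- paste0(elem, site)
        pieces <- c(pieces, substr(s, cursor + 1L, p), ins)
        cursor <- p
        new_pos <- p + shift  # element start in final phase-0 coordinates
        shift <- shift + nchar(ins)
        orig_pos <- c(orig_pos, p); shifts <- c(shifts, shift)
        tid <- tid + 1L
        zyg <- if (ev$type[i] == "te_p0") "heterozygous" else "homozygous"
        p0_te_rows[[length(p0_te_rows) + 1L]] <-
          te_annotation_row(sprintf("te%05d", tid), ch, new_pos, row,
                            ev$age[i], zyg)
        if (ev$type[i] == "te_p0") {
          p0_del_events[[length(p0_del_events) + 1L]] <- tibble::tibble(
            chrom = ch, pos = new_pos, ref = ins, alt = "",
            svtype = "DEL", phase = "P0",
            te_id = sprintf("te%05d", tid), consensus_id = row$consensus_id,
            age = ev$age[i])
        }
      }
      pieces <- c(pieces, substr(s, cursor + 1L, nchar(s)))
      p0[[ch]] <- paste(pieces, collapse = "")
      offsets[[ch]] <- list(orig_pos = orig_pos, shifts = shifts)
    }
    remap <- function(ch, pos) {  # original reference -> final phase-0
      om <- offsets[[ch]]
      if (is.null(om) || !length(om$orig_pos)) return(as.integer(pos))
      idx <- findInterval(pos, om$orig_pos)
      as.integer(pos + ifelse(idx == 0L, 0L, om$shifts[pmax(idx, 1L)]))
    }
    remap_tbl <- function(tb, cols) {
      if (!nrow(tb)) return(tb)
      for (cl in cols)

        tb[[cl]] <- unlist(Map(remap, tb$chrom, tb[[cl]]), use.names = FALSE)
      tb
    }

    genes <- remap_tbl(reference$genes, c("start", "end"))
    tes <- remap_tbl(reference$tes,
                     c("start", "end", "ltr5_start", "ltr5_end",
                       "ltr3_start", "ltr3_end"))
    tes <- dplyr::bind_rows(tes, dplyr::bind_rows(p0_te_rows))
    tes <- dplyr::arrange(tes, .data$chrom, .data$start)

    # ---- pass 2: assemble the phase-1 edit script in phase-0 coordinates
    edits <- list()
    add <- function(tb) edits[[length(edits) + 1L]] <<- tb

    if (length(p0_del_events)) add(dplyr::bind_rows(p0_del_events))
    p1_te <- te_events[te_events$type == "te_p1", , drop = FALSE]
    if (nrow(p1_te)) {
      add(purrr::pmap_dfr(
        list(p1_te$chrom, p1_te$pos, p1_te$lib_i, p1_te$age),
        function(ch, p, li, age) {
          row <- lib[li, ]
          tsd <- unname(params$tsd_len_by_order[row$order])
          if (is.na(tsd)) tsd <- 0L
          p2 <- remap(ch, p)
          site <- if (tsd > 0) seq_sub(p0, ch, p2 - tsd, p2) else ""
          tibble::tibble(chrom = ch, pos = p2, ref = "",
                         alt = paste0(aged_te_copy(row, age, params$mu), site),
                         svtype = "INS", phase = "P1",
                         te_id = NA_character_, consensus_id = row$consensus_id,
                         age = age)
        }))
    }
    take_ref <- function(tb) {
      pos2 <- remap_vec(tb, offsets)
      tibble::tibble(chrom = tb$chrom, pos = pos2,
                     ref = unlist(Map(function(ch, p, w)
                       seq_sub(p0, ch, p, p + w), tb$chrom, pos2, tb$fp),
                       use.names = FALSE),
                     alt = "", svtype = "DEL", phase = "P0")
    }
    if (nrow(sv_ins))
      add(tibble::tibble(chrom = sv_ins$chrom, pos = remap_vec(sv_ins, offsets),
                         ref = "",
                         alt = vapply(rsv_len(nrow(sv_ins)), random_dna,
                                      character(1)),
                         svtype = "INS", phase = "P1"))
    if (nrow(sv_del)) add(take_ref(sv_del))
    if (nrow(ind_ins))
      add(tibble::tibble(chrom = ind_ins$chrom,
                         pos = remap_vec(ind_ins, offsets), ref = "",
                         alt = vapply(rindel_len(nrow(ind_ins)), random_dna,
                                      character(1)),
                         svtype = "INS", phase = "P1"))
    if (nrow(ind_del)) add(take_ref(ind_del))
    if (nrow(snps)) {
      pos2 <- remap_vec(snps, offsets)
      refb <- unlist(Map(function(ch, p) seq_sub(p0, ch, p, p + 1L),
                         snps$chrom, pos2), use.names = FALSE)
      altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1),
                     character(1))
      add(tibble::tibble(chrom = snps$chrom, pos = pos2, ref = refb,
                         alt = unname(altb), svtype = "none", phase = "P1"))
    }

    ed <- dplyr::bind_rows(edits)
    if (!nrow(ed)) {
      truth_variants <- empty_variants()
      p1 <- p0
    } else {
      if (!"te_id" %in% names(ed)) ed$te_id <- NA_character_
      if (!"consensus_id" %in% names(ed)) ed$consensus_id <- NA_character_
      if (!"age" %in% names(ed)) ed$age <- NA_real_
      truth_variants <- tibble::tibble(
        chrom = ed$chrom, pos = ed$pos,
        var_class = variant_class_of(
          ifelse(ed$svtype == "none", 1L, nchar(ed$ref)),
          ifelse(ed$svtype == "none", 1L, nchar(ed$alt))),
        svtype = ed$svtype,
        length = as.integer(ifelse(ed$svtype == "none", 1L,
                                   pmax(nchar(ed$ref), nchar(ed$alt)))),
        ref_allele = ed$ref, alt_allele = ed$alt, phase = ed$phase,
        te_id = ed$te_id, consensus_id = ed$consensus_id, age = ed$age)
      p1 <- apply_variants(p0, truth_variants)
      truth_variants <- normalize_variants(truth_variants, p0)
      truth_variants <- finish_variants(truth_variants)
    }

    gene_ids <- unique(genes$gene_id)
    n_eff <- round(length(gene_ids) * params$ase_effect_fraction)
    eff <- if (n_eff) sample(gene_ids, n_eff) else character(0)
    ratio <- stats::setNames(rep(0.5, length(gene_ids)), gene_ids)
    if (n_eff)
      ratio[eff] <- ifelse(stats::runif(n_eff) < 0.5,
                           params$ase_effect_ratio,
                           1 - params$ase_effect_ratio)
    organs <- sprintf("organ%d", seq_len(params$n_organs))
    gene_ratios <- tidyr::expand_grid(gene_id = gene_ids, organ = organs)
    gene_ratios$ratio <- unname(ratio[gene_ratios$gene_id])

    structure(list(p0 = p0, p1 = p1, genes = genes, tes = tes,
                   truth = list(variants = truth_variants,
                                gene_ratios = gene_ratios),
                   params = params),
              class = "diploid_sim")
  })
}

remap_vec <- function(tb, offsets) {
  unlist(Map(function(ch, p) {
    om <- offsets[[ch]]
    if (is.null(om) || !length(om$orig_pos)) return(as.integer(p))
    idx <- findInterval(p, om$orig_pos)
    as.integer(p + if (idx == 0L) 0L else om$shifts[idx])
  }, tb$chrom, tb$pos), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
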