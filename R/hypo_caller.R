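#' Parameters of the hypomethylated-region rule cascade
#'
#' Defaults follow the published rule set: admissible segments span at
#' least 10 bp and 4 CpGs; flanking segments span at least 300 bp and sit
#' within 5000 bp; a candidate dips at least 2 standard deviations below
#' both flanks and has mean methylation below 0.5; candidates with fewer
#' than 10 CpGs and both flanks below 0.5 are dropped; UMRs require mean
#' and SD below 0.1; additional UMRs require > 500 bp and > 30 CpGs/kb;
#' DMVs require >= 5 kb, chaining gaps < 5 kb and mean CpG spacing
#' <= 500 bp.
#'
#' @param min_size,min_cpg admissibility thresholds (bp, CpGs).
#' @param flank_min_size minimum flank size in bp.
#' @param max_flank_dist maximum distance to a flank in bp.
#' @param dip_sd dip depth in units of the reference SD.
#' @param sd_mode whose SD the dip uses: the segment of interest (`"soi"`,
#'   default), the flank (`"flank"`) or the pooled value (`"pooled"`).
#' @param sd_floor lower floor on the reference SD (guards zero-variance
#'   segments).
#' @param lmr_max_mean upper mean-methylation bound for LMR candidates.
#' @param drop_max_cpg,drop_flank_mean the small-dip drop rule: candidates
#'   with fewer CpGs than `drop_max_cpg` and both flank means below
#'   `drop_flank_mean` are discarded.
#' @param umr_max_mean,umr_max_sd UMR reclassification thresholds.
#' @param add_umr_min_size,add_umr_min_density additional-UMR thresholds
#'   (bp, CpGs per kb).
#' @param dmv_min_size,dmv_gap,dmv_max_spacing DMV thresholds (bp).
#' @return A named list of parameters.
#' @export
hypo_params <- function(min_size = 10, min_cpg = 4,
                        flank_min_size = 300, max_flank_dist = 5000,
                        dip_sd = 2, sd_mode = c("soi", "flank", "pooled"),
                        sd_floor = 0.01,
                        lmr_max_mean = 0.5,
                        drop_max_cpg = 10, drop_flank_mean = 0.5,
                        umr_max_mean = 0.1, umr_max_sd = 0.1,
                        add_umr_min_size = 500, add_umr_min_density = 30,
                        dmv_min_size = 5000, dmv_gap = 5000,
                        dmv_max_spacing = 500) {
  list(
    min_size = min_size, min_cpg = min_cpg,
    flank_min_size = flank_min_size, max_flank_dist = max_flank_dist,
    dip_sd = dip_sd, sd_mode = match.arg(sd_mode), sd_floor = sd_floor,
    lmr_max_mean = lmr_max_mean,
    drop_max_cpg = drop_max_cpg, drop_flank_mean = drop_flank_mean,
    umr_max_mean = umr_max_mean, umr_max_sd = umr_max_sd,
    add_umr_min_size = add_umr_min_size,
    add_umr_min_density = add_umr_min_density,
    dmv_min_size = dmv_min_size, dmv_gap = dmv_gap,
    dmv_max_spacing = dmv_max_spacing
  )
}

seg_size <- function(segments) segments$end - segments$start + 1L

#' Call LMRs and UMRs from a methylation-scale segmentation
#'
#' Applies, in order: (1) admissibility flagging; (2) segments of interest
#' (methylation strictly below both nearest admissible neighbours);
#' (3) flank assignment; (4) candidate LMRs (2-SD dip versus both flanks,
#' mean below 0.5, flanks within 5000 bp); (5) the small-dip drop rule;
#' (6) reclassification of unmethylated low-variance candidates as UMRs;
#' (7) remaining candidates as LMRs; (8) additional UMRs among dense,
#' large, unmethylated segments of interest without a clear dip.
#'
#' A segment of interest at a chromosome end has only one admissible
#' neighbour and is therefore never a candidate (both flanks are required).
#'
#' @param segments segment table from the `lambda2 = 25` methylation fit,
#'   gap-split at 500 bp, with statistics filled in (may span several
#'   chromosomes).
#' @param params a [hypo_params()] list.
#' @return Region table with columns of `segments` plus `label`
#'   (`"UMR"` or `"LMR"`).
#' @export
call_hypomethylated_regions <- function(segments, params = hypo_params()) {
  if (nrow(segments) == 0) return(empty_regions())
  out <- lapply(split(segments, by = "chrom", sorted = TRUE),
                call_hypo_chrom, params = params)
  rbindlist(out)
}

empty_regions <- function() {
  cbind(empty_segments(), data.table(label = character()))
}

call_hypo_chrom <- function(seg, params) {
  p <- params
  seg <- seg[order(seg$start)]
  n <- nrow(seg)
  size <- seg_size(seg)
  admissible <- size >= p$min_size & seg$n_cpg >= p$min_cpg & !is.na(seg$mean)
  adm_idx <- which(admissible)
  if (length(adm_idx) < 3) return(empty_regions())

  # nearest admissible neighbour on each side, in genomic order
  prev_adm <- rep(NA_integer_, n)
  next_adm <- rep(NA_integer_, n)
  last <- NA_integer_
  for (i in seq_len(n)) {
    if (i > 1) prev_adm[i] <- last
    if (admissible[i]) last <- i
  }
  last <- NA_integer_
  for (i in rev(seq_len(n))) {
    if (i < n) next_adm[i] <- last
    if (admissible[i]) last <- i
  }
  soi <- admissible & !is.na(prev_adm) & !is.na(next_adm) &
    seg$mean < seg$mean[ifelse(is.na(prev_adm), 1L, prev_adm)] &
    seg$mean < seg$mean[ifelse(is.na(next_adm), 1L, next_adm)]

  # flanks: nearest admissible, >= 300 bp, non-SOI segment on each side
  flank_ok <- admissible & size >= p$flank_min_size & !soi
  flank_left <- rep(NA_integer_, n)
  flank_right <- rep(NA_integer_, n)
  last <- NA_integer_
  for (i in seq_len(n)) {
    if (i > 1) flank_left[i] <- last
    if (flank_ok[i]) last <- i
  }
  last <- NA_integer_
  for (i in rev(seq_len(n))) {
    if (i < n) flank_right[i] <- last
    if (flank_ok[i]) last <- i
  }

  ref_sd <- function(i, fl, fr) {
    s <- switch(p$sd_mode,
      soi = seg$sd[i],
      flank = max(seg$sd[fl], seg$sd[fr]),
      pooled = stats::weighted.mean(
        c(seg$sd[i], seg$sd[fl], seg$sd[fr]),
        c(seg$n_cpg[i], seg$n_cpg[fl], seg$n_cpg[fr])
      )
    )
    max(s, p$sd_floor)
  }

  candidate <- rep(FALSE, n)
  dropped <- rep(FALSE, n)
  for (i in which(soi)) {
    fl <- flank_left[i]
    fr <- flank_right[i]
    if (is.na(fl) || is.na(fr)) next
    dist_l <- seg$start[i] - seg$end[fl]
    dist_r <- seg$start[fr] - seg$end[i]
    if (dist_l > p$max_flank_dist || dist_r > p$max_flank_dist) next
    s <- ref_sd(i, fl, fr)
    dip <- (seg$mean[fl] - seg$mean[i] >= p$dip_sd * s) &&
      (seg$mean[fr] - seg$mean[i] >= p$dip_sd * s)
    if (!dip || seg$mean[i] >= p$lmr_max_mean) next
    candidate[i] <- TRUE
    if (seg$n_cpg[i] < p$drop_max_cpg &&
        seg$mean[fl] < p$drop_flank_mean &&
        seg$mean[fr] < p$drop_flank_mean) {
      dropped[i] <- TRUE
    }
  }

  kept <- candidate & !dropped
  is_umr <- kept & seg$mean < p$umr_max_mean & seg$sd < p$umr_max_sd
  is_lmr <- kept & !is_umr

  # additional UMRs: dense, large, unmethylated SOIs without a clear dip
  density <- seg$n_cpg / size * 1000
  add_umr <- soi & !candidate &
    seg$mean < p$umr_max_mean & seg$sd < p$umr_max_sd &
    size > p$add_umr_min_size & density > p$add_umr_min_density
  is_umr <- is_umr | add_umr

  out <- seg[is_umr | is_lmr]
  if (nrow(out) == 0) return(empty_regions())
  out[, label := ifelse(is_umr[is_umr | is_lmr], "UMR", "LMR")]
  out[order(start)]
}

#' Call DNA methylation valleys and fold them into the region set
#'
#' Consecutive segments with mean methylation below 0.1 are chained unless
#' separated by a gap of 5 kb or more; chains (which contain any
#' overlapping or adjacent UMRs) become DMVs when the merged span is at
#' least 5 kb with a mean inter-CpG distance of at most 500 bp.  DMV
#' statistics are recomputed over the span's covered CpGs, and UMRs or
#' LMRs overlapping a DMV are removed from the region list.
#'
#' @param regions UMR/LMR table from [call_hypomethylated_regions()]
#'   (single chromosome).
#' @param segments full single-chromosome segment table of the
#'   `lambda2 = 25` fit, with statistics.
#' @param y observed pooled fractions for the chromosome.
#' @param pos CpG coordinates aligned with `y`.
#' @param params a [hypo_params()] list.
#' @return Region table with DMVs added and shadowed UMRs/LMRs removed.
#' @export
call_dmvs <- function(regions, segments, y, pos, params = hypo_params()) {
  p <- params
  if (nrow(segments) == 0) return(regions)
  seg <- segments[order(segments$start)]
  low <- !is.na(seg$mean) & seg$mean < p$umr_max_mean
  if (!any(low)) return(regions)
  chr <- seg$chrom[1]

  idx <- which(low)
  # break chains at non-low segments and at >= dmv_gap separations
  new_chain <- c(TRUE, diff(idx) > 1L |
    (seg$start[idx[-1]] - seg$end[idx[-length(idx)]]) >= p$dmv_gap)
  chain_id <- cumsum(new_chain)
  dmvs <- list()
  for (cid in unique(chain_id)) {
    members <- idx[chain_id == cid]
    f <- min(seg$first_idx[members])
    l <- max(seg$last_idx[members])
    span_start <- pos[f]
    span_end <- pos[l]
    size <- span_end - span_start + 1L
    ncpg <- l - f + 1L
    spacing <- if (ncpg > 1) (span_end - span_start) / (ncpg - 1) else Inf
    if (size >= p$dmv_min_size && spacing <= p$dmv_max_spacing) {
      dmvs[[length(dmvs) + 1L]] <- data.table(
        chrom = chr, start = span_start, end = span_end,
        first_idx = f, last_idx = l, n_cpg = ncpg,
        level = NA_real_, mean = NA_real_, sd = NA_real_, label = "DMV"
      )
    }
  }
  if (length(dmvs) == 0) return(regions)
  dmv <- segment_stats(rbindlist(dmvs), y)
  keep <- rep(TRUE, nrow(regions))
  for (k in seq_len(nrow(dmv))) {
    keep <- keep & !(regions$chrom == chr &
      regions$start <= dmv$end[k] & regions$end >= dmv$start[k])
  }
  rbindlist(list(regions[keep], dmv))[order(start)]
}

#' Suppress LMRs that overlap PMDs
#'
#' LMRs inside partially methylated domains cannot be distinguished from
#' the PMD's own high-variance methylation and are not reported; UMRs and
#' DMVs are retained.  Overlap means at least 1 bp in common.
#'
#' @param regions UMR/LMR/DMV table.
#' @param pmds PMD region table (may be empty).
#' @return The filtered region table.
#' @export
suppress_in_pmds <- function(regions, pmds) {
  if (is.null(pmds) || nrow(pmds) == 0 || nrow(regions) == 0) return(regions)
  keep <- rep(TRUE, nrow(regions))
  for (k in seq_len(nrow(pmds))) {
    keep <- keep & !(regions$label == "LMR" &
      regions$chrom == pmds$chrom[k] &
      regions$start <= pmds$end[k] & regions$end >= pmds$start[k])
  }
  regions[keep]
}
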