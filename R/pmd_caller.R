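#' Rolling per-CpG methylation variability track
#'
#' The PMD signal is the local standard deviation of the observed
#' methylation fractions: for each CpG, the sample SD of `y` over a
#' centered window of `window_cpgs` CpGs, truncated at chromosome ends.
#' Weights (coverages) are carried over so the variance-scale fused lasso
#' remains coverage-weighted.
#'
#' @param y observed per-CpG fractions (NA = uncovered; ignored within the
#'   window).
#' @param pos CpG coordinates aligned with `y`.
#' @param cov per-CpG coverages, used as weights.
#' @param window_cpgs odd window width in CpGs (default 25).
#' @return A list `variance_track` with `pos`, `s` (rolling SD, >= 0) and
#'   `c` (weights).
#' @export
compute_variance_track <- function(y, pos, cov = rep(1, length(y)),
                                   window_cpgs = 25L) {
  stopifnot(window_cpgs >= 3, window_cpgs %% 2 == 1,
            length(y) == length(pos))
  n <- length(y)
  h <- (window_cpgs - 1L) %/% 2L
  ok <- !is.na(y)
  y0 <- ifelse(ok, y, 0)
  cs <- cumsum(y0)
  cs2 <- cumsum(y0^2)
  cn <- cumsum(as.numeric(ok))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sum_y <- cs[hi] - c(0, cs)[lo]
  sum_y2 <- cs2[hi] - c(0, cs2)[lo]
  m <- cn[hi] - c(0, cn)[lo]
  ss <- sum_y2 - sum_y^2 / pmax(m, 1)
  s <- ifelse(m > 1, sqrt(pmax(ss, 0) / (m - 1)), 0)
  structure(list(pos = pos, s = s, c = cov), class = "variance_track")
}

#' Parameters of the PMD caller
#'
#' @param lambda2 fusion strength of the variance-scale segmentation
#'   (default 1000: PMDs are large domains).
#' @param gap_bp split threshold between consecutive CpGs (default 5 kb).
#' @param min_size minimum admissible segment size in bp (> 5 kb).
#' @param min_cpg minimum admissible CpG count.
#' @param max_spacing maximum mean inter-CpG distance in bp (excludes very
#'   large, CpG-poor outlier segments).
#' @param max_mean mean-methylation ceiling (default 0.70, the classical
#'   PMD definition).
#' @param min_sd minimum methylation standard deviation (default 0.15).
#' @param window_cpgs rolling window of [compute_variance_track()].
#' @return A named list of parameters.
#' @export
pmd_params <- function(lambda2 = 1000, gap_bp = 5000, min_size = 5000,
                       min_cpg = 4, max_spacing = 500, max_mean = 0.70,
                       min_sd = 0.15, window_cpgs = 25L) {
  list(lambda2 = lambda2, gap_bp = gap_bp, min_size = min_size,
       min_cpg = min_cpg, max_spacing = max_spacing, max_mean = max_mean,
       min_sd = min_sd, window_cpgs = window_cpgs)
}

#' Call partially methylated domains on one chromosome
#'
#' Fits the fused lasso to the variability track (`lambda2 = 1000`), splits
#' the resulting segments at inter-CpG gaps of 5 kb or more and at UMRs or
#' DMVs, keeps admissible segments (size > 5 kb, >= 4 CpGs, mean CpG
#' spacing < 500 bp) and calls PMDs as those whose methylation (computed
#' from `y`) has mean below `max_mean` and standard deviation above
#' `min_sd`.  Contiguous PMDs (adjacent in the CpG array, not separated by
#' a large gap) are merged and their statistics recomputed.
#'
#' @param variance a `variance_track` from [compute_variance_track()].
#' @param y observed pooled methylation fractions for the chromosome.
#' @param umrs_dmvs UMR/DMV region table used for splitting (LMRs are
#'   ignored).
#' @param params a [pmd_params()] list.
#' @param chrom chromosome name.
#' @return PMD region table (possibly empty) with `label = "PMD"`.
#' @export
call_pmds <- function(variance, y, umrs_dmvs = NULL, params = pmd_params(),
                      chrom = "chr") {
  p <- params
  pos <- variance$pos
  if (length(pos) == 0) return(empty_regions())
  fit <- solve_fused_lasso_1d(variance$s, variance$c, p$lambda2)
  seg <- beta_to_segments(fit$beta, pos, chrom = chrom, gap_bp = p$gap_bp)
  if (!is.null(umrs_dmvs) && nrow(umrs_dmvs) > 0) {
    excl <- umrs_dmvs[umrs_dmvs$label %in% c("UMR", "DMV"), , drop = FALSE]
    seg <- split_at_regions(seg, excl, y, pos)
  } else {
    seg <- segment_stats(seg, y)
  }
  if (nrow(seg) == 0) return(empty_regions())
  size <- seg_size(seg)
  spacing <- ifelse(seg$n_cpg > 1, (seg$end - seg$start) / (seg$n_cpg - 1), Inf)
  admissible <- size > p$min_size & seg$n_cpg >= p$min_cpg &
    spacing < p$max_spacing
  is_pmd <- admissible & !is.na(seg$mean) &
    seg$mean < p$max_mean & seg$sd > p$min_sd
  if (!any(is_pmd)) return(empty_regions())
  pmd <- seg[is_pmd][order(start)]

  # merge contiguous PMDs: bordering CpGs adjacent in the array and not
  # separated by a large gap
  merged <- list()
  cur <- pmd[1]
  for (k in seq_len(nrow(pmd))[-1]) {
    contiguous <- pmd$first_idx[k] == cur$last_idx + 1L &&
      (pmd$start[k] - cur$end) < p$gap_bp
    if (contiguous) {
      cur$end <- pmd$end[k]
      cur$last_idx <- pmd$last_idx[k]
      cur$n_cpg <- cur$last_idx - cur$first_idx + 1L
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- pmd[k]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- segment_stats(rbindlist(merged), y)
  out[, label := "PMD"]
  out[]
}
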