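#' Paired Wilcoxon signed-rank test with exact small-sample null
#'
#' Zero differences are dropped; ties in the absolute differences get
#' mid-ranks.  For `n <= exact_max` informative pairs the two-sided
#' p-value comes from the exact sign-flip null distribution (computed by
#' convolution, so ties are handled exactly); above that, from the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b paired observations.
#' @param exact_max largest n for which the exact null is enumerated.
#' @return Two-sided p-value.
#' @export
wilcoxon_paired <- function(a, b, exact_max = 25L) {
  d <- b - a
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    warning("no nonzero paired differences; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))  # mid-ranks doubled are integers
    f <- c(1, numeric(sum(r2)))     # f[s+1] = #sign assignments with 2W = s
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(length(f) - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):length(probs)])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null (via the signed rank-count distribution) when both groups
#' have at most `exact_max` observations and there are no ties; normal
#' approximation with tie and continuity corrections otherwise.
#'
#' @param a,b the two groups of observations.
#' @param exact_max largest per-group n for the exact null.
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(a, b, exact_max = 25L) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0 || n2 == 0) {
    warning("empty group in rank-sum test; p = 1")
    return(1)
  }
  r <- rank(c(a, b))
  ties <- any(duplicated(c(a, b)))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- if (U > n1 * n2 / 2) {
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n1, n2)
    }
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  nt <- n1 + n2
  tie <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((nt + 1) - sum(tie^3 - tie) / (nt * (nt - 1)))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' Wilcoxon p-value for a DMR span
#'
#' Compares the pooled per-CpG methylation fractions of the two conditions
#' over the span's CpGs; sites uncovered in either pooled condition are
#' excluded.  The default compares the two sets of values with the
#' rank-sum test; `method = "paired"` uses the per-CpG signed-rank test
#' instead (see the methods vignette for why rank-sum is the default).
#'
#' @param ya,yb pooled fractions of the span's CpGs in each condition
#'   (NA = uncovered).
#' @param method `"ranksum"` or `"paired"`.
#' @return Two-sided p-value; 1 (with a warning) when no CpG is covered in
#'   both conditions.
#' @export
wilcoxon_dmr <- function(ya, yb, method = c("ranksum", "paired")) {
  method <- match.arg(method)
  ok <- !is.na(ya) & !is.na(yb)
  if (!any(ok)) {
    warning("no CpG covered in both conditions; p = 1")
    return(1)
  }
  if (method == "paired") {
    suppressWarnings(p <- wilcoxon_paired(ya[ok], yb[ok]))
    if (all(yb[ok] == ya[ok])) p <- 1
    p
  } else {
    wilcoxon_ranksum(ya[ok], yb[ok])
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure with monotonicity enforcement, applied genome-wide
#' across all candidate DMRs after the coverage-score filter.
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted values (FDR) in `[0, 1]`.
#' @export
adjust_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Segment the methylation differences between two conditions
#'
#' Runs the coupled two-condition fit and extracts segments from the
#' difference coefficients (run-length decomposition plus 500 bp gap
#' split, borders on CpGs).  Each segment's `mean` and `sd` are the mean
#' and SD of the per-CpG pooled methylation differences (second condition
#' minus reference) over its covered CpGs.
#'
#' @param cmat a two-condition [build_condition_matrix()] result.
#' @param lambda2 fusion strength (default 25).
#' @param gap_bp inter-CpG split threshold.
#' @param fit optional precomputed [solve_two_condition()] result.
#' @return Segment table across chromosomes (indices refer to the
#'   per-chromosome aligned arrays).
#' @export
segment_differences <- function(cmat, lambda2 = 25, gap_bp = 500L,
                                fit = NULL) {
  if (is.null(fit)) fit <- solve_two_condition(cmat, lambda2 = lambda2)
  out <- lapply(names(cmat$chroms), function(chr) {
    entry <- cmat$chroms[[chr]]
    f <- fit$chroms[[chr]]
    d <- condition_differences(entry)
    seg <- beta_to_segments(f$beta_diff, entry$pos, chrom = chr,
                            gap_bp = gap_bp)
    segment_stats(seg, d)
  })
  rbindlist(out)
}

# per-CpG pooled difference (b - a); NA where either condition uncovered
condition_differences <- function(entry) {
  sa <- pooled_signal(entry, "a")
  sb <- pooled_signal(entry, "b")
  sb$y - sa$y
}

#' Group neighbouring difference segments
#'
#' Adjacent segments (contiguous in the CpG array) are merged when their
#' mean methylation differences differ by less than `d` (10% by default);
#' merged spans keep CpG borders and get recomputed statistics.
#'
#' @param segments single-chromosome difference-segment table.
#' @param d level-gap threshold.
#' @param diffs per-CpG pooled differences (for recomputed statistics).
#' @param pos CpG coordinates.
#' @return The grouped segment table.
#' @export
group_segments <- function(segments, d = 0.10, diffs = NULL, pos = NULL) {
  if (nrow(segments) <= 1) return(segments)
  seg <- segments[order(segments$start)]
  n <- nrow(seg)
  contiguous <- seg$first_idx[-1] == seg$last_idx[-n] + 1L
  gap <- abs(seg$mean[-1] - seg$mean[-n])
  merge_with_prev <- contiguous & !is.na(gap) & gap < d
  gid <- cumsum(c(TRUE, !merge_with_prev))
  groups <- list()
  for (g in unique(gid)) {
    members <- which(gid == g)
    f <- seg$first_idx[members[1]]
    l <- seg$last_idx[members[length(members)]]
    groups[[length(groups) + 1L]] <- data.table(
      chrom = seg$chrom[1],
      start = seg$start[members[1]], end = seg$end[members[length(members)]],
      first_idx = f, last_idx = l, n_cpg = l - f + 1L,
      level = stats::weighted.mean(seg$level[members], seg$n_cpg[members]),
      mean = NA_real_, sd = NA_real_
    )
  }
  out <- rbindlist(groups)
  if (!is.null(diffs)) out <- segment_stats(out, diffs)
  out
}

#' CpG coverage score of a span
#'
#' The percent of the span's CpGs (union site set) covered by at least
#' `min_cov` reads in every sample of both conditions.  DMRs scoring below
#' 70% are discarded downstream so that the reported mean difference is
#' supported by data at most CpGs.
#'
#' @param first_idx,last_idx span bounds as indices into the chromosome
#'   arrays.
#' @param entry one chromosome entry of a two-condition matrix.
#' @param min_cov minimum read count per sample.
#' @return Percent in `[0, 100]`.
#' @export
coverage_score <- function(first_idx, last_idx, entry, min_cov = 5L) {
  idx <- first_idx:last_idx
  covs <- cbind(entry$cov_a[idx, , drop = FALSE],
                if (!is.null(entry$cov_b)) entry$cov_b[idx, , drop = FALSE])
  100 * sum(rowSums(covs >= min_cov) == ncol(covs)) / length(idx)
}

#' Threshold filter on candidate DMRs
#'
#' Retains candidates with at least `n_min` CpGs covered in each
#' condition, an absolute mean methylation difference of at least `d`, and
#' `p <= p_max`; when `q_max` is given, the FDR criterion `fdr <= q_max`
#' replaces the p-value criterion.
#'
#' @param candidates scored DMR table (columns `n_cpg_a`, `n_cpg_b`,
#'   `diff`, `p`, `fdr`).
#' @param n_min minimum per-condition covered-CpG count.
#' @param d minimum absolute mean difference.
#' @param p_max p-value ceiling.
#' @param q_max optional FDR ceiling replacing `p_max`.
#' @return The retained DMRs.
#' @export
filter_dmrs <- function(candidates, n_min = 4L, d = 0.10, p_max = 0.05,
                        q_max = NULL) {
  if (nrow(candidates) == 0) return(candidates)
  keep <- pmin(candidates$n_cpg_a, candidates$n_cpg_b) >= n_min &
    !is.na(candidates$diff) & abs(candidates$diff) >= d
  keep <- if (is.null(q_max)) {
    keep & candidates$p <= p_max
  } else {
    keep & candidates$fdr <= q_max
  }
  candidates[keep]
}

#' Annotate DMRs with per-condition region classes
#'
#' Each DMR is labelled, per condition, with the region class (LMR, UMR,
#' DMV or PMD) overlapping it most, provided the overlap covers at least
#' 10% of the DMR for the small classes or 50% for PMDs.  The annotation
#' is rendered as a transition, e.g. `"LMRtoUMR"`, `"toPMD"` (no label in
#' the reference condition) or `"fromDMV"` (no label in the second
#' condition); DMRs without a qualifying overlap on either side get an
#' empty annotation.
#'
#' @param dmrs DMR table.
#' @param regions_a,regions_b region calls per condition (may be `NULL` or
#'   empty).
#' @param min_frac minimum overlap fraction for LMR/UMR/DMV.
#' @param pmd_min_frac minimum overlap fraction for PMD.
#' @return The DMR table with an `annotation` column.
#' @export
annotate_dmrs <- function(dmrs, regions_a = NULL, regions_b = NULL,
                          min_frac = 0.10, pmd_min_frac = 0.50) {
  if (nrow(dmrs) == 0) {
    dmrs$annotation <- character(0)
    return(dmrs)
  }
  side_label <- function(regions, chr, s, e) {
    if (is.null(regions) || nrow(regions) == 0) return("")
    len <- e - s + 1
    best <- ""
    best_ov <- 0
    for (cls in c("LMR", "UMR", "DMV", "PMD")) {
      rr <- regions[regions$label == cls & regions$chrom == chr, ,
                    drop = FALSE]
      if (nrow(rr) == 0) next
      ov <- sum(pmax(0, pmin(rr$end, e) - pmax(rr$start, s) + 1))
      thr <- if (cls == "PMD") pmd_min_frac else min_frac
      if (ov / len >= thr && ov > best_ov) {
        best <- cls
        best_ov <- ov
      }
    }
    best
  }
  ann <- character(nrow(dmrs))
  for (k in seq_len(nrow(dmrs))) {
    la <- side_label(regions_a, dmrs$chrom[k], dmrs$start[k], dmrs$end[k])
    lb <- side_label(regions_b, dmrs$chrom[k], dmrs$start[k], dmrs$end[k])
    ann[k] <- if (la == "" && lb == "") {
      ""
    } else if (la == "") {
      paste0("to", lb)
    } else if (lb == "") {
      paste0("from", la)
    } else {
      paste0(la, "to", lb)
    }
  }
  dmrs$annotation <- ann
  dmrs
}
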