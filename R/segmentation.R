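#' Convert a piecewise-constant fit into genomic segments
#'
#' Maximal runs of (tolerance-)equal fitted values become segments; a run
#' is further split wherever two consecutive CpGs are `gap_bp` or more
#' apart, so that segments never bridge CpG deserts.  Segment borders fall
#' on CpG coordinates (start = first CpG, end = last CpG, 1-based
#' inclusive).
#'
#' @param beta fitted values for one chromosome.
#' @param pos strictly increasing CpG coordinates aligned with `beta`.
#' @param chrom chromosome name (scalar).
#' @param gap_bp split threshold on the inter-CpG distance; 500 for the
#'   methylation-scale segmentation, 5000 for the variance-scale one.
#' @param tol plateau equality tolerance.  The default 0.01 merges adjacent
#'   plateaus closer than 1% methylation: the fused fit's level resolution
#'   is bounded by the penalty-to-weight ratio, and the exact optimum
#'   generically leaves shrinkage-scale micro-plateaus at region edges
#'   that no downstream rule can distinguish (all classification
#'   thresholds sit at 10% or more).
#' @return A `data.table` of segments: `chrom`, `start`, `end`,
#'   `first_idx`, `last_idx`, `n_cpg`, `level`, and placeholder `mean`,
#'   `sd` columns (fill with [segment_stats()]).
#' @export
beta_to_segments <- function(beta, pos, chrom = "chr", gap_bp = 500L,
                             tol = 0.01) {
  stopifnot(length(beta) == length(pos), gap_bp > 0)
  n <- length(beta)
  if (n == 0) return(empty_segments())
  if (n > 1) stopifnot(all(diff(pos) > 0))
  runs <- fused_runs(beta, tol = tol)
  gap_after <- which(diff(pos) >= gap_bp)  # split between i and i+1
  first <- integer(0)
  last <- integer(0)
  level <- numeric(0)
  for (k in seq_len(nrow(runs))) {
    f <- runs$first[k]
    l <- runs$last[k]
    cuts <- gap_after[gap_after >= f & gap_after < l]
    starts <- c(f, cuts + 1L)
    ends <- c(cuts, l)
    first <- c(first, starts)
    last <- c(last, ends)
    level <- c(level, rep(runs$level[k], length(starts)))
  }
  data.table(
    chrom = chrom, start = pos[first], end = pos[last],
    first_idx = first, last_idx = last, n_cpg = last - first + 1L,
    level = level, mean = NA_real_, sd = NA_real_
  )
}

empty_segments <- function() {
  data.table(
    chrom = character(), start = integer(), end = integer(),
    first_idx = integer(), last_idx = integer(), n_cpg = integer(),
    level = numeric(), mean = numeric(), sd = numeric()
  )
}

#' Per-segment methylation statistics
#'
#' Computes for each segment the number of CpGs, the unweighted mean of the
#' observed fractions over CpGs with coverage (NA entries of `y` are
#' uncovered sites) and the sample standard deviation (n-1 denominator;
#' 0 for singleton segments, so downstream rule comparisons never meet
#' undefined values).
#'
#' @param segments a segment table from [beta_to_segments()].
#' @param y observed per-CpG fractions aligned with the chromosome arrays
#'   the segment indices refer to.
#' @return The segment table with `mean` and `sd` filled in.
#' @export
segment_stats <- function(segments, y) {
  if (nrow(segments) == 0) return(segments)
  out <- data.table::copy(segments)
  m <- numeric(nrow(out))
  s <- numeric(nrow(out))
  for (k in seq_len(nrow(out))) {
    v <- y[out$first_idx[k]:out$last_idx[k]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      m[k] <- NA_real_
      s[k] <- NA_real_
    } else {
      m[k] <- mean(v)
      s[k] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  out[, `:=`(mean = m, sd = s)]
  out[]
}

#' Split segments at excluded regions
#'
#' Cuts every segment at the boundaries of the exclusion regions, drops the
#' pieces that fall inside an exclusion, and recomputes statistics on the
#' surviving pieces.  Used to keep the variance-scale segmentation from
#' spanning UMRs or DMVs before PMD calling.
#'
#' @param segments single-chromosome segment table.
#' @param exclusions a table with `chrom`, `start`, `end` (sorted,
#'   non-overlapping); regions on other chromosomes are ignored.
#' @param y observed fractions (for the recomputed statistics).
#' @param pos CpG coordinates aligned with `y`.
#' @return The split segment table.
#' @export
split_at_regions <- function(segments, exclusions, y, pos) {
  if (nrow(segments) == 0 || is.null(exclusions) || nrow(exclusions) == 0) {
    return(segments)
  }
  chr <- segments$chrom[1]
  excl <- exclusions[exclusions$chrom == chr, , drop = FALSE]
  if (nrow(excl) == 0) return(segments)
  excluded <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(excl))) {
    excluded <- excluded | (pos >= excl$start[k] & pos <= excl$end[k])
  }
  pieces <- list()
  for (k in seq_len(nrow(segments))) {
    idx <- segments$first_idx[k]:segments$last_idx[k]
    keep <- idx[!excluded[idx]]
    if (length(keep) == 0) next
    brk <- which(diff(keep) > 1L)
    starts <- keep[c(1L, brk + 1L)]
    ends <- keep[c(brk, length(keep))]
    pieces[[length(pieces) + 1L]] <- data.table(
      chrom = chr, start = pos[starts], end = pos[ends],
      first_idx = starts, last_idx = ends, n_cpg = ends - starts + 1L,
      level = segments$level[k], mean = NA_real_, sd = NA_real_
    )
  }
  if (length(pieces) == 0) return(empty_segments())
  segment_stats(rbindlist(pieces), y)
}
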