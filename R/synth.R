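#' Region plan for a synthetic methylome
#'
#' Each row plants one region: `class` (UMR, LMR, DMV or PMD), the target
#' methylation `level` (for PMDs, the mean of a high-dispersion
#' per-CpG beta distribution), the number of CpGs and the mean intra-region
#' CpG spacing in bp.  Defaults emulate the classes' biology: UMRs are
#' short, dense and unmethylated (CpG-island promoters); LMRs carry
#' intermediate methylation at moderate density (distal regulatory
#' elements); DMVs are large unmethylated valleys; PMDs are very large
#' domains of heterogeneous intermediate methylation.
#'
#' @param n_umr,n_lmr,n_dmv,n_pmd region counts.
#' @param umr_cpgs,lmr_cpgs,dmv_cpgs,pmd_cpgs CpG-count ranges (min, max).
#' @return A `data.table` plan for [simulate_methylome()].
#' @export
region_plan <- function(n_umr = 0, n_lmr = 0, n_dmv = 0, n_pmd = 0,
                        umr_cpgs = c(20, 40), lmr_cpgs = c(10, 20),
                        dmv_cpgs = c(60, 80), pmd_cpgs = c(2000, 2000)) {
  pick <- function(n, rng) {
    if (n == 0) integer(0) else sample(rng[1]:rng[2], n, replace = TRUE)
  }
  rbindlist(list(
    data.table(class = rep("UMR", n_umr), level = 0.03,
               n_cpg = pick(n_umr, umr_cpgs), spacing = 25),
    data.table(class = rep("LMR", n_lmr), level = 0.25,
               n_cpg = pick(n_lmr, lmr_cpgs), spacing = 60),
    data.table(class = rep("DMV", n_dmv), level = 0.03,
               n_cpg = pick(n_dmv, dmv_cpgs), spacing = 100),
    data.table(class = rep("PMD", n_pmd), level = 0.5,
               n_cpg = pick(n_pmd, pmd_cpgs), spacing = 100)
  ))
}

# beta shape parameters from mean and sd
beta_ab <- function(m, s) {
  k <- m * (1 - m) / s^2 - 1
  stopifnot(k > 0)
  c(a = m * k, b = (1 - m) * k)
}

# inter-CpG gaps: >= 2 bp, geometric tail, mean = spacing; planted regions
# cap their internal gaps below the 500 bp segmentation split so a truth
# region is never itself a CpG desert (incoherent with its class)
rgaps <- function(n, spacing, max_gap = NA) {
  if (n == 0) return(integer(0))
  g <- 2L + stats::rgeom(n, 1 / pmax(spacing - 1, 1.001))
  if (!is.na(max_gap)) g <- pmin(g, as.integer(max_gap))
  g
}

#' Simulate a single-condition methylome with planted regions
#'
#' CpG positions follow a geometric inter-CpG spacing model (background
#' mean 100 bp, the genome-wide CpG density); planted regions use their
#' own density.  Per-CpG true methylation is the background level
#' (optionally with beta-distributed CpG-to-CpG heterogeneity) outside
#' planted regions and the planted level inside; PMDs draw
#' high-dispersion beta levels per CpG.  Coverage is negative binomial and
#' methylated counts are binomial, independently per replicate.
#'
#' @param plan a [region_plan()] table (may be empty or `NULL`).
#' @param n_cpg total number of CpGs on the chromosome.
#' @param background background methylation level.
#' @param het_sd CpG-level SD of the background (0 = homogeneous).
#' @param spacing mean background inter-CpG distance in bp.
#' @param coverage mean per-CpG read coverage.
#' @param coverage_size negative-binomial size (overdispersion) parameter.
#' @param pmd_sd per-CpG SD of methylation inside PMDs.
#' @param n_reps number of replicates.
#' @param min_gap_cpgs minimum number of background CpGs between planted
#'   regions (keeps flanks clean).
#' @param seed RNG seed (the generator is fully reproducible given a seed).
#' @param chrom chromosome name.
#' @return A list with `tracks` (list of [methylome_track()]), `truth`
#'   (region table with `class`, `level`, `first_idx`, `last_idx`), `pos`
#'   and `level` (the per-CpG true fractions).
#' @export
simulate_methylome <- function(plan = NULL, n_cpg = 1e5, background = 0.8,
                               het_sd = 0, spacing = 100, coverage = 30,
                               coverage_size = 15, pmd_sd = 0.3,
                               n_reps = 1, min_gap_cpgs = 100,
                               seed = 1L, chrom = "chr1") {
  set.seed(seed)
  if (is.null(plan)) plan <- region_plan()
  if (nrow(plan) > 0) {
    stopifnot(all(plan$n_cpg >= 1))
    plan <- plan[sample(nrow(plan))]  # random genomic order
  }
  n_region <- sum(plan$n_cpg)
  n_bg <- n_cpg - n_region
  k <- nrow(plan) + 1L
  if (n_bg < k * min_gap_cpgs) {
    stop("not enough background CpGs to separate the planted regions")
  }
  extra <- as.vector(stats::rmultinom(1, n_bg - k * min_gap_cpgs,
                                      rep(1, k)))
  bg_runs <- min_gap_cpgs + extra

  cls <- rep("background", n_cpg)
  lvl <- numeric(n_cpg)
  spc <- rep(spacing, n_cpg)
  region_first <- integer(nrow(plan))
  region_last <- integer(nrow(plan))
  at <- 0L
  for (j in seq_len(k)) {
    at <- at + bg_runs[j]
    if (j <= nrow(plan)) {
      idx <- (at + 1L):(at + plan$n_cpg[j])
      cls[idx] <- plan$class[j]
      lvl[idx] <- plan$level[j]
      spc[idx] <- plan$spacing[j]
      region_first[j] <- idx[1]
      region_last[j] <- idx[length(idx)]
      at <- at + plan$n_cpg[j]
    }
  }
  bg <- cls == "background"
  if (het_sd > 0) {
    ab <- beta_ab(background, het_sd)
    lvl[bg] <- stats::rbeta(sum(bg), ab["a"], ab["b"])
  } else {
    lvl[bg] <- background
  }
  pmd <- cls == "PMD"
  if (any(pmd)) {
    for (j in which(plan$class == "PMD")) {
      idx <- region_first[j]:region_last[j]
      ab <- beta_ab(plan$level[j], pmd_sd)
      lvl[idx] <- stats::rbeta(length(idx), ab["a"], ab["b"])
    }
  }
  # the gap preceding CpG i follows the spacing model of CpG i; gaps inside
  # planted regions stay below the 500 bp split threshold
  gaps <- integer(n_cpg)
  for (s in unique(spc)) {
    sel <- which(spc == s)
    gaps[sel] <- rgaps(length(sel), spacing = s)
  }
  inside <- cls != "background"
  gaps[inside] <- pmin(gaps[inside], 499L)
  pos <- as.integer(cumsum(as.numeric(gaps)))

  tracks <- lapply(seq_len(n_reps), function(r) {
    cov <- stats::rnbinom(n_cpg, mu = coverage, size = coverage_size)
    meth <- stats::rbinom(n_cpg, cov, lvl)
    methylome_track(rep(chrom, n_cpg), pos, meth, cov - meth,
                    sample = sprintf("sim_rep%d", r))
  })
  truth <- if (nrow(plan) == 0) {
    data.table(chrom = character(), start = integer(), end = integer(),
               class = character(), level = numeric(),
               first_idx = integer(), last_idx = integer())
  } else {
    data.table(
      chrom = chrom, start = pos[region_first], end = pos[region_last],
      class = plan$class, level = plan$level,
      first_idx = region_first, last_idx = region_last
    )[order(start)]
  }
  list(tracks = tracks, truth = truth, pos = pos, level = lvl)
}

#' Simulate a two-condition benchmark with planted DMRs
#'
#' Both conditions share the same per-CpG background methylation
#' (homogeneous constant level, or heterogeneous beta-distributed
#' CpG-to-CpG levels); inside each planted DMR the second condition's
#' level is shifted by a difference drawn uniformly from `diff_bin`, in a
#' random feasible direction (levels are kept inside `[0.01, 0.99]`, and a
#' direction that would saturate is flipped).  DMR lengths are uniform on
#' `dmr_cpgs`.
#'
#' @param n_dmrs number of planted DMRs.
#' @param diff_bin methylation-difference bin, e.g. `c(0.4, 0.6)`; the
#'   four benchmark subsets are 0.1-0.2, 0.2-0.3, 0.3-0.4 and 0.4-0.6.
#' @param background `"heterogeneous"` (beta, mean 0.75, SD 0.15) or
#'   `"homogeneous"` (constant 0.75).
#' @param n_cpg,spacing,coverage,coverage_size,n_reps as in
#'   [simulate_methylome()].
#' @param dmr_cpgs DMR length range in CpGs.
#' @param min_gap_cpgs minimum background CpGs between DMRs.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return A list with `cond_a`, `cond_b` (lists of tracks), `truth`
#'   (with per-DMR true mean difference `diff`), `pos`, `level_a`,
#'   `level_b`.
#' @export
simulate_dmr_benchmark <- function(n_dmrs = 200, diff_bin = c(0.4, 0.6),
                                   background = c("heterogeneous",
                                                  "homogeneous"),
                                   n_cpg = 6e4, spacing = 100,
                                   coverage = 30, coverage_size = 15,
                                   n_reps = 2, dmr_cpgs = c(4, 50),
                                   min_gap_cpgs = 100, seed = 1L,
                                   chrom = "chr1") {
  background <- match.arg(background)
  set.seed(seed)
  bg_mean <- 0.75
  lens <- if (n_dmrs > 0) {
    sample(dmr_cpgs[1]:dmr_cpgs[2], n_dmrs, replace = TRUE)
  } else {
    integer(0)
  }
  n_region <- sum(lens)
  k <- n_dmrs + 1L
  n_bg <- n_cpg - n_region
  stopifnot(n_bg >= k * min_gap_cpgs)
  extra <- as.vector(stats::rmultinom(1, n_bg - k * min_gap_cpgs,
                                      rep(1, k)))
  bg_runs <- min_gap_cpgs + extra

  level_a <- if (background == "heterogeneous") {
    ab <- beta_ab(bg_mean, 0.15)
    stats::rbeta(n_cpg, ab["a"], ab["b"])
  } else {
    rep(bg_mean, n_cpg)
  }
  level_b <- level_a
  first <- integer(n_dmrs)
  last <- integer(n_dmrs)
  at <- 0L
  for (j in seq_len(k)) {
    at <- at + bg_runs[j]
    if (j <= n_dmrs) {
      idx <- (at + 1L):(at + lens[j])
      delta <- stats::runif(1, diff_bin[1], diff_bin[2])
      m <- mean(level_a[idx])
      feas <- c(up = m + delta <= 0.95, down = m - delta >= 0.05)
      dir <- if (all(feas)) {
        sample(c(1, -1), 1)
      } else if (feas["up"]) 1 else -1
      level_b[idx] <- pmin(pmax(level_a[idx] + dir * delta, 0.01), 0.99)
      first[j] <- idx[1]
      last[j] <- idx[length(idx)]
      at <- at + lens[j]
    }
  }
  gaps <- rgaps(n_cpg, spacing)
  in_dmr <- rep(FALSE, n_cpg)
  for (j in seq_len(n_dmrs)) in_dmr[first[j]:last[j]] <- TRUE
  gaps[in_dmr] <- pmin(gaps[in_dmr], 499L)
  pos <- as.integer(cumsum(as.numeric(gaps)))

  sim_tracks <- function(lvl, tag) {
    lapply(seq_len(n_reps), function(r) {
      cov <- stats::rnbinom(n_cpg, mu = coverage, size = coverage_size)
      meth <- stats::rbinom(n_cpg, cov, lvl)
      methylome_track(rep(chrom, n_cpg), pos, meth, cov - meth,
                      sample = sprintf("%s_rep%d", tag, r))
    })
  }
  cond_a <- sim_tracks(level_a, "condA")
  cond_b <- sim_tracks(level_b, "condB")
  truth <- if (n_dmrs == 0) {
    data.table(chrom = character(), start = integer(), end = integer(),
               class = character(), diff = numeric(),
               first_idx = integer(), last_idx = integer())
  } else {
    data.table(
      chrom = chrom, start = pos[first], end = pos[last], class = "DMR",
      diff = vapply(seq_len(n_dmrs), function(j) {
        mean(level_b[first[j]:last[j]] - level_a[first[j]:last[j]])
      }, numeric(1)),
      first_idx = first, last_idx = last
    )
  }
  list(cond_a = cond_a, cond_b = cond_b, truth = truth, pos = pos,
       level_a = level_a, level_b = level_b)
}

#' Score called regions against a planted truth set
#'
#' Sensitivity is the fraction of truth regions matched by at least one
#' call; precision the fraction of calls matching at least one truth
#' region (undefined, `NaN`, when there are no calls); F1 their harmonic
#' mean.  A match requires at least 1 bp of overlap and, under the default
#' rule, agreement of the sign of the methylation difference (when both
#' tables carry a `diff` column).  The `"boundary"` rule additionally
#' requires class agreement and both boundaries within `max_boundary_cpg`
#' CpGs of the truth (for planted-region recovery checks).
#'
#' Confidence intervals: exact binomial (Clopper-Pearson) for sensitivity
#' and precision; delta-method normal approximation for F1.
#'
#' @param truth,called region tables with `chrom`, `start`, `end` and
#'   optionally `diff` (DMRs) or `class`/`label` columns.
#' @param rule `"overlap_sign"` (default), `"overlap"`, or `"boundary"`.
#' @param pos CpG coordinate vector (required for `"boundary"`).
#' @param max_boundary_cpg boundary tolerance in CpG index units.
#' @param conf_level confidence level of the intervals.
#' @return A `benchmark_score` list: `sensitivity`, `precision`, `f1`,
#'   their CIs, and the match counts.
#' @export
score_calls <- function(truth, called,
                        rule = c("overlap_sign", "overlap", "boundary"),
                        pos = NULL, max_boundary_cpg = 2L,
                        conf_level = 0.95) {
  rule <- match.arg(rule)
  n_truth <- nrow(truth)
  n_called <- nrow(called)
  called_label <- if ("label" %in% names(called)) called$label
    else if ("class" %in% names(called)) called$class else NULL
  use_sign <- rule == "overlap_sign" &&
    "diff" %in% names(truth) && "diff" %in% names(called)

  idx_of <- function(x) findInterval(x, pos)
  match_pair <- function(ti, ci) {
    if (truth$chrom[ti] != called$chrom[ci]) return(FALSE)
    ov <- min(truth$end[ti], called$end[ci]) -
      max(truth$start[ti], called$start[ci]) + 1
    if (ov < 1) return(FALSE)
    if (use_sign &&
        sign(truth$diff[ti]) != sign(called$diff[ci])) return(FALSE)
    if (rule == "boundary") {
      if (!is.null(called_label) && "class" %in% names(truth) &&
          truth$class[ti] != called_label[ci]) return(FALSE)
      if (abs(idx_of(truth$start[ti]) - idx_of(called$start[ci])) >
            max_boundary_cpg ||
          abs(idx_of(truth$end[ti]) - idx_of(called$end[ci])) >
            max_boundary_cpg) return(FALSE)
    }
    TRUE
  }
  truth_hit <- rep(FALSE, n_truth)
  call_hit <- rep(FALSE, n_called)
  for (ti in seq_len(n_truth)) {
    # restrict to overlapping calls for speed
    cand <- which(called$chrom == truth$chrom[ti] &
                    called$start <= truth$end[ti] &
                    called$end >= truth$start[ti])
    for (ci in cand) {
      if (match_pair(ti, ci)) {
        truth_hit[ti] <- TRUE
        call_hit[ci] <- TRUE
      }
    }
  }
  sens <- if (n_truth > 0) mean(truth_hit) else NaN
  prec <- if (n_called > 0) mean(call_hit) else NaN
  f1 <- if (is.finite(sens) && is.finite(prec) && (sens + prec) > 0) {
    2 * sens * prec / (sens + prec)
  } else {
    NaN
  }
  bci <- function(x, n) {
    if (n == 0) return(c(NaN, NaN))
    as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
  }
  sens_ci <- bci(sum(truth_hit), n_truth)
  prec_ci <- bci(sum(call_hit), n_called)
  f1_ci <- c(NaN, NaN)
  if (is.finite(f1) && n_truth > 0 && n_called > 0) {
    vs <- sens * (1 - sens) / n_truth
    vp <- prec * (1 - prec) / n_called
    dds <- 2 * prec^2 / (sens + prec)^2
    ddp <- 2 * sens^2 / (sens + prec)^2
    se <- sqrt(dds^2 * vs + ddp^2 * vp)
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    f1_ci <- pmin(pmax(c(f1 - zq * se, f1 + zq * se), 0), 1)
  }
  structure(
    list(sensitivity = sens, precision = prec, f1 = f1,
         sensitivity_ci = sens_ci, precision_ci = prec_ci, f1_ci = f1_ci,
         n_truth = n_truth, n_called = n_called,
         matched_truth = sum(truth_hit), matched_calls = sum(call_hit)),
    class = "benchmark_score"
  )
}

#' @export
print.benchmark_score <- function(x, ...) {
  cat(sprintf(
    paste0("benchmark_score: sensitivity %.3f [%.3f, %.3f], ",
           "precision %.3f [%.3f, %.3f], F1 %.3f [%.3f, %.3f]\n",
           "(%d/%d truth matched, %d/%d calls matched)\n"),
    x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
    x$precision, x$precision_ci[1], x$precision_ci[2],
    x$f1, x$f1_ci[1], x$f1_ci[2],
    x$matched_truth, x$n_truth, x$matched_calls, x$n_called
  ))
  invisible(x)
}
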