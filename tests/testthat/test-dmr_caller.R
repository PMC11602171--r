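test_that("paired signed-rank test reproduces the exact small-sample null", {
  a <- c(.9, .8, .85, .95)
  b <- c(.1, .2, .15, .05)
  # 4 informative pairs, all one sign: 2 of the 2^4 sign assignments reach
  # the observed rank sum, so the two-sided exact p is 2/16
  expect_equal(wilcoxon_paired(a, b), 0.125, tolerance = 1e-12)
  expect_equal(wilcoxon_dmr(a, a, method = "paired"), 1)

  set.seed(17)
  for (n in c(6, 12, 25)) {  # exact regime, tie-free
    x <- runif(n)
    y <- x + rnorm(n, 0.05, 0.2)
    ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxon_paired(x, y), ref, tolerance = 1e-9)
  }
  for (n in c(30, 80)) {     # normal regime with continuity correction
    x <- runif(n)
    y <- x + rnorm(n, 0.02, 0.1)
    ref <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE,
                              correct = TRUE)$p.value
    expect_equal(wilcoxon_paired(x, y), ref, tolerance = 1e-9)
  }
  # ties in |d| are handled exactly via the convolution
  x <- c(0, 0, 0, 0, 0, 0)
  y <- c(.2, .2, .2, .2, -.2, .3)
  p <- wilcoxon_paired(x, y)
  expect_true(p > 0 && p <= 1)
})

test_that("rank-sum test matches the reference implementation", {
  set.seed(18)
  for (n in c(4, 10, 20)) {  # exact, tie-free
    x <- runif(n)
    y <- runif(n) + 0.2
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(wilcoxon_ranksum(x, y), ref, tolerance = 1e-9)
  }
  for (n in c(30, 60)) {     # normal approximation
    x <- runif(n)
    y <- runif(n) + 0.1
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(wilcoxon_ranksum(x, y), ref, tolerance = 1e-9)
  }
  # ties switch to the tie-corrected normal approximation, as in the
  # reference
  x <- c(.1, .2, .2, .3, .5)
  y <- c(.2, .4, .5, .6, .7)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))$p.value
  expect_equal(wilcoxon_ranksum(x, y), ref, tolerance = 1e-9)
  # uncovered CpGs are excluded; no valid pairs warns and returns 1
  expect_warning(p <- wilcoxon_dmr(c(NA, NA), c(.1, .2)), "p = 1")
  expect_equal(p, 1)
})

test_that("Benjamini-Hochberg adjustment is the step-up procedure", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.3), 0.3)
  set.seed(19)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(q >= p - 1e-12))
  expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p
})

test_that("neighbouring difference segments group by level proximity", {
  seg <- seg_table(
    seg_row(1000, 1500, 10, 0.32, 0.05),
    seg_row(1600, 2100, 10, 0.38, 0.05)
  )
  out <- group_segments(seg)  # gap 0.06 < 0.10: merged
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_cpg, 20L)
  expect_equal(out$start, 1000L)
  expect_equal(out$end, 2100L)

  seg2 <- seg_table(
    seg_row(1000, 1500, 10, 0.05, 0.05),
    seg_row(1600, 2100, 10, 0.40, 0.05)
  )
  expect_equal(nrow(group_segments(seg2)), 2L)

  one <- seg_table(seg_row(1000, 1500, 10, 0.2, 0.05))
  expect_equal(group_segments(one), one)
})

test_that("the coverage score counts CpGs covered in every sample", {
  pos <- seq(100L, 1000L, by = 100L)  # 10 CpGs
  mk <- function(cov) make_track(pos, rep(0L, 10), cov)
  covs <- rep(list(rep(30L, 10)), 4)
  covs[[2]][3] <- 4L  # below threshold in one replicate
  covs[[4]][7] <- 0L
  cm <- build_condition_matrix(list(mk(covs[[1]]), mk(covs[[2]])),
                               list(mk(covs[[3]]), mk(covs[[4]])))
  e <- cm$chroms[["chr1"]]
  expect_equal(coverage_score(1L, 10L, e), 80)
  expect_equal(coverage_score(1L, 2L, e), 100)
  covs2 <- rep(list(rep(30L, 10)), 4)
  for (k in 1:4) covs2[[k]][c(1, 2, 5, 9)] <- 2L
  cm2 <- build_condition_matrix(list(mk(covs2[[1]]), mk(covs2[[2]])),
                                list(mk(covs2[[3]]), mk(covs2[[4]])))
  expect_equal(coverage_score(1L, 10L, cm2$chroms[["chr1"]]), 60)
})

test_that("retention thresholds and the FDR switch behave as documented", {
  cand <- data.table::data.table(
    chrom = "chr1", start = c(1, 100, 200, 300, 400) * 10L,
    end = c(1, 100, 200, 300, 400) * 10L + 50L,
    n_cpg = c(20L, 20L, 3L, 20L, 20L),
    n_cpg_a = c(20L, 20L, 3L, 20L, 20L),
    n_cpg_b = c(20L, 20L, 3L, 20L, 20L),
    coverage_score = 95,
    mean_a = 0.4, mean_b = 0.4,
    diff = c(0.50, 0.09, 0.50, 0.50, 0.12),
    p = c(0.001, 0.001, 0.001, 0.20, 0.04),
    fdr = c(0.004, 0.004, 0.004, 0.25, 0.08)
  )
  kept <- filter_dmrs(cand)
  expect_equal(kept$start, c(10L, 4000L))  # diff >= .1, n >= 4, p <= .05
  # FDR mode replaces the p criterion: row 5 (p .04, fdr .08) drops out
  kept_q <- filter_dmrs(cand, q_max = 0.05)
  expect_equal(kept_q$start, 10L)
})

test_that("DMR annotation picks the dominant overlapping class per condition", {
  dmr <- data.table::data.table(chrom = "chr1", start = 1000L, end = 1999L,
                                diff = 0.3)
  mkreg <- function(start, end, label) {
    r <- seg_row(start, end, 10, 0.1, 0.02)
    r$label <- label
    r
  }
  out <- annotate_dmrs(dmr, mkreg(1000, 1599, "UMR"),
                       mkreg(1600, 1999, "LMR"))
  expect_equal(out$annotation, "UMRtoLMR")  # 60% vs 40% overlaps
  expect_equal(annotate_dmrs(dmr, NULL, NULL)$annotation, "")
  # PMD overlap below 50% does not qualify
  expect_equal(annotate_dmrs(dmr, NULL, mkreg(1000, 1449, "PMD"))$annotation,
               "")
  expect_equal(annotate_dmrs(dmr, NULL, mkreg(1000, 1500, "PMD"))$annotation,
               "toPMD")
  expect_equal(annotate_dmrs(dmr, mkreg(900, 1200, "DMV"), NULL)$annotation,
               "fromDMV")
})

test_that("difference segmentation recovers planted blocks and stays piecewise constant", {
  set.seed(20)
  n <- 150
  pos <- cumsum(sample(50:150, n, replace = TRUE))
  lvl_a <- rep(0.6, n)
  lvl_b <- lvl_a
  lvl_b[61:110] <- 0.9  # +0.3 over a 50-CpG block
  mk <- function(lvl) {
    cov <- rep(40L, n)
    m <- rbinom(n, cov, lvl)
    make_track(pos, m, cov - m)
  }
  cm <- build_condition_matrix(list(mk(lvl_a)), list(mk(lvl_b)))
  fit <- solve_two_condition(cm)
  seg <- segment_differences(cm, fit = fit)
  # the block may come back as one segment or a few near-level pieces
  # (grouping merges those later); together they cover it
  hit <- seg[seg$mean > 0.2, ]
  expect_gte(nrow(hit), 1L)
  expect_equal(weighted.mean(hit$mean, hit$n_cpg), 0.3, tolerance = 0.07)
  expect_gte(min(hit$start), pos[59])
  expect_lte(max(hit$end), pos[112])
  expect_gte(sum(hit$n_cpg), 46L)
  # per-CpG fused differences are constant within each segment
  bd <- fit$chroms[[1]]$beta_diff
  for (k in seq_len(nrow(seg))) {
    idx <- seg$first_idx[k]:seg$last_idx[k]
    expect_lt(diff(range(bd[idx])), 0.011)
  }
  # identical conditions: all difference levels near zero
  cm0 <- build_condition_matrix(list(mk(lvl_a)), list(mk(lvl_a)))
  seg0 <- segment_differences(cm0)
  expect_lt(max(abs(seg0$level)), 0.05)
})

test_that("swapping the conditions negates differences for matched regions", {
  # the coupled fit re-parameterizes under a label swap (the reference
  # coefficients absorb the difference), so region borders can shift by a
  # few CpGs; the recovered truth set and the per-region statistics of
  # position-matched DMRs are label-symmetric
  set.seed(22)
  sim <- simulate_dmr_benchmark(n_dmrs = 10, n_cpg = 4000, seed = 22)
  f <- call_dmrs(sim$cond_a, sim$cond_b)
  r <- call_dmrs(sim$cond_b, sim$cond_a)
  truth_swapped <- data.table::copy(sim$truth)
  truth_swapped$diff <- -truth_swapped$diff
  expect_equal(score_calls(sim$truth, f$dmrs)$sensitivity,
               score_calls(truth_swapped, r$dmrs)$sensitivity)
  key_f <- paste(f$dmrs$start, f$dmrs$end)
  key_r <- paste(r$dmrs$start, r$dmrs$end)
  shared <- intersect(key_f, key_r)
  expect_gt(length(shared), 0)
  mf <- f$dmrs[match(shared, key_f)]
  mr <- r$dmrs[match(shared, key_r)]
  expect_equal(mf$diff, -mr$diff, tolerance = 1e-12)
  expect_equal(mf$p, mr$p, tolerance = 1e-12)
  expect_equal(mf$coverage_score, mr$coverage_score)
  # every retained DMR satisfies the documented thresholds
  expect_true(all(abs(f$dmrs$diff) >= 0.10))
  expect_true(all(f$dmrs$p <= 0.05))
  expect_true(all(pmin(f$dmrs$n_cpg_a, f$dmrs$n_cpg_b) >= 4))
  expect_true(all(f$dmrs$coverage_score >= 70))
})
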