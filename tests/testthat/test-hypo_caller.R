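# Fixtures are hand-built segment tables; the cascade operates on segment
# statistics alone, so positional data only enter the DMV tests.

test_that("a dip between admissible neighbours becomes an LMR", {
  seg <- seg_table(
    seg_row(1000, 2000, 50, 0.80, 0.05),
    seg_row(2100, 2400, 12, 0.20, 0.05),
    seg_row(2500, 3500, 40, 0.90, 0.05)
  )
  out <- call_hypomethylated_regions(seg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$label, "LMR")
  expect_equal(out$start, 2100L)
  expect_equal(out$end, 2400L)
})

test_that("unmethylated low-variance candidates are reclassified as UMRs", {
  seg <- seg_table(
    seg_row(1000, 2000, 50, 0.80, 0.05),
    seg_row(2100, 2400, 15, 0.05, 0.04),
    seg_row(2500, 3500, 40, 0.90, 0.05)
  )
  out <- call_hypomethylated_regions(seg)
  expect_equal(out$label, "UMR")
})

test_that("small dips between low-methylation flanks are dropped", {
  seg <- seg_table(
    seg_row(1000, 2000, 50, 0.45, 0.05),
    seg_row(2100, 2250, 6, 0.20, 0.05),
    seg_row(2400, 3500, 40, 0.40, 0.05)
  )
  expect_equal(nrow(call_hypomethylated_regions(seg)), 0L)
  # same dip with 10 CpGs (or one methylated flank) is retained
  seg10 <- data.table::copy(seg)
  seg10$n_cpg[2] <- 10L
  expect_equal(call_hypomethylated_regions(seg10)$label, "LMR")
  segm <- data.table::copy(seg)
  segm$mean[3] <- 0.80
  expect_equal(call_hypomethylated_regions(segm)$label, "LMR")
})

test_that("dense unmethylated segments without a clear dip are additional UMRs", {
  # flanks at 0.15: dip 0.07 < 2 x 0.06, so no candidate; density
  # 28 CpGs / 0.8 kb = 35 CpGs/kb and size 800 bp qualify it
  seg <- seg_table(
    seg_row(1000, 2000, 50, 0.15, 0.03),
    seg_row(2100, 2899, 28, 0.08, 0.06),
    seg_row(3000, 4000, 40, 0.15, 0.03)
  )
  out <- call_hypomethylated_regions(seg)
  expect_equal(out$label, "UMR")
  expect_equal(out$start, 2100L)
  # a sparser or smaller segment of interest is not rescued
  sparse <- data.table::copy(seg)
  sparse$n_cpg[2] <- 20L  # 25 CpGs/kb < 30
  expect_equal(nrow(call_hypomethylated_regions(sparse)), 0L)
})

test_that("segments of interest at chromosome ends are never candidates", {
  seg <- seg_table(
    seg_row(1000, 1500, 20, 0.10, 0.05),  # lowest, but no left neighbour
    seg_row(1600, 2600, 40, 0.80, 0.05),
    seg_row(2700, 3700, 40, 0.90, 0.05)
  )
  expect_equal(nrow(call_hypomethylated_regions(seg)), 0L)
})

test_that("flanks further than 5 kb disqualify a candidate", {
  seg <- seg_table(
    seg_row(1000, 2000, 50, 0.80, 0.05),
    seg_row(8000, 8300, 12, 0.20, 0.05),  # left flank 6 kb away
    seg_row(8400, 9400, 40, 0.90, 0.05)
  )
  expect_equal(nrow(call_hypomethylated_regions(seg)), 0L)
})

test_that("unmethylated chains become DMVs that absorb overlapping UMRs", {
  # 35 CpGs spaced 200 bp: a 6.8 kb unmethylated span in a methylated sea
  pos <- c(seq(1000L, 7800L, by = 200L), seq(8400L, 10400L, by = 200L))
  y <- c(rep(0.05, 35), rep(0.8, 11))
  beta <- c(rep(0.04, 15), rep(0.08, 20), rep(0.8, 11))
  seg <- segment_stats(beta_to_segments(beta, pos), y)
  regions <- call_hypomethylated_regions(seg)
  out <- call_dmvs(regions, seg, y, pos)
  dmv <- out[out$label == "DMV"]
  expect_equal(nrow(dmv), 1L)
  expect_equal(dmv$start, 1000L)
  expect_equal(dmv$end, 7800L)
  expect_equal(dmv$n_cpg, 35L)
  expect_lt(dmv$mean, 0.1)
  # nothing else overlaps the DMV
  others <- out[out$label != "DMV"]
  expect_false(any(others$start <= dmv$end & others$end >= dmv$start))
})

test_that("short or gap-broken unmethylated spans are not DMVs", {
  # 3.8 kb span: fails the 5 kb size threshold
  pos <- c(seq(1000L, 4800L, by = 200L), seq(5400L, 7400L, by = 200L))
  y <- c(rep(0.05, 20), rep(0.8, 11))
  beta <- y
  seg <- segment_stats(beta_to_segments(beta, pos), y)
  out <- call_dmvs(call_hypomethylated_regions(seg), seg, y, pos)
  expect_equal(sum(out$label == "DMV"), 0L)

  # two 3.8 kb unmethylated spans split by a 6 kb gap chain separately and
  # each fails the size threshold
  pos2 <- c(seq(1000L, 4800L, by = 200L), seq(10800L, 14600L, by = 200L))
  y2 <- rep(0.05, 40)
  seg2 <- segment_stats(beta_to_segments(rep(0.05, 40), pos2), y2)
  out2 <- call_dmvs(methseg:::empty_regions(), seg2, y2, pos2)
  expect_equal(sum(out2$label == "DMV"), 0L)
})

test_that("LMRs overlapping PMDs are suppressed, UMRs kept", {
  regions <- rbind(
    cbind(seg_row(1000, 1500, 10, 0.3, 0.05), data.table::data.table(label = "LMR")),
    cbind(seg_row(2000, 2500, 10, 0.05, 0.02), data.table::data.table(label = "UMR")),
    cbind(seg_row(9000, 9500, 10, 0.3, 0.05), data.table::data.table(label = "LMR"))
  )
  expect_equal(suppress_in_pmds(regions, NULL), regions)
  pmds <- seg_row(500, 3000, 100, 0.5, 0.2)
  pmds$label <- "PMD"
  out <- suppress_in_pmds(regions, pmds)
  expect_equal(out$label, c("UMR", "LMR"))  # first LMR inside PMD removed
  expect_equal(out$start, c(2000L, 9000L))
  # an abutting but non-overlapping LMR is kept
  pmds2 <- seg_row(9501, 12000, 100, 0.5, 0.2)
  pmds2$label <- "PMD"
  expect_equal(nrow(suppress_in_pmds(regions, pmds2)), 3L)
})

test_that("post-call label constraints hold on a synthetic methylome", {
  set.seed(21)
  plan <- region_plan(n_umr = 8, n_lmr = 8)
  sim <- simulate_methylome(plan, n_cpg = 20000, seed = 21)
  res <- call_regions(sim$tracks)
  reg <- res$regions
  expect_true(all(reg$mean[reg$label %in% c("UMR", "DMV")] < 0.1))
  expect_true(all(reg$mean[reg$label == "LMR"] >= 0 &
                    reg$mean[reg$label == "LMR"] < 0.5))
  # no genomic base carries two labels
  reg <- reg[order(reg$start)]
  if (nrow(reg) > 1) {
    expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
  }
})
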