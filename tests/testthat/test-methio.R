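test_that("bismark coverage rows parse to counts; the percent column is ignored", {
  path <- write_lines_tmp(c(
    "chr1\t10469\t10469\t66.67\t2\t1",
    "chr1\t10471\t10471\t0\t0\t7",
    "chr2\t5000\t5000\t99.99\t12\t0"
  ))
  tr <- read_methylation_table(path)
  expect_s3_class(tr, "methylome_track")
  expect_equal(nrow(tr), 3L)
  row <- tr[tr$chrom == "chr1" & tr$pos == 10469L]
  expect_equal(row$meth, 2L)
  expect_equal(row$unmeth, 1L)

  empty <- read_methylation_table(write_lines_tmp(character()))
  expect_equal(nrow(empty), 0L)
})

test_that("malformed, duplicated and unsorted inputs are reported", {
  bad <- write_lines_tmp(c(
    "chr1\t100\t100\t50\t3\t3",
    "chr1\t200\t200\t50\tNOPE\t3"
  ))
  expect_error(read_methylation_table(bad), "line 2")

  dup <- write_lines_tmp(c(
    "chr1\t100\t100\t50\t3\t3",
    "chr1\t100\t100\t50\t1\t1"
  ))
  expect_error(read_methylation_table(dup), "duplicate")

  unsorted <- write_lines_tmp(c(
    "chr1\t200\t200\t50\t3\t3",
    "chr1\t100\t100\t50\t1\t1"
  ))
  expect_warning(tr <- read_methylation_table(unsorted), "sort")
  expect_equal(tr$pos, c(100L, 200L))
})

test_that("generic dialects round-trip, including 0-based positions", {
  fmt <- list(chrom = 1, pos = 2, meth = 3, unmeth = 4, zero_based = TRUE)
  path <- write_lines_tmp(c("chr1\t99\t4\t6", "chr1\t149\t0\t9"))
  tr <- read_methylation_table(path, format = fmt)
  expect_equal(tr$pos, c(100L, 150L))  # shifted to 1-based on read

  out <- tempfile()
  write_methylation_table(tr, out, format = fmt)
  back <- read_methylation_table(out, format = fmt)
  expect_equal(as.data.frame(back), as.data.frame(tr), ignore_attr = TRUE)

  # meth + cov dialect
  fmt2 <- list(chrom = 1, pos = 2, meth = 3, cov = 4)
  path2 <- write_lines_tmp(c("chr1\t10\t4\t10"))
  tr2 <- read_methylation_table(path2, format = fmt2)
  expect_equal(tr2$unmeth, 6)
  bad <- write_lines_tmp(c("chr1\t10\t11\t10"))
  expect_error(read_methylation_table(bad, format = fmt2), "line 1")

  # bismark round trip preserves counts
  tr3 <- make_track(c(10L, 30L), c(2L, 5L), c(8L, 0L))
  f3 <- tempfile()
  write_methylation_table(tr3, f3)
  expect_equal(as.data.frame(read_methylation_table(f3))[, -1],
               as.data.frame(tr3)[, -1], ignore_attr = TRUE)
})

test_that("coverage filter keeps sites at the threshold and is idempotent", {
  tr <- make_track(pos = c(10L, 20L, 30L, 40L),
                   meth = c(2L, 3L, 1L, 10L),
                   unmeth = c(2L, 2L, 4L, 0L))
  f <- filter_by_coverage(tr)  # default 5
  expect_equal(f$pos, c(20L, 30L, 40L))  # coverage 4 removed, 5 kept
  expect_equal(filter_by_coverage(tr, 1)$pos, tr$pos)
  expect_equal(as.data.frame(filter_by_coverage(f)), as.data.frame(f))

  set.seed(11)
  rt <- make_track(pos = seq(10L, 1000L, by = 10L),
                   meth = rbinom(100, 20, 0.5),
                   unmeth = rbinom(100, 20, 0.5))
  for (mc in c(1L, 5L, 22L)) {
    expect_equal(nrow(filter_by_coverage(rt, mc)),
                 sum(rt$meth + rt$unmeth >= mc))  # brute-force scan
  }
})

test_that("replicate pooling sums counts over the union of sites", {
  r1 <- make_track(pos = c(100L, 200L), meth = c(2L, 1L),
                   unmeth = c(3L, 1L))
  r2 <- make_track(pos = c(100L, 300L), meth = c(4L, 7L),
                   unmeth = c(1L, 3L))
  p <- pool_replicates(list(r1, r2))
  shared <- p[p$pos == 100L]
  expect_equal(shared$meth, 6L)
  expect_equal(shared$meth + shared$unmeth, 10L)
  expect_equal(shared$meth / (shared$meth + shared$unmeth), 0.6)
  # site present in only one replicate keeps that replicate's counts
  expect_equal(p[p$pos == 300L]$meth, 7L)
  expect_equal(p$pos, c(100L, 200L, 300L))
  # count conservation
  expect_equal(sum(p$meth), sum(r1$meth) + sum(r2$meth))
  expect_equal(sum(p$unmeth), sum(r1$unmeth) + sum(r2$unmeth))
  # single replicate is an identity
  expect_equal(as.data.frame(pool_replicates(list(r1)))[, -1],
               as.data.frame(r1)[, -1])
  # chromosome sets differing across replicates warn and take the union
  r3 <- make_track(pos = 50L, meth = 1L, unmeth = 1L, chrom = "chrX")
  expect_warning(pu <- pool_replicates(list(r1, r3)), "union")
  expect_setequal(unique(pu$chrom), c("chr1", "chrX"))
})

test_that("condition matrix aligns samples on the union of CpG positions", {
  a1 <- make_track(pos = c(10L, 20L), meth = c(1L, 2L), unmeth = c(4L, 3L))
  a2 <- make_track(pos = c(30L, 40L), meth = c(5L, 0L), unmeth = c(0L, 5L))
  cm <- build_condition_matrix(list(a1, a2))
  e <- cm$chroms[["chr1"]]
  expect_equal(length(e$pos), 4L)  # disjoint sites: lengths add
  expect_equal(e$cov_a[, 1], c(5, 5, 0, 0))
  expect_equal(e$cov_a[, 2], c(0, 0, 5, 5))
  # coverage 0 implies meth 0
  expect_true(all(e$meth_a[e$cov_a == 0] == 0))

  cm2 <- build_condition_matrix(list(a1, a1))
  expect_equal(length(cm2$chroms[["chr1"]]$pos), 2L)

  # random samples agree with an independent sorted-union oracle, and the
  # alignment is invariant to replicate order
  set.seed(5)
  mk <- function() {
    pos <- sort(sample(1:500, 40))
    make_track(pos, rbinom(40, 20, 0.3), rbinom(40, 20, 0.7))
  }
  t1 <- mk(); t2 <- mk(); t3 <- mk()
  cm3 <- build_condition_matrix(list(t1, t2), list(t3))
  expect_equal(cm3$chroms[["chr1"]]$pos,
               sort(unique(c(t1$pos, t2$pos, t3$pos))))
  cm4 <- build_condition_matrix(list(t2, t1), list(t3))
  expect_equal(rowSums(cm3$chroms[["chr1"]]$cov_a),
               rowSums(cm4$chroms[["chr1"]]$cov_a))
})
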