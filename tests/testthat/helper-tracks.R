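# small fixture builders shared across the suite

make_track <- function(pos, meth, unmeth, chrom = "chr1", sample = "s") {
  methylome_track(rep(chrom, length(pos)), pos, meth, unmeth,
                  sample = sample)
}

write_lines_tmp <- function(lines, ext = ".cov") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a hand-built segment table row (indices must be kept consistent by the
# caller when positional data are involved)
seg_row <- function(start, end, n_cpg, mean, sd, first_idx = 1L,
                    level = mean, chrom = "chr1") {
  data.table::data.table(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    first_idx = as.integer(first_idx),
    last_idx = as.integer(first_idx + n_cpg - 1L),
    n_cpg = as.integer(n_cpg), level = level, mean = mean, sd = sd
  )
}

seg_table <- function(...) {
  rows <- list(...)
  # assign consecutive CpG indices in genomic order
  out <- data.table::rbindlist(rows)
  out <- out[order(out$start)]
  at <- 0L
  for (k in seq_len(nrow(out))) {
    out$first_idx[k] <- at + 1L
    out$last_idx[k] <- at + out$n_cpg[k]
    at <- at + out$n_cpg[k]
  }
  out
}
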