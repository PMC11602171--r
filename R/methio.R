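#' @importFrom data.table data.table as.data.table setattr setorderv fread
#'   fwrite rbindlist copy := .N .SD
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "chrom", "pos", "meth", "unmeth", "start", "end", "n_cpg", "level",
  "label", "first_idx", "last_idx", "N", "."
))

#' Construct a per-CpG methylome track
#'
#' A methylome track stores one record per CpG: chromosome, 1-based position
#' of the C on the plus strand, methylated read count and unmethylated read
#' count.  Positions are unique and strictly increasing within a chromosome.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based CpG positions.
#' @param meth,unmeth non-negative integer read counts.
#' @param sample optional sample identifier.
#' @return A `methylome_track` (a `data.table` with columns `chrom`, `pos`,
#'   `meth`, `unmeth`, sorted by chromosome and position).
#' @export
methylome_track <- function(chrom, pos, meth, unmeth, sample = NA_character_) {
  dt <- data.table(
    chrom = as.character(chrom), pos = as.integer(pos),
    meth = as.integer(meth), unmeth = as.integer(unmeth)
  )
  if (nrow(dt) > 0) {
    if (any(dt$meth < 0) || any(dt$unmeth < 0)) {
      stop("negative read counts are not allowed")
    }
    setorderv(dt, c("chrom", "pos"))
    dup <- dt[, .N, by = c("chrom", "pos")][N > 1]
    if (nrow(dup) > 0) {
      stop(sprintf(
        "duplicate CpG position %s:%d", dup$chrom[1], dup$pos[1]
      ))
    }
  }
  setattr(dt, "sample", sample)
  setattr(dt, "class", c("methylome_track", class(dt)))
  dt
}

#' @export
print.methylome_track <- function(x, ...) {
  cat(sprintf(
    "methylome_track: %d CpGs on %d chromosome(s)%s\n",
    nrow(x), length(unique(x$chrom)),
    if (is.na(attr(x, "sample"))) "" else paste0(" [", attr(x, "sample"), "]")
  ))
  NextMethod()
}

#' Read a per-CpG methylation table
#'
#' Reads either the bismark coverage dialect (chromosome, start, end,
#' percent methylation, count methylated, count unmethylated; 1-based,
#' start == end) or a generic column mapping.  The percent column, when
#' present, is ignored in favour of the counts.
#'
#' @param path path to a (optionally gzipped) TSV file.
#' @param format either the string `"bismark"` or a list describing a
#'   generic dialect with elements `chrom`, `pos`, and either
#'   `meth` + `unmeth` or `meth` + `cov` (column indices), plus
#'   `zero_based = TRUE/FALSE` (default `FALSE`).  Zero-based positions are
#'   shifted by +1 on read.
#' @param sample optional sample identifier attached to the track.
#' @return A [methylome_track()].  Rows are sorted per chromosome; a file
#'   with non-monotone positions is sorted with a warning; a duplicated
#'   position on a chromosome is an error, as is a malformed row (the error
#'   names the offending line).
#' @export
read_methylation_table <- function(path, format = "bismark", sample = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(sample)) sample <- basename(path)
  raw <- if (file.size(path) == 0) {
    data.table()
  } else {
    fread(path, header = FALSE, colClasses = "character", fill = TRUE)
  }
  if (nrow(raw) == 0) {
    return(methylome_track(character(), integer(), integer(), integer(),
                           sample = sample))
  }
  if (identical(format, "bismark")) {
    cols <- list(chrom = 1L, pos = 2L, meth = 5L, unmeth = 6L)
    zero_based <- FALSE
    need <- 6L
  } else {
    stopifnot(is.list(format), all(c("chrom", "pos", "meth") %in% names(format)))
    cols <- format
    zero_based <- isTRUE(format$zero_based)
    need <- max(unlist(format[names(format) %in%
                                c("chrom", "pos", "meth", "unmeth", "cov")]))
  }
  if (ncol(raw) < need) {
    stop(sprintf("expected at least %d columns, found %d", need, ncol(raw)))
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, bad[1], raw[[col]][bad[1]]))
    }
    v
  }
  chromv <- raw[[cols$chrom]]
  posv <- num(cols$pos, "position") + if (zero_based) 1L else 0L
  methv <- num(cols$meth, "methylated-count")
  if (!is.null(cols$unmeth)) {
    unmethv <- num(cols$unmeth, "unmethylated-count")
  } else {
    covv <- num(cols$cov, "coverage")
    if (any(covv < methv)) {
      stop(sprintf("coverage smaller than methylated count at line %d",
                   which(covv < methv)[1]))
    }
    unmethv <- covv - methv
  }
  # detect unsorted input before methylome_track() silently orders it
  o <- order(chromv, posv)
  if (is.unsorted(o)) {
    warning("positions not monotone within chromosome; sorting")
  }
  methylome_track(chromv, posv, methv, unmethv, sample = sample)
}

#' Write a per-CpG methylation table
#'
#' @param track a [methylome_track()].
#' @param path output path.
#' @param format `"bismark"` (chrom, start, end, percent, meth, unmeth) or a
#'   generic list as in [read_methylation_table()] (columns written in the
#'   order chrom, pos, meth, unmeth, positions shifted back by -1 when
#'   `zero_based = TRUE`).
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(track, path, format = "bismark") {
  if (identical(format, "bismark")) {
    cov <- track$meth + track$unmeth
    out <- data.table(
      chrom = track$chrom, start = track$pos, end = track$pos,
      pct = ifelse(cov > 0, 100 * track$meth / cov, 0),
      meth = track$meth, unmeth = track$unmeth
    )
  } else {
    shift <- if (isTRUE(format$zero_based)) 1L else 0L
    out <- data.table(
      chrom = track$chrom, pos = track$pos - shift,
      meth = track$meth, unmeth = track$unmeth
    )
  }
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Filter CpG sites by minimum coverage
#'
#' Keeps only sites covered by at least `min_cov` reads (default 5, the
#' usual minimum for confident per-CpG methylation estimates).
#'
#' @param track a [methylome_track()].
#' @param min_cov minimum total read count (`meth + unmeth`), >= 1.
#' @return The filtered track, order preserved.
#' @export
filter_by_coverage <- function(track, min_cov = 5L) {
  stopifnot(min_cov >= 1)
  keep <- (track$meth + track$unmeth) >= min_cov
  out <- track[keep]
  setattr(out, "sample", attr(track, "sample"))
  setattr(out, "class", class(track))
  out
}

#' Pool replicate tracks into one per-condition track
#'
#' Replicates are integrated by adding the methylated and unmethylated
#' counts at each CpG, recomputing coverages; the site set is the union of
#' the replicates' sites.
#'
#' @param tracks a list of [methylome_track()] objects (>= 1).
#' @param sample identifier for the pooled track.
#' @return A pooled [methylome_track()].
#' @export
pool_replicates <- function(tracks, sample = "pooled") {
  stopifnot(length(tracks) >= 1)
  if (length(tracks) == 1) {
    out <- data.table::copy(tracks[[1]])
    setattr(out, "sample", sample)
    return(out)
  }
  chromsets <- lapply(tracks, function(t) unique(t$chrom))
  if (length(unique(lapply(chromsets, sort))) > 1) {
    warning("chromosome sets differ across replicates; taking the union")
  }
  all <- rbindlist(lapply(tracks, as.data.table))
  pooled <- all[, list(meth = sum(meth), unmeth = sum(unmeth)),
                by = c("chrom", "pos")]
  methylome_track(pooled$chrom, pooled$pos, pooled$meth, pooled$unmeth,
                  sample = sample)
}

#' Align samples of one or two conditions on the union of CpG sites
#'
#' Builds, per chromosome, aligned per-sample vectors of methylated counts
#' and coverages over the union of CpG positions across all samples.  A
#' site absent from a sample gets coverage 0 (and therefore weight 0 in the
#' model); missing data are never imputed.
#'
#' @param cond_a list of [methylome_track()] replicates of the reference
#'   condition (non-empty).
#' @param cond_b optional list of replicates of the second condition.
#' @param labels length-2 character vector of condition labels.
#' @return A `condition_matrix`: a list with `labels`, `n_reps`, and
#'   `chroms`, the latter a named list holding for each chromosome `pos`
#'   plus matrices `meth_a`, `cov_a` (sites x replicates) and, with two
#'   conditions, `meth_b`, `cov_b`.
#' @export
build_condition_matrix <- function(cond_a, cond_b = NULL,
                                   labels = c("a", "b")) {
  stopifnot(length(cond_a) >= 1)
  two <- !is.null(cond_b) && length(cond_b) > 0
  all_tracks <- c(cond_a, if (two) cond_b else list())
  chroms <- sort(unique(unlist(lapply(all_tracks, function(t) unique(t$chrom)))))
  align <- function(tracks, chr, upos) {
    m <- matrix(0L, length(upos), length(tracks))
    cv <- matrix(0L, length(upos), length(tracks))
    for (j in seq_along(tracks)) {
      t <- tracks[[j]][chrom == chr]
      idx <- match(t$pos, upos)
      m[idx, j] <- t$meth
      cv[idx, j] <- t$meth + t$unmeth
    }
    list(meth = m, cov = cv)
  }
  out <- list(
    labels = if (two) labels else labels[1],
    n_reps = c(length(cond_a), if (two) length(cond_b) else 0L),
    chroms = list()
  )
  for (chr in chroms) {
    upos <- sort(unique(unlist(lapply(
      all_tracks, function(t) t$pos[t$chrom == chr]
    ))))
    aa <- align(cond_a, chr, upos)
    entry <- list(pos = upos, meth_a = aa$meth, cov_a = aa$cov)
    if (two) {
      bb <- align(cond_b, chr, upos)
      entry$meth_b <- bb$meth
      entry$cov_b <- bb$cov
    }
    out$chroms[[chr]] <- entry
  }
  class(out) <- "condition_matrix"
  out
}

#' @export
print.condition_matrix <- function(x, ...) {
  n <- sum(vapply(x$chroms, function(e) length(e$pos), integer(1)))
  cat(sprintf(
    "condition_matrix: %d CpGs, %d chromosome(s), conditions: %s (reps %s)\n",
    n, length(x$chroms), paste(x$labels, collapse = " vs "),
    paste(x$n_reps[x$n_reps > 0], collapse = "/")
  ))
  invisible(x)
}

# Pooled fractions and coverages per chromosome; y is NA where coverage 0.
pooled_signal <- function(entry, which = c("a", "b")) {
  which <- match.arg(which)
  m <- entry[[paste0("meth_", which)]]
  cv <- entry[[paste0("cov_", which)]]
  cov <- rowSums(cv)
  y <- ifelse(cov > 0, rowSums(m) / cov, NA_real_)
  list(y = y, cov = cov)
}
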