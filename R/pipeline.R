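#' Call UMRs, LMRs, DMVs and PMDs for one condition
#'
#' The in-memory single-condition pipeline: coverage-filter each replicate,
#' pool replicates, fit the methylation-scale fused lasso
#' (`lambda2 = 25`), segment with 500 bp gap splitting, run the
#' hypomethylated-region cascade and the DMV chaining, then build the
#' variability track, fit the variance-scale fused lasso
#' (`lambda2 = 1000`) split at UMRs/DMVs, call PMDs and finally suppress
#' LMRs inside PMDs.
#'
#' @param tracks list of [methylome_track()] replicates.
#' @param min_cov minimum per-site coverage (default 5).
#' @param lambda2 methylation-scale fusion strength (default 25).
#' @param gap_bp methylation-scale gap split (default 500).
#' @param hypo a [hypo_params()] list.
#' @param pmd a [pmd_params()] list.
#' @return A list with `regions` (UMR/LMR/DMV table), `pmds`, `segments`
#'   (the methylation-scale segmentation) and `pooled` (the pooled track).
#' @export
call_regions <- function(tracks, min_cov = 5L, lambda2 = 25,
                         gap_bp = 500L, hypo = hypo_params(),
                         pmd = pmd_params()) {
  stopifnot(length(tracks) >= 1)
  tracks <- lapply(tracks, filter_by_coverage, min_cov = min_cov)
  pooled <- pool_replicates(tracks)
  if (nrow(pooled) == 0) {
    warning("no CpG passes the coverage filter; returning empty calls")
    return(list(regions = empty_regions(), pmds = empty_regions(),
                segments = empty_segments(), pooled = pooled))
  }
  regions <- list()
  pmds <- list()
  segments <- list()
  for (chr in unique(pooled$chrom)) {
    sub <- pooled[chrom == chr]
    pos <- sub$pos
    cov <- sub$meth + sub$unmeth
    y <- sub$meth / cov
    fit <- solve_fused_lasso_1d(y, cov, lambda2)
    seg <- segment_stats(
      beta_to_segments(fit$beta, pos, chrom = chr, gap_bp = gap_bp), y
    )
    reg <- call_hypomethylated_regions(seg, hypo)
    reg <- call_dmvs(reg, seg, y, pos, hypo)
    vt <- compute_variance_track(y, pos, cov, pmd$window_cpgs)
    pm <- call_pmds(vt, y, reg, pmd, chrom = chr)
    reg <- suppress_in_pmds(reg, pm)
    regions[[chr]] <- reg
    pmds[[chr]] <- pm
    segments[[chr]] <- seg
  }
  list(regions = rbindlist(regions), pmds = rbindlist(pmds),
       segments = rbindlist(segments), pooled = pooled)
}

#' Call DMRs between two conditions
#'
#' The in-memory two-condition pipeline: coverage-filter, align both
#' conditions on the union of CpGs, run the coupled fused-lasso fit,
#' segment the difference coefficients, group neighbouring segments whose
#' difference levels are within `d`, discard spans with a CpG coverage
#' score below `r_min`, test each remaining span with the Wilcoxon test on
#' pooled per-CpG fractions, adjust genome-wide with Benjamini-Hochberg,
#' apply the retention thresholds and annotate against per-condition
#' region calls when provided.
#'
#' @param cond_a,cond_b lists of replicate [methylome_track()]s (reference
#'   condition first).
#' @param min_cov minimum per-site coverage.
#' @param lambda2 fusion strength of the difference fit.
#' @param d minimum methylation difference (also the grouping threshold).
#' @param n_min minimum per-condition covered-CpG count.
#' @param p_max p-value ceiling.
#' @param q_max optional FDR ceiling replacing `p_max`.
#' @param r_min minimum CpG coverage score (percent).
#' @param test `"ranksum"` or `"paired"` Wilcoxon variant.
#' @param regions_a,regions_b optional per-condition region tables
#'   (UMR/LMR/DMV and PMDs together) used for annotation.
#' @return A list with `dmrs` (retained DMR table) and `candidates` (all
#'   scored spans after the coverage filter, with `p` and `fdr`).
#' @export
call_dmrs <- function(cond_a, cond_b, min_cov = 5L, lambda2 = 25,
                      d = 0.10, n_min = 4L, p_max = 0.05, q_max = NULL,
                      r_min = 70, test = c("ranksum", "paired"),
                      regions_a = NULL, regions_b = NULL) {
  test <- match.arg(test)
  if (length(cond_a) == 0 || length(cond_b) == 0) {
    stop("both conditions need replicates; use call_regions for one condition")
  }
  cond_a <- lapply(cond_a, filter_by_coverage, min_cov = min_cov)
  cond_b <- lapply(cond_b, filter_by_coverage, min_cov = min_cov)
  cmat <- build_condition_matrix(cond_a, cond_b)
  fit <- solve_two_condition(cmat, lambda2 = lambda2)

  spans <- list()
  for (chr in names(cmat$chroms)) {
    entry <- cmat$chroms[[chr]]
    dvec <- condition_differences(entry)
    seg <- segment_stats(
      beta_to_segments(fit$chroms[[chr]]$beta_diff, entry$pos,
                       chrom = chr, gap_bp = 500L),
      dvec
    )
    grp <- group_segments(seg, d = d, diffs = dvec, pos = entry$pos)
    if (nrow(grp) == 0) next
    sa <- pooled_signal(entry, "a")
    sb <- pooled_signal(entry, "b")
    rows <- lapply(seq_len(nrow(grp)), function(k) {
      idx <- grp$first_idx[k]:grp$last_idx[k]
      ya <- sa$y[idx]
      yb <- sb$y[idx]
      score <- coverage_score(grp$first_idx[k], grp$last_idx[k], entry,
                              min_cov = min_cov)
      ma <- mean(ya, na.rm = TRUE)
      mb <- mean(yb, na.rm = TRUE)
      data.table(
        chrom = chr, start = grp$start[k], end = grp$end[k],
        n_cpg = length(idx),
        n_cpg_a = sum(!is.na(ya)), n_cpg_b = sum(!is.na(yb)),
        coverage_score = score,
        mean_a = ma, mean_b = mb, diff = mb - ma,
        p = NA_real_, fdr = NA_real_
      )
    })
    chunk <- rbindlist(rows)
    keep <- chunk$coverage_score >= r_min
    chunk <- chunk[keep]
    grp <- grp[keep]
    if (nrow(chunk) == 0) next
    chunk$p <- vapply(seq_len(nrow(grp)), function(k) {
      idx <- grp$first_idx[k]:grp$last_idx[k]
      suppressWarnings(wilcoxon_dmr(sa$y[idx], sb$y[idx], method = test))
    }, numeric(1))
    spans[[chr]] <- chunk
  }
  candidates <- if (length(spans) > 0) rbindlist(spans) else
    data.table(chrom = character(), start = integer(), end = integer(),
               n_cpg = integer(), n_cpg_a = integer(), n_cpg_b = integer(),
               coverage_score = numeric(), mean_a = numeric(),
               mean_b = numeric(), diff = numeric(), p = numeric(),
               fdr = numeric())
  if (nrow(candidates) > 0) candidates$fdr <- adjust_fdr(candidates$p)
  dmrs <- filter_dmrs(candidates, n_min = n_min, d = d, p_max = p_max,
                      q_max = q_max)
  dmrs <- annotate_dmrs(dmrs, regions_a, regions_b)
  list(dmrs = dmrs, candidates = candidates)
}

#' Assemble a run configuration
#'
#' @param samples data.frame sample sheet with columns `sample`,
#'   `condition`, `replicate`, `path` and optionally `format` (defaults to
#'   bismark coverage).
#' @param output_dir output directory (created if needed).
#' @param min_cov,min_cpg,pmd_max_mean,min_diff,min_score,max_p,max_q the
#'   thresholds mirrored by the command-line flags `-c`, `-n`, `-m`, `-d`,
#'   `-r`, `-p`, `-q`.
#' @param lambda2_meth,lambda2_var fusion strengths of the
#'   methylation-scale and variance-scale fits.
#' @param test Wilcoxon variant for DMR testing.
#' @param seed RNG seed recorded in the manifest (the pipelines themselves
#'   are deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(samples, output_dir = ".", min_cov = 5L,
                       min_cpg = 4L, pmd_max_mean = 0.70, min_diff = 0.10,
                       min_score = 70, max_p = 0.05, max_q = NULL,
                       lambda2_meth = 25, lambda2_var = 1000,
                       test = c("ranksum", "paired"), seed = 1L) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("sample", "condition", "path") %in% names(samples)))
  if (is.null(samples$format)) samples$format <- "bismark"
  stopifnot(min_cov >= 1, min_cpg >= 1, pmd_max_mean > 0, pmd_max_mean <= 1,
            min_diff >= 0, min_diff <= 1, min_score >= 0, min_score <= 100,
            max_p >= 0, max_p <= 1, lambda2_meth > 0, lambda2_var > 0)
  structure(
    list(samples = samples, output_dir = output_dir, min_cov = min_cov,
         min_cpg = min_cpg, pmd_max_mean = pmd_max_mean,
         min_diff = min_diff, min_score = min_score, max_p = max_p,
         max_q = max_q, lambda2_meth = lambda2_meth,
         lambda2_var = lambda2_var, test = match.arg(test), seed = seed),
    class = "run_config"
  )
}

read_config_tracks <- function(config, condition) {
  sheet <- config$samples[config$samples$condition == condition, ,
                          drop = FALSE]
  if (nrow(sheet) == 0) stop("no samples for condition '", condition, "'")
  missing <- sheet$path[!file.exists(sheet$path)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(sheet)), function(i) {
    fmt <- sheet$format[[i]]
    read_methylation_table(sheet$path[i], format = fmt,
                           sample = sheet$sample[i])
  })
}

config_params <- function(config) {
  list(hypo = hypo_params(min_cpg = config$min_cpg),
       pmd = pmd_params(lambda2 = config$lambda2_var,
                        min_cpg = config$min_cpg,
                        max_mean = config$pmd_max_mean))
}

#' Run the single-condition pipeline from a configuration
#'
#' Reads each condition's replicates, calls UMRs/LMRs/DMVs and PMDs, and
#' writes per-condition TSV region files (with BED mirrors), a QC plot set
#' and a JSON run manifest to the output directory.
#'
#' @param config a [run_config()].
#' @param conditions conditions to process (default: all in the sheet).
#' @param plots create QC plots (default TRUE).
#' @return Invisibly, a named list per condition with the region tables
#'   and the written file paths.
#' @export
run_single_condition <- function(config, conditions = NULL, plots = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(conditions)) conditions <- unique(config$samples$condition)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  pars <- config_params(config)
  out <- list()
  for (cond in conditions) {
    tracks <- read_config_tracks(config, cond)
    res <- call_regions(tracks, min_cov = config$min_cov,
                        lambda2 = config$lambda2_meth,
                        hypo = pars$hypo, pmd = pars$pmd)
    files <- c(
      write_regions(res$regions, file.path(
        config$output_dir, paste0(cond, "_lmr_umr_dmv"))),
      write_regions(res$pmds, file.path(
        config$output_dir, paste0(cond, "_pmd")))
    )
    if (plots) {
      files <- c(files, qc_plots(
        tracks = list(res$pooled), segments = res$segments,
        dir = config$output_dir, prefix = cond
      ))
    }
    counts <- table(factor(res$regions$label,
                           levels = c("UMR", "LMR", "DMV")))
    message(sprintf(
      "[%s] %d UMRs, %d LMRs, %d DMVs, %d PMDs",
      cond, counts["UMR"], counts["LMR"], counts["DMV"], nrow(res$pmds)
    ))
    write_manifest(config, file.path(
      config$output_dir, paste0(cond, "_manifest.json")),
      counts = c(as.list(counts), PMD = nrow(res$pmds)),
      condition = cond)
    out[[cond]] <- list(regions = res$regions, pmds = res$pmds,
                        files = files)
  }
  invisible(out)
}

#' Run the two-condition DMR pipeline from a configuration
#'
#' Requires exactly two conditions in the sample sheet (the first in sheet
#' order is the reference).  Region calls for both conditions are computed
#' first so DMRs can be annotated with their class transitions; the DMR
#' table is then written as TSV (plus BED mirror) with a JSON manifest.
#'
#' @param config a [run_config()].
#' @param annotate call per-condition regions first and annotate DMRs
#'   (default TRUE).
#' @return Invisibly, a list with `dmrs`, `candidates` and written paths.
#' @export
run_dmr <- function(config, annotate = TRUE) {
  stopifnot(inherits(config, "run_config"))
  conds <- unique(config$samples$condition)
  if (length(conds) != 2) {
    stop("DMR calling needs exactly two conditions (got ",
         length(conds), "); use run_single_condition otherwise")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  tracks_a <- read_config_tracks(config, conds[1])
  tracks_b <- read_config_tracks(config, conds[2])
  regions_a <- regions_b <- NULL
  if (annotate) {
    pars <- config_params(config)
    ra <- call_regions(tracks_a, min_cov = config$min_cov,
                       lambda2 = config$lambda2_meth,
                       hypo = pars$hypo, pmd = pars$pmd)
    rb <- call_regions(tracks_b, min_cov = config$min_cov,
                       lambda2 = config$lambda2_meth,
                       hypo = pars$hypo, pmd = pars$pmd)
    regions_a <- rbindlist(list(ra$regions, ra$pmds), fill = TRUE)
    regions_b <- rbindlist(list(rb$regions, rb$pmds), fill = TRUE)
  }
  res <- call_dmrs(
    tracks_a, tracks_b, min_cov = config$min_cov,
    lambda2 = config$lambda2_meth, d = config$min_diff,
    n_min = config$min_cpg, p_max = config$max_p, q_max = config$max_q,
    r_min = config$min_score, test = config$test,
    regions_a = regions_a, regions_b = regions_b
  )
  files <- write_dmrs(res$dmrs, file.path(config$output_dir, "dmrs"))
  message(sprintf("%d DMRs retained (of %d candidate spans)",
                  nrow(res$dmrs), nrow(res$candidates)))
  write_manifest(config, file.path(config$output_dir, "dmr_manifest.json"),
                 counts = list(DMR = nrow(res$dmrs)),
                 condition = paste(conds, collapse = "_vs_"))
  invisible(list(dmrs = res$dmrs, candidates = res$candidates,
                 files = files))
}

#' Write a region table as TSV and BED
#'
#' The TSV columns are chromosome, start, end (1-based inclusive), number
#' of CpGs, mean methylation, standard deviation and annotation.  The BED
#' mirror converts to 0-based half-open coordinates (start - 1) with the
#' annotation as the name field.
#'
#' @param regions region table with a `label` column.
#' @param stem output path without extension.
#' @return The written paths.
#' @export
write_regions <- function(regions, stem) {
  tsv <- paste0(stem, ".tsv")
  bed <- paste0(stem, ".bed")
  out <- data.table(
    chromosome = regions$chrom, start = regions$start, end = regions$end,
    n_cpg = regions$n_cpg, mean_methylation = round(regions$mean, 4),
    standard_deviation = round(regions$sd, 4), annotation = regions$label
  )
  fwrite(out, tsv, sep = "\t")
  fwrite(data.table(regions$chrom, regions$start - 1L, regions$end,
                    regions$label),
         bed, sep = "\t", col.names = FALSE)
  c(tsv, bed)
}

#' Write a DMR table as TSV and BED
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param stem output path without extension.
#' @return The written paths.
#' @export
write_dmrs <- function(dmrs, stem) {
  tsv <- paste0(stem, ".tsv")
  bed <- paste0(stem, ".bed")
  out <- data.table(
    chromosome = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    n_cpg_a = dmrs$n_cpg_a, n_cpg_b = dmrs$n_cpg_b,
    coverage_score = round(dmrs$coverage_score, 2),
    mean_a = round(dmrs$mean_a, 4), mean_b = round(dmrs$mean_b, 4),
    mean_difference = round(dmrs$diff, 4),
    p_value = dmrs$p, fdr = dmrs$fdr, annotation = dmrs$annotation
  )
  fwrite(out, tsv, sep = "\t")
  fwrite(data.table(dmrs$chrom, dmrs$start - 1L, dmrs$end,
                    ifelse(dmrs$annotation == "", ".", dmrs$annotation),
                    round(dmrs$diff, 4)),
         bed, sep = "\t", col.names = FALSE)
  c(tsv, bed)
}

write_manifest <- function(config, path, counts, condition) {
  sheet <- config$samples[config$samples$condition %in%
                            strsplit(condition, "_vs_")[[1]] |
                            config$samples$condition == condition, ,
                          drop = FALSE]
  hashes <- tryCatch(
    as.list(tools::md5sum(sheet$path[file.exists(sheet$path)])),
    error = function(e) list()
  )
  manifest <- list(
    condition = condition,
    parameters = config[setdiff(names(config), c("samples", "output_dir"))],
    inputs = hashes,
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Quality-control plots
#'
#' Writes a read-depth histogram and a CpG methylation histogram for the
#' (pooled) tracks, a segment mean-versus-SD scatter (the PMD diagnostic)
#' when segments are given, and a condition-versus-condition DMR scatter
#' when DMRs are given.  Empty inputs skip the corresponding plot with a
#' message.
#'
#' @param tracks list of [methylome_track()]s.
#' @param segments optional segment table with `mean` and `sd`.
#' @param dmrs optional DMR table with `mean_a` and `mean_b`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return The created file paths, invisibly.
#' @export
qc_plots <- function(tracks, segments = NULL, dmrs = NULL, dir = ".",
                     prefix = "qc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  all <- rbindlist(lapply(tracks, as.data.table))
  if (nrow(all) > 0) {
    cov <- all$meth + all$unmeth
    f <- file.path(dir, paste0(prefix, "_coverage_hist.png"))
    grDevices::png(f, width = 600, height = 450)
    graphics::hist(pmin(cov, stats::quantile(cov, 0.995)), breaks = 50,
                   main = "Read depth per CpG", xlab = "coverage",
                   col = "grey70", border = NA)
    grDevices::dev.off()
    files <- c(files, f)
    f <- file.path(dir, paste0(prefix, "_methylation_hist.png"))
    grDevices::png(f, width = 600, height = 450)
    graphics::hist(all$meth / pmax(cov, 1), breaks = 50,
                   main = "CpG methylation", xlab = "methylated fraction",
                   col = "grey70", border = NA)
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (!is.null(segments) && nrow(segments) > 0) {
    f <- file.path(dir, paste0(prefix, "_segment_mean_sd.png"))
    grDevices::png(f, width = 600, height = 450)
    graphics::plot(segments$mean, segments$sd, pch = 16, cex = 0.4,
                   col = grDevices::rgb(0, 0, 0, 0.3),
                   xlab = "segment mean methylation",
                   ylab = "segment SD", main = "PMD diagnostic")
    graphics::abline(v = 0.7, h = 0.15, lty = 2, col = "red")
    grDevices::dev.off()
    files <- c(files, f)
  } else if (!is.null(segments)) {
    message("no segments; skipping mean-vs-SD scatter")
  }
  if (!is.null(dmrs) && nrow(dmrs) > 0) {
    f <- file.path(dir, paste0(prefix, "_dmr_scatter.png"))
    grDevices::png(f, width = 600, height = 450)
    graphics::plot(dmrs$mean_a, dmrs$mean_b, pch = 16, cex = 0.5,
                   col = grDevices::rgb(0.8, 0.2, 0.2, 0.5),
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "mean methylation (reference)",
                   ylab = "mean methylation (condition)",
                   main = "DMR methylation")
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
    files <- c(files, f)
  } else if (!is.null(dmrs)) {
    message("no DMRs; skipping condition-vs-condition scatter")
  }
  invisible(files)
}
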