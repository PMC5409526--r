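#' Quality-control thresholds
#'
#' Negative reporting in a clinical pipeline is only safe when the data were
#' good enough that a real CNV would have been seen. Samples whose best
#' correlation with any other sample is low, and targets with low coverage
#' across the batch, are flagged (never silently dropped).
#'
#' @param min_correlation Minimum acceptable max correlation per sample
#'   (default 0.98).
#' @param min_coverage Minimum acceptable median per-target count
#'   (default 100).
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_correlation = 0.98, min_coverage = 100) {
  if (!(min_correlation > 0 && min_correlation <= 1)) {
    stop("min_correlation must be in (0, 1]")
  }
  if (min_coverage < 0) stop("min_coverage must be >= 0")
  structure(list(min_correlation = min_correlation,
                 min_coverage = min_coverage), class = "qc_thresholds")
}

#' Flag samples whose reference correlation is below threshold
#'
#' @param selections List of `reference_selection` objects, one per sample.
#' @param thresholds A `qc_thresholds`.
#' @return data.frame: sample, max_correlation, n_comp, status (pass/fail).
#' @export
flag_samples <- function(selections, thresholds) {
  out <- do.call(rbind, lapply(selections, function(s) {
    data.frame(sample = s$test_id,
               max_correlation = s$max_correlation,
               n_comp = s$n_comp,
               status = if (s$max_correlation >= thresholds$min_correlation)
                 "pass" else "fail",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Flag targets whose median coverage is below threshold
#'
#' The median across samples is the even-size mean-of-central-pair median; a
#' target passes when its median equals the threshold.
#'
#' @param m A `coverage_matrix`.
#' @param thresholds A `qc_thresholds`.
#' @return data.frame: chrom, start, end, gene, median_count, status.
#' @export
flag_targets <- function(m, thresholds) {
  med <- apply(m$counts, 1, stats::median)
  data.frame(chrom = m$targets$chrom, start = m$targets$start,
             end = m$targets$end, gene = m$targets$gene,
             median_count = med,
             status = ifelse(med >= thresholds$min_coverage, "pass", "fail"),
             stringsAsFactors = FALSE)
}

#' Full QC report for a batch
#'
#' @param m A `coverage_matrix`.
#' @param selections List of `reference_selection`s (one per sample); if
#'   NULL they are computed.
#' @param thresholds A `qc_thresholds`.
#' @param max_refs Maximum reference samples when computing selections.
#' @return List of class `qc_report` with data.frames `samples`, `targets`.
#' @export
qc_report <- function(m, selections = NULL, thresholds = qc_thresholds(),
                      max_refs = 10L) {
  if (is.null(selections)) {
    selections <- lapply(colnames(m$counts), function(id)
      select_reference(m, id, max_refs = max_refs))
  }
  structure(list(samples = flag_samples(selections, thresholds),
                 targets = flag_targets(m, thresholds)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", sum(x$samples$status == "fail"), "of",
      nrow(x$samples), "samples flagged;",
      sum(x$targets$status == "fail"), "of", nrow(x$targets),
      "targets flagged\n")
  invisible(x)
}

#' Write the QC report to TSV files
#'
#' @param report A `qc_report`.
#' @param sample_path,target_path Output paths.
#' @return Invisibly, c(sample_path, target_path).
#' @export
write_qc <- function(report, sample_path, target_path) {
  utils::write.table(report$samples, sample_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$targets, target_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(sample_path, target_path))
}
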