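.CALL_COLUMNS <- c("sample", "correlation", "n_comp", "cnv_type", "n_exons",
                   "chrom", "start", "end", "gene", "custom_first",
                   "custom_last", "bf", "reads_expected", "reads_observed",
                   "reads_ratio")

#' Write CNV calls to a TSV file
#'
#' One row per call; a run with no calls writes the header only, so a negative
#' result is still an explicit, parseable output.
#'
#' @param calls data.frame of calls (as in `cnv_fit$calls`), possibly 0 rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines(paste(.CALL_COLUMNS, collapse = "\t"), path)
    return(invisible(path))
  }
  utils::write.table(calls[, .CALL_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a calls TSV written by [write_calls()]
#'
#' @param path Path to the calls TSV.
#' @return data.frame of calls (0 rows for a header-only file).
#' @export
read_calls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

## 95% pointwise interval for the observed/expected ratio under CN2, from the
## fitted beta-binomial (normal approximation on the count scale; accurate at
## panel depths of hundreds of reads and above).
ratio_interval <- function(n, fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  mu <- fit$mu
  v <- n * mu * (1 - mu) * (1 + pmax(n - 1, 0) * fit$phi)
  lo <- (n * mu - z * sqrt(v)) / (n * mu)
  hi <- (n * mu + z * sqrt(v)) / (n * mu)
  cbind(lo = pmax(lo, 0), hi = hi)
}

#' Plot a CNV fit: coverage and observed/expected ratio
#'
#' Two stacked panels in the style of clinical CNV review plots: the top
#' panel shows log-normalised coverage (log of count over sample total) of
#' the test sample (blue) against each chosen reference sample (grey); the
#' bottom panel shows the per-target ratio of observed to expected coverage
#' with a pointwise 95% interval from the fitted beta-binomial, with called
#' targets highlighted in red.
#'
#' @param x A `cnv_fit`.
#' @param m The `coverage_matrix` the fit was produced from.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @method plot cnv_fit
#' @export
plot.cnv_fit <- function(x, m, ...) {
  if (missing(m)) stop("plot.cnv_fit needs the coverage_matrix the call was made from")
  sel <- x$selection
  test <- x$test_counts
  idx <- seq_along(test)
  lognorm <- function(v) log(pmax(v, 0.5) / sum(v))
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))

  ref_cols <- sel$chosen
  yl <- range(vapply(c(sel$test_id, ref_cols), function(id)
    range(lognorm(m$counts[, id])), numeric(2)))
  graphics::plot(idx, lognorm(test), type = "n", ylim = yl,
                 xlab = "", ylab = "log normalised coverage",
                 main = sprintf("%s (r = %.4f, %d refs)", sel$test_id,
                                sel$max_correlation, sel$n_comp))
  for (id in ref_cols) {
    graphics::lines(idx, lognorm(m$counts[, id]), col = "grey70")
  }
  graphics::lines(idx, lognorm(test), col = "blue", lwd = 2)

  n <- test + x$ref_counts
  ratio <- residuals(x)
  band <- ratio_interval(n, x$fit)
  called <- rep(FALSE, length(idx))
  if (nrow(x$calls) > 0L) {
    for (k in seq_len(nrow(x$calls))) {
      called[x$calls$first_target[k]:x$calls$last_target[k]] <- TRUE
    }
  }
  graphics::plot(idx, ratio, type = "n",
                 ylim = range(c(ratio, band), finite = TRUE),
                 xlab = "target", ylab = "observed / expected")
  graphics::polygon(c(idx, rev(idx)), c(band[, "lo"], rev(band[, "hi"])),
                    col = "grey85", border = NA)
  graphics::abline(h = 1, lty = 2)
  graphics::points(idx, ratio, pch = 19,
                   col = ifelse(called, "red", "black"))
  invisible(x)
}

#' Render a per-call figure to an image file
#'
#' @param fit A `cnv_fit` (must contain at least one call, or set
#'   `require_call = FALSE` to plot a negative sample).
#' @param m The `coverage_matrix` used for the call.
#' @param path Output PNG path.
#' @param require_call Error when the fit has no calls (default FALSE).
#' @return `path`, invisibly.
#' @export
plot_call <- function(fit, m, path, require_call = FALSE) {
  if (require_call && nrow(fit$calls) == 0L) {
    stop("fit for ", fit$selection$test_id, " has no calls to plot")
  }
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  plot(fit, m)
  invisible(path)
}
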