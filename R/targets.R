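#' Read a BED file of panel targets
#'
#' Parses a tab-separated BED file (0-based, half-open intervals) into a
#' target table. The fourth column, when present, is stored as the gene
#' symbol. Duplicate intervals are removed and the result is sorted by
#' (chrom, start, end); this order is the exon order used by the HMM.
#'
#' @param path Path to a BED file with at least three tab-separated columns.
#' @return A `target_set`: a data.frame with columns `chrom`, `start`
#'   (0-based inclusive), `end` (0-based exclusive), `gene` and
#'   `custom_number` (NA unless annotated via [read_annotation()]).
#' @seealso [read_annotation()], [count_reads()]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) stop("BED file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- vapply(fields, length, integer(1))
  bad <- which(n_col < 3L)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in ", path,
         ": expected >= 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1], " in ",
         path, ": non-integer coordinates")
  }
  gene <- ifelse(n_col >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else "", character(1)), "")
  ts <- data.frame(chrom = chrom, start = start, end = end, gene = gene,
                   custom_number = NA_integer_, stringsAsFactors = FALSE)
  as_target_set(ts)
}

#' Coerce a data.frame of intervals into a canonical target set
#'
#' Validates, de-duplicates and sorts by (chrom, start, end). Rows with
#' `end <= start` or an empty chromosome name are rejected.
#'
#' @param df data.frame with columns chrom, start, end and optionally gene,
#'   custom_number.
#' @return A sorted, de-duplicated `target_set` data.frame.
#' @export
as_target_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$gene)) df$gene <- ""
  if (is.null(df$custom_number)) df$custom_number <- NA_integer_
  if (any(!nzchar(df$chrom))) stop("empty chromosome name in targets")
  if (any(df$end <= df$start)) {
    stop("invalid target interval (end <= start) at row ",
         which(df$end <= df$start)[1])
  }
  df <- df[!duplicated(df[, c("chrom", "start", "end")]), , drop = FALSE]
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("target_set", "data.frame")
  df
}

#' Attach gene symbols and custom exon numbers from an annotation file
#'
#' The annotation file is a TSV with columns chrom, start, end, gene,
#' custom_number (header required), matching targets on exact coordinates.
#' Custom numbers let laboratories report calls in the exon numbering of
#' their transcripts of interest, which may run against genomic coordinates
#' for reverse-strand genes.
#'
#' @param targets A `target_set`.
#' @param path Path to the annotation TSV.
#' @return The `target_set` with `gene` and `custom_number` filled in.
#' @export
read_annotation <- function(targets, path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene", "custom_number")
  if (!all(need %in% names(ann))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  idx <- match(key(targets), key(ann))
  hit <- !is.na(idx)
  targets$gene[hit] <- ann$gene[idx[hit]]
  targets$custom_number[hit] <- as.integer(ann$custom_number[idx[hit]])
  targets
}

#' Count reads overlapping each target in one BAM file
#'
#' Counts primary, non-duplicate, non-supplementary reads with mapping
#' quality >= `min_mapq` whose aligned span overlaps the target by at least
#' one base. A read overlapping two targets increments both. The BAM must be
#' coordinate-sorted and indexed.
#'
#' @param bam Path to an indexed BAM file.
#' @param targets A `target_set`.
#' @param min_mapq Minimum mapping quality (default 20).
#' @return Integer vector of per-target counts, in target order.
#' @export
count_reads <- function(bam, targets, min_mapq = 20L) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  idx1 <- paste0(bam, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam)
  if (!file.exists(idx1) && !file.exists(idx2)) {
    stop("BAM index (.bai) not found for: ", bam)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  known <- targets$chrom %in% names(hdr)
  counts <- integer(nrow(targets))
  if (any(!known)) {
    warning("targets on chromosomes absent from BAM header set to 0: ",
            paste(unique(targets$chrom[!known]), collapse = ", "))
  }
  if (any(known)) {
    gr <- GenomicRanges::GRanges(
      seqnames = targets$chrom[known],
      ranges = IRanges::IRanges(start = targets$start[known] + 1L,
                                end = targets$end[known]))
    param <- Rsamtools::ScanBamParam(
      which = gr,
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isDuplicate = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isUnmappedQuery = FALSE),
      mapqFilter = as.integer(min_mapq))
    res <- Rsamtools::countBam(bam, param = param)
    ## countBam returns one row per `which` range, in input order
    counts[known] <- as.integer(res$records)
  }
  counts
}

#' Build a coverage matrix from BAM files
#'
#' @param bams Character vector of indexed BAM paths; sample ids are taken
#'   from file names (without extension) unless `sample_ids` is given.
#' @param targets A `target_set`.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param sample_ids Optional character vector of unique sample identifiers.
#' @return A `coverage_matrix` (see [coverage_matrix()]).
#' @export
count_matrix <- function(bams, targets, min_mapq = 20L, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.bam$", "", basename(bams))
  }
  counts <- vapply(bams, count_reads, integer(nrow(targets)),
                   targets = targets, min_mapq = min_mapq)
  counts <- matrix(as.integer(counts), nrow = nrow(targets),
                   dimnames = list(NULL, sample_ids))
  coverage_matrix(targets, counts)
}

#' Construct a coverage matrix
#'
#' Container for per-target, per-sample read counts: the unit of data every
#' downstream step (reference selection, model fit, HMM, QC, simulations)
#' consumes.
#'
#' @param targets A `target_set` with one row per matrix row.
#' @param counts Non-negative integer matrix, targets x samples, with unique
#'   column names (sample ids).
#' @return An object of class `coverage_matrix`: list with elements
#'   `targets` and `counts`.
#' @export
coverage_matrix <- function(targets, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(targets)) {
    stop("counts has ", nrow(counts), " rows but targets has ", nrow(targets))
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts must have unique sample-id column names")
  }
  if (any(counts < 0)) stop("negative read counts are not allowed")
  if (any(counts != round(counts))) stop("read counts must be integers")
  storage.mode(counts) <- "integer"
  structure(list(targets = targets, counts = counts),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat("coverage_matrix:", nrow(x$counts), "targets x",
      ncol(x$counts), "samples\n")
  cat("  chromosomes:", paste(unique(x$targets$chrom), collapse = ", "), "\n")
  cat("  median count:", stats::median(x$counts), "\n")
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$counts)

#' Write a coverage matrix to a TSV file
#'
#' Columns: chrom, start, end, gene, then one integer column per sample.
#' `read_coverage_tsv(write_coverage_tsv(m))` reproduces `m`.
#'
#' @param m A `coverage_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(m, path) {
  df <- data.frame(chrom = m$targets$chrom, start = m$targets$start,
                   end = m$targets$end, gene = m$targets$gene,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(m$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coverage matrix from a TSV file
#'
#' @param path TSV written by [write_coverage_tsv()] (key columns chrom,
#'   start, end, gene followed by one column per sample).
#' @return A `coverage_matrix`.
#' @export
read_coverage_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop("duplicated sample column in coverage TSV: ",
         header[duplicated(header)][1])
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  key <- c("chrom", "start", "end", "gene")
  if (!all(key %in% names(df))) {
    stop("coverage TSV must start with columns: ", paste(key, collapse = ", "))
  }
  sample_cols <- setdiff(names(df), key)
  if (length(sample_cols) == 0L) stop("coverage TSV contains no sample columns")
  cnt <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(cnt) || any(cnt != round(cnt))) {
    stop("non-integer count cell in coverage TSV")
  }
  targets <- as_target_set(df[, key, drop = FALSE])
  ## as_target_set sorts; reorder counts to match
  ord <- order(df$chrom, df$start, df$end)
  coverage_matrix(targets, cnt[ord, , drop = FALSE])
}
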