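## Run expr with a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Synthetic panel model
#'
#' Describes a small exon-targeted panel. The default emulates a two-gene
#' BRCA-like panel: gene A with 23 exons over roughly 80 kb (forward strand)
#' and gene B with 26 exons over roughly 85 kb (reverse strand), each on its
#' own synthetic chromosome. Exon lengths and intron gaps may be supplied
#' explicitly; otherwise they are drawn reproducibly inside [make_panel()].
#'
#' @param genes List of gene descriptions, each a list with `name`, `chrom`,
#'   `strand` ("+"/"-"), `n_exons`, `span` (approximate genomic extent, bp)
#'   and optionally `exon_lengths`, `gaps` (explicit bp values).
#' @return List of class `panel_model`.
#' @export
panel_model <- function(genes = list(
  list(name = "GENEA", chrom = "chrA", strand = "+", n_exons = 23L,
       span = 8e4),
  list(name = "GENEB", chrom = "chrB", strand = "-", n_exons = 26L,
       span = 8.5e4))) {
  for (g in genes) {
    if (g$n_exons < 1L) stop("gene ", g$name, ": exon count must be >= 1")
  }
  structure(list(genes = genes), class = "panel_model")
}

#' Build a synthetic target set from a panel model
#'
#' Exon lengths are log-normal around 180 bp and intron gaps fill the stated
#' gene span, both drawn from a dedicated stream so the same seed always
#' yields the same panel. Custom exon numbers follow transcript direction:
#' on a reverse-strand gene they descend with genomic coordinate.
#'
#' @param model A `panel_model`.
#' @param seed Integer seed.
#' @return A `target_set` with `gene` and `custom_number` filled in.
#' @export
make_panel <- function(model = panel_model(), seed = 1L) {
  with_seed(seed, {
    rows <- lapply(model$genes, function(g) {
      n <- g$n_exons
      len <- g$exon_lengths
      if (is.null(len)) {
        len <- pmax(50L, as.integer(round(stats::rlnorm(n, log(180), 0.4))))
      }
      gaps <- g$gaps
      if (is.null(gaps) && n > 1L) {
        w <- stats::rlnorm(n - 1L, 0, 0.5)
        gaps <- as.integer(round(w / sum(w) * max(g$span - sum(len), n * 100)))
      } else if (is.null(gaps)) {
        gaps <- integer(0)
      }
      start <- cumsum(c(10000L, len[-n] + gaps))
      custom <- if (identical(g$strand, "-")) rev(seq_len(n)) else seq_len(n)
      data.frame(chrom = g$chrom, start = start, end = start + len,
                 gene = g$name, custom_number = custom,
                 stringsAsFactors = FALSE)
    })
    as_target_set(do.call(rbind, rows))
  })
}

#' Simulation specification for synthetic coverage pools
#'
#' Emulates the count structure of pooled capture sequencing: a per-target
#' probe efficiency shared by every sample (this is what makes samples highly
#' correlated and makes a reference model work), a per-sample library-size
#' factor, and mild extra-Poisson noise per cell.
#'
#' @param n_samples Number of samples (default 48, one enrichment pool).
#' @param mean_reads Mean reads per target at normal copy number
#'   (default 1000).
#' @param probe_log_sd Log-sd of the shared per-target probe efficiency
#'   (default 0.5).
#' @param libsize_log_sd Log-sd of the per-sample library factor
#'   (default 0.1).
#' @param dispersion Negative-binomial size parameter per cell (default
#'   1000, i.e. ~3% extra-Poisson noise; `Inf` gives pure Poisson).
#' @param implants List of CNVs to implant; each element a list with
#'   `sample` (id or index), `gene`, `exons` (c(first, last) in custom exon
#'   numbers), `kind` ("deletion" or "duplication").
#' @param seed Integer seed.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 48L, mean_reads = 1000, probe_log_sd = 0.5,
                     libsize_log_sd = 0.1, dispersion = 1000,
                     implants = list(), seed = 1L) {
  stopifnot(n_samples >= 1, mean_reads > 0, probe_log_sd >= 0,
            libsize_log_sd >= 0, dispersion > 0)
  structure(list(n_samples = as.integer(n_samples), mean_reads = mean_reads,
                 probe_log_sd = probe_log_sd, libsize_log_sd = libsize_log_sd,
                 dispersion = dispersion, implants = implants,
                 seed = as.integer(seed)), class = "sim_spec")
}

## Resolve an implant spec to target row indices on a panel.
implant_rows <- function(panel, implant) {
  rows <- which(panel$gene == implant$gene &
                  panel$custom_number >= min(implant$exons) &
                  panel$custom_number <= max(implant$exons))
  if (length(rows) == 0L) {
    stop("implant outside panel bounds: ", implant$gene, " exons ",
         paste(implant$exons, collapse = "-"))
  }
  sort(rows)
}

#' Simulate a coverage pool with known implanted CNVs
#'
#' Counts are drawn negative-binomial with mean
#' `mean_reads * e_i * s_j * c_ij / 2`, where `e_i` is the shared per-target
#' probe efficiency, `s_j` the per-sample library factor and `c_ij` the
#' implanted copy number (2 unless an implant covers the cell).
#'
#' @param spec A `sim_spec`.
#' @param panel A `target_set` from [make_panel()].
#' @return List with `matrix` (a `coverage_matrix`) and `truth` (data.frame:
#'   sample, gene, exon_first, exon_last, first_target, last_target, chrom,
#'   start, end, kind — one row per implant).
#' @export
simulate_pool <- function(spec, panel) {
  n_t <- nrow(panel)
  ids <- sprintf("S%02d", seq_len(spec$n_samples))
  with_seed(spec$seed, {
    e <- stats::rlnorm(n_t, 0, spec$probe_log_sd)
    s <- stats::rlnorm(spec$n_samples, 0, spec$libsize_log_sd)
    cn <- matrix(2, n_t, spec$n_samples)
    truth <- list()
    for (im in spec$implants) {
      j <- if (is.character(im$sample)) match(im$sample, ids) else im$sample
      if (is.na(j) || j < 1L || j > spec$n_samples) {
        stop("implant sample out of range: ", im$sample)
      }
      rows <- implant_rows(panel, im)
      cn[rows, j] <- if (im$kind == "deletion") 1 else 3
      truth[[length(truth) + 1L]] <- data.frame(
        sample = ids[j], gene = im$gene,
        exon_first = min(im$exons), exon_last = max(im$exons),
        first_target = rows[1], last_target = rows[length(rows)],
        chrom = panel$chrom[rows[1]],
        start = panel$start[rows[1]] + 1L,
        end = panel$end[rows[length(rows)]],
        kind = im$kind, stringsAsFactors = FALSE)
    }
    mu <- outer(e, s) * spec$mean_reads * cn / 2
    cnt <- if (is.infinite(spec$dispersion)) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = spec$dispersion)
    }
    cnt <- matrix(as.integer(cnt), n_t, spec$n_samples,
                  dimnames = list(NULL, ids))
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      sample = character(0), gene = character(0), exon_first = integer(0),
      exon_last = integer(0), first_target = integer(0),
      last_target = integer(0), chrom = character(0), start = integer(0),
      end = integer(0), kind = character(0), stringsAsFactors = FALSE)
    list(matrix = coverage_matrix(panel, cnt), truth = truth)
  })
}

#' Default BRCA-like implant design for benchmark pools
#'
#' Sixteen exon CNVs (a mix of single- and multi-exon deletions and
#' duplications, in the proportions typical of clinical BRCA series) spread
#' over the first sixteen samples of a pool; spans are given in custom exon
#' numbers of the default two-gene panel.
#'
#' @return List of implant descriptions for [sim_spec()].
#' @export
default_implants <- function() {
  spans <- list(
    list(gene = "GENEA", exons = c(5, 8),   kind = "duplication"),
    list(gene = "GENEA", exons = c(13, 13), kind = "duplication"),
    list(gene = "GENEA", exons = c(20, 20), kind = "deletion"),
    list(gene = "GENEA", exons = c(1, 12),  kind = "deletion"),
    list(gene = "GENEA", exons = c(1, 2),   kind = "deletion"),
    list(gene = "GENEA", exons = c(21, 23), kind = "deletion"),
    list(gene = "GENEA", exons = c(8, 13),  kind = "deletion"),
    list(gene = "GENEA", exons = c(16, 16), kind = "deletion"),
    list(gene = "GENEA", exons = c(22, 22), kind = "deletion"),
    list(gene = "GENEA", exons = c(20, 22), kind = "deletion"),
    list(gene = "GENEB", exons = c(14, 16), kind = "deletion"),
    list(gene = "GENEB", exons = c(1, 11),  kind = "deletion"),
    list(gene = "GENEB", exons = c(1, 2),   kind = "deletion"),
    list(gene = "GENEB", exons = c(2, 2),   kind = "deletion"),
    list(gene = "GENEB", exons = c(21, 21), kind = "duplication"),
    list(gene = "GENEB", exons = c(21, 24), kind = "deletion"))
  mapply(function(sp, j) c(list(sample = j), sp), spans,
         seq_along(spans), SIMPLIFY = FALSE)
}

#' Write a synthetic fixture to disk
#'
#' Writes BED, annotation TSV, coverage TSV and truth TSV into `dir`.
#'
#' @param pool Result of [simulate_pool()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- pool$matrix$targets
  bed <- file.path(dir, "panel.bed")
  writeLines(paste(panel$chrom, panel$start, panel$end, panel$gene,
                   sep = "\t"), bed)
  ann <- file.path(dir, "annotation.tsv")
  utils::write.table(panel[, c("chrom", "start", "end", "gene",
                               "custom_number")],
                     ann, sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- file.path(dir, "coverage.tsv")
  write_coverage_tsv(pool$matrix, cov)
  tru <- file.path(dir, "truth.tsv")
  utils::write.table(pool$truth, tru, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed, annotation = ann, coverage = cov, truth = tru))
}
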