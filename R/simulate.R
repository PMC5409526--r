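## round half away from zero (base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## derived substream seed, kept inside 32-bit signed range
substream <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 1000003 + i * 2011 + j * 7) %% 2147483647)
}

#' Spike specification for a single synthetic exon CNV
#'
#' @param sample Sample id or column index.
#' @param target_index Row index of the exon to spike.
#' @param kind "deletion" (coverage halved) or "duplication" (increased by
#'   half).
#' @param factor Optional explicit scaling factor overriding the kind's
#'   default 0.5 / 1.5 (e.g. 1.0 for a null spike).
#' @return List of class `spike_spec`.
#' @export
spike_spec <- function(sample, target_index, kind, factor = NULL) {
  if (!kind %in% c("deletion", "duplication")) {
    stop('kind must be "deletion" or "duplication"')
  }
  structure(list(sample = sample, target_index = as.integer(target_index),
                 kind = kind, factor = factor), class = "spike_spec")
}

#' Implant a single-exon spike into a coverage matrix
#'
#' Replaces the one (target, sample) cell by its count scaled by 0.5
#' (deletion) or 1.5 (duplication), rounded half away from zero; every other
#' cell is untouched.
#'
#' @param m A `coverage_matrix`.
#' @param spec A `spike_spec`.
#' @return The spiked `coverage_matrix`.
#' @export
spike_exon <- function(m, spec) {
  j <- if (is.character(spec$sample)) match(spec$sample, colnames(m$counts))
       else spec$sample
  if (is.na(j) || j < 1L || j > ncol(m$counts)) {
    stop("spike sample out of range: ", spec$sample)
  }
  i <- spec$target_index
  if (i < 1L || i > nrow(m$counts)) stop("spike target out of range: ", i)
  f <- if (!is.null(spec$factor)) spec$factor
       else if (spec$kind == "deletion") 0.5 else 1.5
  m$counts[i, j] <- as.integer(round_half_away(m$counts[i, j] * f))
  m
}

#' Single-exon spike-in sensitivity study
#'
#' For each target exon and CNV kind, repeatedly picks a random sample from a
#' CNV-negative pool, spikes that exon's coverage by +/-50%, re-runs the full
#' caller, and scores a success when a call of the spiked kind overlaps the
#' spiked exon. Sensitivity is the percentage of successful repeats. Each
#' (exon, kind) pair uses its own derived random substream, so results for
#' one exon do not depend on which other exons are evaluated.
#'
#' @param m A `coverage_matrix` of CNV-negative samples.
#' @param target_indices Target rows to evaluate (default: all).
#' @param kinds Character vector in ("deletion", "duplication").
#' @param reps Repeats per (exon, kind) (default 100; the full-scale design
#'   uses 1000).
#' @param seed Integer seed.
#' @param params,qc,max_refs Passed to [cnv_call()].
#' @param factor Optional explicit spike factor (see [spike_spec()]).
#' @return data.frame: target_index, chrom, gene, custom_number, kind,
#'   sensitivity (%).
#' @export
single_exon_sensitivity <- function(m, target_indices = seq_len(nrow(m$counts)),
                                    kinds = c("deletion", "duplication"),
                                    reps = 100L, seed = 1L,
                                    params = hmm_params(),
                                    qc = qc_thresholds(), max_refs = 10L,
                                    factor = NULL) {
  if (reps < 1L) stop("reps must be >= 1")
  ids <- colnames(m$counts)
  rows <- list()
  for (kind in kinds) {
    kcode <- match(kind, c("deletion", "duplication"))
    for (i in target_indices) {
      hits <- with_seed(substream(seed, i, kcode), {
        sum(vapply(seq_len(reps), function(rep) {
          sid <- ids[sample.int(length(ids), 1L)]
          sm <- spike_exon(m, spike_spec(sid, i, kind, factor = factor))
          fit <- cnv_call(sm, sid, params = params, qc = qc,
                          max_refs = max_refs)
          calls <- fit$calls
          any(calls$cnv_type == kind & calls$first_target <= i &
                calls$last_target >= i)
        }, logical(1)))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        target_index = i, chrom = m$targets$chrom[i],
        gene = m$targets$gene[i], custom_number = m$targets$custom_number[i],
        kind = kind, sensitivity = 100 * hits / reps,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binomial read-resampling specification
#'
#' Each original read is replicated `N_r ~ Binomial(n, p)` times with
#' `n * p = factor`; the parameters are chosen to stay as close to Poisson as
#' possible: down-sampling (`factor <= 1`) uses `n = 1, p = factor` (exact
#' Bernoulli/Poisson thinning); up-sampling uses `n = ceiling(10 * factor)`,
#' `p = factor / n`, keeping the variance within ~10% of the mean.
#'
#' @param factor Target depth ratio (> 0).
#' @return List of class `resample_spec` with `factor`, `n`, `p`.
#' @export
resample_spec <- function(factor) {
  if (!(factor > 0)) stop("resampling factor must be > 0")
  if (factor <= 1) {
    n <- 1L; p <- factor
  } else {
    n <- as.integer(ceiling(10 * factor)); p <- factor / n
  }
  stopifnot(abs(n * p - factor) < 1e-9)
  structure(list(factor = factor, n = n, p = p), class = "resample_spec")
}

#' Resample one read count to a new depth
#'
#' The sum of `count` independent Binomial(n, p) read-replication draws,
#' realised as a single Binomial(n * count, p) draw (identical in
#' distribution). Expectation is `factor * count`.
#'
#' @param count Non-negative integer count (vectorised).
#' @param spec A `resample_spec`.
#' @return Resampled integer count(s).
#' @export
resample_count <- function(count, spec) {
  if (any(count < 0)) stop("counts must be >= 0")
  if (spec$n == 1L && spec$p == 1) return(as.integer(count))
  as.integer(stats::rbinom(length(count), size = spec$n * count, prob = spec$p))
}

#' Resample every cell of a coverage matrix
#'
#' @param m A `coverage_matrix`.
#' @param spec A `resample_spec`.
#' @return A `coverage_matrix` at the new depth.
#' @export
resample_matrix <- function(m, spec) {
  cnt <- matrix(resample_count(as.vector(m$counts), spec),
                nrow(m$counts), ncol(m$counts),
                dimnames = dimnames(m$counts))
  coverage_matrix(m$targets, cnt)
}

#' Score calls against a truth set
#'
#' A truth variant is detected iff some call in the same sample, of the same
#' kind, overlaps its span by at least one target. Specificity is the
#' percentage of CNV-negative samples with no call at all.
#'
#' @param calls data.frame of calls (columns sample, cnv_type, first_target,
#'   last_target), e.g. rbind-ed from [cnv_call()] results.
#' @param truth data.frame with columns sample, kind, first_target,
#'   last_target.
#' @param samples All sample ids evaluated (denominator for specificity).
#' @return List: `sensitivity` (%, NA when truth is empty), `specificity`
#'   (%, NA when every sample carries a CNV), `n_truth`, `n_negative`.
#' @export
score_calls <- function(calls, truth, samples) {
  detected <- if (nrow(truth) == 0L) logical(0) else
    vapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      any(calls$sample == tr$sample & calls$cnv_type == tr$kind &
            calls$first_target <= tr$last_target &
            calls$last_target >= tr$first_target)
    }, logical(1))
  negatives <- setdiff(samples, unique(truth$sample))
  clean <- vapply(negatives, function(id) !any(calls$sample == id), logical(1))
  list(sensitivity = if (nrow(truth)) 100 * mean(detected) else NA_real_,
       specificity = if (length(negatives)) 100 * mean(clean) else NA_real_,
       n_truth = nrow(truth), n_negative = length(negatives))
}

#' Pool-size x coverage grid experiment
#'
#' Re-runs the caller on replicate pools drawn (without replacement) from a
#' larger set with known implanted CNVs, after binomial resampling of every
#' cell to a target depth. Replicates whose pool contains no CNV sample are
#' excluded from the sensitivity average; replicates whose pool is entirely
#' CNV samples are excluded from the specificity average.
#'
#' @param pool List with `matrix` (a `coverage_matrix`) and `truth`
#'   (as from [simulate_pool()]).
#' @param pool_sizes Integer vector of pool sizes to evaluate.
#' @param coverages Numeric vector of depth factors relative to the native
#'   depth of `pool$matrix`.
#' @param reps Replicates per grid cell (default 50).
#' @param seed Integer seed; fixed seed gives a bit-identical result.
#' @param params,qc,max_refs Passed to [cnv_call()].
#' @return data.frame of class `simulation_result`: one row per grid cell
#'   with pool_size, coverage_factor, mean/min/max sensitivity and
#'   specificity, and n_excluded_sens / n_excluded_spec.
#' @export
grid_experiment <- function(pool, pool_sizes, coverages, reps = 50L,
                            seed = 1L, params = hmm_params(),
                            qc = qc_thresholds(), max_refs = 10L) {
  m <- pool$matrix
  truth <- pool$truth
  ids <- colnames(m$counts)
  if (any(pool_sizes > length(ids))) {
    stop("pool size exceeds available samples (", length(ids), ")")
  }
  cells <- list()
  for (ps in pool_sizes) {
    for (f in coverages) {
      rs <- resample_spec(f)
      sens <- numeric(0); spc <- numeric(0)
      excl_sens <- 0L; excl_spec <- 0L
      for (rep in seq_len(reps)) {
        res <- with_seed(substream(seed, which(ps == pool_sizes) * 1000 + rep,
                                   which(f == coverages)), {
          members <- sort(sample(ids, ps))
          sub <- coverage_matrix(m$targets,
                                 m$counts[, members, drop = FALSE])
          sub <- resample_matrix(sub, rs)
          tr <- truth[truth$sample %in% members, , drop = FALSE]
          calls <- do.call(rbind, lapply(members, function(id)
            cnv_call(sub, id, params = params, qc = qc,
                     max_refs = max_refs)$calls))
          if (is.null(calls)) calls <- data.frame(
            sample = character(0), cnv_type = character(0),
            first_target = integer(0), last_target = integer(0))
          score_calls(calls, tr, members)
        })
        if (is.na(res$sensitivity)) excl_sens <- excl_sens + 1L
        else sens <- c(sens, res$sensitivity)
        if (is.na(res$specificity)) excl_spec <- excl_spec + 1L
        else spc <- c(spc, res$specificity)
      }
      cells[[length(cells) + 1L]] <- data.frame(
        pool_size = ps, coverage_factor = f,
        sensitivity_mean = mean(sens), sensitivity_min = suppressWarnings(min(sens)),
        sensitivity_max = suppressWarnings(max(sens)),
        specificity_mean = mean(spc), specificity_min = suppressWarnings(min(spc)),
        specificity_max = suppressWarnings(max(spc)),
        n_excluded_sens = excl_sens, n_excluded_spec = excl_spec,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  class(out) <- c("simulation_result", "data.frame")
  out
}
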