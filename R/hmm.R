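## HMM state order used throughout: 1 = del (CN1), 2 = normal (CN2), 3 = dup (CN3)
.STATES <- c("del", "normal", "dup")
.STATE_CN <- c(1L, 2L, 3L)

#' HMM parameters
#'
#' @param q Per-step prior probability of entering each CNV state
#'   (default 0.01). Raising q trades false-discovery rate for sensitivity.
#' @param L Expected CNV length in bp (default 50,000): sets how fast the
#'   probability of a CNV persisting across an inter-exon gap decays, so that
#'   exons far apart on the chromosome are treated independently.
#' @return List of class `hmm_params`.
#' @export
hmm_params <- function(q = 0.01, L = 5e4) {
  if (!(q > 0 && q < 0.5)) stop("q must be in (0, 0.5)")
  if (!(L > 0)) stop("L must be positive")
  structure(list(q = q, L = L), class = "hmm_params")
}

#' Expected test-read proportion under a copy-number state
#'
#' Scales the fitted normal-copy mean `mu` on the odds scale by c/2: the test
#' sample contributes c/2 times its diploid share of reads, so the proportion
#' becomes `c*mu / (c*mu + 2*(1-mu))`. At c = 2 this is `mu`.
#'
#' @param mu Proportion in (0, 1).
#' @param c Copy number, one of 1, 2, 3.
#' @return Proportion under copy number `c`.
#' @export
state_mean <- function(mu, c) {
  stopifnot(mu > 0, mu < 1)
  if (!all(c %in% c(1L, 2L, 3L))) stop("copy number must be 1, 2 or 3")
  c * mu / (c * mu + 2 * (1 - mu))
}

#' Distance-dependent transition matrix
#'
#' Rows/columns ordered (del, normal, dup). The normal row is the constant
#' prior (q, 1-2q, q). A CNV state persists across a gap of d bp with
#' probability `e = exp(-d/L)` and otherwise re-draws from the prior:
#' stay = e + (1-e)q, to normal = (1-e)(1-2q), to the other CNV = (1-e)q.
#' At d = 0 a CNV always persists; at d = Inf (chromosome change) all rows
#' collapse to the prior, making adjacent targets independent.
#'
#' @param d Gap in bp between consecutive targets (>= 0, may be `Inf`).
#' @param params An `hmm_params`.
#' @return 3x3 row-stochastic matrix.
#' @export
transition_matrix <- function(d, params) {
  stopifnot(d >= 0)
  q <- params$q
  e <- exp(-d / params$L)   # exp(-Inf) == 0
  prior <- c(q, 1 - 2 * q, q)
  tm <- matrix(0, 3, 3, dimnames = list(.STATES, .STATES))
  tm[2, ] <- prior
  tm[1, ] <- c(e + (1 - e) * q, (1 - e) * (1 - 2 * q), (1 - e) * q)
  tm[3, ] <- c((1 - e) * q, (1 - e) * (1 - 2 * q), e + (1 - e) * q)
  tm
}

#' Initial state distribution
#'
#' Equal to the prior row (q, 1-2q, q), so the first exon on a chromosome can
#' be called a CNV with the same prior as any other entry point.
#'
#' @param params An `hmm_params`.
#' @return Length-3 probability vector over (del, normal, dup).
#' @export
initial_distribution <- function(params) {
  q <- params$q
  stats::setNames(c(q, 1 - 2 * q, q), .STATES)
}

#' Gaps between consecutive targets, Inf at chromosome boundaries
#'
#' @param targets A `target_set`.
#' @return Numeric vector of length `nrow(targets) - 1`.
#' @export
target_gaps <- function(targets) {
  k <- nrow(targets)
  if (k < 2L) return(numeric(0))
  d <- pmax(targets$start[-1] - targets$end[-k], 0)
  d[targets$chrom[-1] != targets$chrom[-k]] <- Inf
  d
}

#' Viterbi decoding of the three-state copy-number HMM
#'
#' Maximum-a-posteriori state path in log space. Ties are broken in favour of
#' normal, then deletion (conservative for clinical reporting).
#'
#' @param emissions Targets x 3 matrix of log-likelihoods, columns
#'   (del, normal, dup).
#' @param gaps Per-step gaps in bp (`Inf` at chromosome boundaries); length
#'   `nrow(emissions) - 1`.
#' @param params An `hmm_params`.
#' @return Character vector of states, one per target.
#' @export
viterbi <- function(emissions, gaps, params) {
  K <- nrow(emissions)
  if (K == 0L) return(character(0))
  if (length(gaps) != K - 1L) stop("gaps must have length nrow(emissions) - 1")
  if (any(!is.finite(emissions))) stop("emissions must be finite")
  pref <- c(2L, 1L, 3L)  # tie-break preference: normal, del, dup
  delta <- matrix(-Inf, K, 3)
  psi <- matrix(NA_integer_, K, 3)
  delta[1, ] <- log(initial_distribution(params)) + emissions[1, ]
  if (K > 1L) {
    for (t in 2:K) {
      ltm <- log(transition_matrix(gaps[t - 1L], params))
      for (s in 1:3) {
        cand <- delta[t - 1L, ] + ltm[, s]
        best <- pref[which.max(cand[pref])]
        psi[t, s] <- best
        delta[t, s] <- cand[best] + emissions[t, s]
      }
    }
  }
  path <- integer(K)
  path[K] <- pref[which.max(delta[K, pref])]
  if (K > 1L) for (t in (K - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  .STATES[path]
}

#' Emission log-likelihood matrix
#'
#' Per target, the beta-binomial log-likelihood of the test count given the
#' test+reference total, at the state mean for copy numbers 1, 2 and 3 with
#' the shared fitted overdispersion.
#'
#' @param test_counts,ref_counts Integer vectors per target.
#' @param fit A `betabin_fit`.
#' @return Targets x 3 matrix, columns (del, normal, dup).
#' @export
emission_matrix <- function(test_counts, ref_counts, fit) {
  n <- test_counts + ref_counts
  em <- matrix(0, length(n), 3, dimnames = list(NULL, .STATES))
  pos <- n > 0
  for (s in 1:3) {
    mu_s <- state_mean(fit$mu, .STATE_CN[s])
    em[pos, s] <- betabin_logpmf(test_counts[pos], n[pos], mu_s, fit$phi)
  }
  em
}

#' Segment a decoded state path into CNV calls
#'
#' Maximal runs of `del` or `dup` become one call each; runs never span
#' chromosome boundaries. The Bayes factor is the log10 likelihood ratio of
#' the called state vs normal summed over the span. Reported coordinates are
#' 1-based inclusive.
#'
#' @param path Character state vector from [viterbi()].
#' @param targets A `target_set` aligned with `path`.
#' @param test_counts,ref_counts Integer vectors per target.
#' @param fit A `betabin_fit`.
#' @param selection A `reference_selection` (for QC context columns).
#' @param emissions Optional precomputed [emission_matrix()].
#' @return data.frame of calls (possibly 0 rows) with columns: sample,
#'   correlation, n_comp, cnv_type, n_exons, chrom, start, end, gene,
#'   custom_first, custom_last, first_target, last_target, bf,
#'   reads_expected, reads_observed, reads_ratio.
#' @export
segment_calls <- function(path, targets, test_counts, ref_counts, fit,
                          selection, emissions = NULL) {
  if (is.null(emissions)) {
    emissions <- emission_matrix(test_counts, ref_counts, fit)
  }
  K <- length(path)
  empty <- data.frame(
    sample = character(0), correlation = numeric(0), n_comp = integer(0),
    cnv_type = character(0), n_exons = integer(0), chrom = character(0),
    start = integer(0), end = integer(0), gene = character(0),
    custom_first = integer(0), custom_last = integer(0),
    first_target = integer(0), last_target = integer(0), bf = numeric(0),
    reads_expected = numeric(0), reads_observed = numeric(0),
    reads_ratio = numeric(0), stringsAsFactors = FALSE)
  if (K == 0L) return(empty)
  ## break runs at state changes and chromosome changes
  grp <- cumsum(c(TRUE, path[-1] != path[-K] |
                    targets$chrom[-1] != targets$chrom[-K]))
  rows <- lapply(split(seq_len(K), grp), function(idx) {
    st <- path[idx[1]]
    if (st == "normal") return(NULL)
    s_col <- match(st, .STATES)
    n_tot <- test_counts[idx] + ref_counts[idx]
    expected <- sum(round(n_tot * fit$mu))
    observed <- sum(test_counts[idx])
    genes <- unique(targets$gene[idx])
    genes <- genes[nzchar(genes)]
    data.frame(
      sample = selection$test_id,
      correlation = selection$max_correlation,
      n_comp = selection$n_comp,
      cnv_type = if (st == "del") "deletion" else "duplication",
      n_exons = length(idx),
      chrom = targets$chrom[idx[1]],
      start = targets$start[idx[1]] + 1L,
      end = targets$end[idx[length(idx)]],
      gene = paste(genes, collapse = ","),
      custom_first = targets$custom_number[idx[1]],
      custom_last = targets$custom_number[idx[length(idx)]],
      first_target = idx[1],
      last_target = idx[length(idx)],
      bf = sum(emissions[idx, s_col] - emissions[idx, 2]) / log(10),
      reads_expected = expected,
      reads_observed = observed,
      reads_ratio = observed / expected,
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call copy-number variants for one sample
#'
#' The full per-sample pipeline: select well-correlated reference samples,
#' fit the beta-binomial read-share model, build per-state emissions, decode
#' the distance-aware HMM by Viterbi, and segment the path into calls.
#'
#' @param m A `coverage_matrix` with >= 2 samples.
#' @param test_id Sample id of the sample of interest.
#' @param params An `hmm_params` (default [hmm_params()]).
#' @param qc A `qc_thresholds` (default [qc_thresholds()]).
#' @param max_refs Maximum reference samples (default 10).
#' @param trim Outlier-trimming fraction passed to [select_reference()].
#' @return Object of class `cnv_fit`: list with `calls` (data.frame),
#'   `selection`, `fit`, `path`, `emissions`, `targets`, `test_counts`,
#'   `ref_counts`, `params`, `qc_row`.
#' @examples
#' pool <- simulate_pool(sim_spec(n_samples = 6, mean_reads = 300, seed = 1),
#'                       make_panel(seed = 1))
#' fit <- cnv_call(pool$matrix, "S01")
#' fit
#' @export
cnv_call <- function(m, test_id, params = hmm_params(),
                     qc = qc_thresholds(), max_refs = 10L, trim = 0.06) {
  if (ncol(m$counts) < 2L) stop("need >= 2 samples to call CNVs")
  sel <- tryCatch(select_reference(m, test_id, max_refs = max_refs,
                                   trim = trim),
                  error = function(e) {
                    stop("sample ", test_id, ": ", conditionMessage(e))
                  })
  fit <- sel$fit
  test <- m$counts[, test_id]
  em <- emission_matrix(test, sel$ref_counts, fit)
  path <- viterbi(em, target_gaps(m$targets), params)
  calls <- segment_calls(path, m$targets, test, sel$ref_counts, fit, sel, em)
  qc_row <- data.frame(sample = test_id,
                       max_correlation = sel$max_correlation,
                       n_comp = sel$n_comp,
                       status = ifelse(sel$max_correlation >= qc$min_correlation,
                                       "pass", "fail"),
                       stringsAsFactors = FALSE)
  structure(list(calls = calls, selection = sel, fit = fit, path = path,
                 emissions = em, targets = m$targets, test_counts = test,
                 ref_counts = sel$ref_counts, params = params, qc_row = qc_row),
            class = "cnv_fit")
}

#' @export
print.cnv_fit <- function(x, ...) {
  cat(sprintf("CNV calls for sample %s (%d targets, %d reference samples, r = %.4f)\n",
              x$selection$test_id, length(x$path), x$selection$n_comp,
              x$selection$max_correlation))
  if (nrow(x$calls) == 0L) {
    cat("  no CNV called\n")
  } else {
    print(x$calls[, c("cnv_type", "chrom", "start", "end", "gene", "n_exons",
                      "bf", "reads_ratio")])
  }
  invisible(x)
}

#' @method summary cnv_fit
#' @export
summary.cnv_fit <- function(object, ...) {
  cat("Per-sample exon CNV fit\n")
  cat(sprintf("  sample:          %s\n", object$selection$test_id))
  cat(sprintf("  reference:       %d samples (%s)\n", object$selection$n_comp,
              paste(object$selection$chosen, collapse = ", ")))
  cat(sprintf("  max correlation: %.4f (QC %s)\n",
              object$selection$max_correlation, object$qc_row$status))
  cat(sprintf("  model:           mu = %.5f, phi = %.3g\n",
              object$fit$mu, object$fit$phi))
  cat(sprintf("  calls:           %d\n", nrow(object$calls)))
  if (nrow(object$calls) > 0L) print(object$calls)
  invisible(object)
}

#' @method coef cnv_fit
#' @export
coef.cnv_fit <- function(object, ...) {
  c(mu = object$fit$mu, phi = object$fit$phi)
}

#' Observed/expected coverage ratios of a CNV fit
#'
#' @param object A `cnv_fit`.
#' @param ... Unused.
#' @return Per-target ratio of observed test counts to their expectation
#'   under normal copy number (`(test+ref) * mu`).
#' @method residuals cnv_fit
#' @export
residuals.cnv_fit <- function(object, ...) {
  n <- object$test_counts + object$ref_counts
  object$test_counts / (n * object$fit$mu)
}
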