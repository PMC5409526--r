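#' Beta-binomial log probability mass
#'
#' Beta-binomial in the mean/intraclass-correlation parameterisation:
#' `alpha = mu * (1 - phi) / phi`, `beta = (1 - mu) * (1 - phi) / phi` for
#' `phi` in (0, 1); `phi = 0` is the binomial limit. `phi` is the
#' overdispersion (the correlation between the Bernoulli components), so the
#' variance is `n * mu * (1 - mu) * (1 + (n - 1) * phi)`.
#'
#' @param x Integer count(s), 0 <= x <= n.
#' @param n Integer total(s).
#' @param mu Mean proportion in (0, 1).
#' @param phi Overdispersion in [0, 1).
#' @return Log probability, vectorised over `x`/`n`.
#' @export
betabin_logpmf <- function(x, n, mu, phi) {
  if (!(mu > 0 && mu < 1)) stop("mu must be in (0, 1)")
  if (!(phi >= 0 && phi < 1)) stop("phi must be in [0, 1)")
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n")
  if (phi < 1e-8) {
    ## binomial branch: below this the beta-binomial correction is O(n^2*phi)
    ## in log-likelihood while lbeta() with alpha, beta ~ 1/phi loses more
    ## precision to cancellation than the correction is worth
    return(stats::dbinom(x, n, mu, log = TRUE))
  }
  a <- mu * (1 - phi) / phi
  b <- (1 - mu) * (1 - phi) / phi
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

#' Pearson correlation of a test sample against all other samples
#'
#' Correlations are computed on raw per-target counts; targets with zero
#' count in every sample are excluded. A zero-variance vector yields
#' correlation 0 with a warning (such samples are useless as references and
#' should be flagged by QC, not crash the run).
#'
#' @param m A `coverage_matrix`.
#' @param test_id Sample id present in `m`.
#' @return Named numeric vector of correlations, one per other sample.
#' @export
pairwise_correlation <- function(m, test_id) {
  cnt <- m$counts
  if (!test_id %in% colnames(cnt)) stop("unknown sample id: ", test_id)
  if (nrow(cnt) < 2L) stop("need at least 2 targets to correlate")
  keep <- rowSums(cnt) > 0
  cnt <- cnt[keep, , drop = FALSE]
  x <- cnt[, test_id]
  others <- setdiff(colnames(cnt), test_id)
  sd_x <- stats::sd(x)
  r <- vapply(others, function(id) {
    y <- cnt[, id]
    if (sd_x == 0 || stats::sd(y) == 0) {
      warning("zero variance in correlation between ", test_id, " and ", id,
              "; reported as 0")
      return(0)
    }
    stats::cor(x, y)
  }, numeric(1))
  r
}

#' Fit the beta-binomial model of test counts against an aggregated reference
#'
#' For each target i the test count `x_i` given the total `n_i = x_i + r_i`
#' (r = aggregated reference) is modelled as beta-binomial with a global mean
#' `mu` (the expected share of test reads under normal copy number) and a
#' global overdispersion `phi` that absorbs residual inter-target noise left
#' after probe effects cancel in the proportion.
#'
#' `mu` is initialised at `sum(x) / sum(n)` and `(mu, phi)` maximise the
#' summed log-likelihood; `phi` is bounded to [0, 0.5]. If the optimiser
#' fails, the fit falls back to the initial `mu` with `phi = 1e-4` and
#' `converged = FALSE`.
#'
#' With `trim > 0` the fit is refitted after dropping the
#' `ceiling(trim * K)` targets with the largest absolute standardised
#' residuals under the initial fit. On small panels a single real CNV exon
#' would otherwise inflate the overdispersion estimate and blunt its own
#' detection; trimming makes `phi` reflect the normal-copy targets.
#'
#' @param test_counts Integer vector of test-sample counts per target.
#' @param ref_counts Integer vector of aggregated reference counts.
#' @param trim Fraction of targets to exclude as outliers before the final
#'   fit (default 0: the plain maximum-likelihood fit).
#' @param init Optional c(mu, phi) starting point for the optimiser (used to
#'   warm-start successive fits over growing reference sets).
#' @return List of class `betabin_fit`: `mu`, `phi`, `loglik`, `converged`.
#' @export
fit_betabin <- function(test_counts, ref_counts, trim = 0, init = NULL) {
  stopifnot(length(test_counts) == length(ref_counts))
  n <- test_counts + ref_counts
  keep <- n > 0
  if (sum(keep) < 5L) stop("need >= 5 informative targets (test+ref > 0)")
  x <- test_counts[keep]
  n <- n[keep]
  if (sum(x) == 0) stop("all test counts are zero; cannot fit proportion model")
  mu0 <- sum(x) / sum(n)
  mu0 <- min(max(mu0, 1e-6), 1 - 1e-6)
  start <- if (is.null(init)) c(mu0, 0.01) else
    c(min(max(init[1], 1e-4), 1 - 1e-4), min(max(init[2], 1e-3), 0.49))
  ml <- function(x, n, start) {
    nll <- function(par) {
      ## numeric gradient steps may poke just outside the box
      if (par[1] <= 0 || par[1] >= 1 || par[2] < 0 || par[2] >= 1) return(1e12)
      -sum(betabin_logpmf(x, n, par[1], par[2]))
    }
    fit <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B",
                   lower = c(1e-6, 0), upper = c(1 - 1e-6, 0.5),
                   control = list(factr = 1e9)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) NULL
    else list(mu = fit$par[1], phi = fit$par[2], value = fit$value,
              conv = fit$convergence == 0)
  }
  fit <- ml(x, n, start)
  if (!is.null(fit) && trim > 0 && length(x) > 5L) {
    n_drop <- min(ceiling(trim * length(x)), length(x) - 5L)
    v <- n * fit$mu * (1 - fit$mu) * (1 + pmax(n - 1, 0) * fit$phi)
    z <- abs(x - n * fit$mu) / sqrt(pmax(v, 1e-12))
    keep <- order(z, decreasing = TRUE)[-seq_len(n_drop)]
    refit <- ml(x[keep], n[keep], c(fit$mu, fit$phi))
    if (!is.null(refit)) fit <- refit
  }
  if (is.null(fit)) {
    warning("beta-binomial optimisation failed; falling back to moment fit")
    out <- list(mu = mu0, phi = 1e-4,
                loglik = sum(betabin_logpmf(x, n, mu0, 1e-4)),
                converged = FALSE)
  } else {
    out <- list(mu = fit$mu, phi = fit$phi,
                loglik = sum(betabin_logpmf(x, n, fit$mu, max(fit$phi, 0))),
                converged = fit$conv)
  }
  class(out) <- "betabin_fit"
  out
}

#' @export
print.betabin_fit <- function(x, ...) {
  cat(sprintf("beta-binomial fit: mu = %.5f, phi = %.3g, loglik = %.2f%s\n",
              x$mu, x$phi, x$loglik,
              if (x$converged) "" else " (fallback)"))
  invisible(x)
}

## Expected log-likelihood ratio (nats) in favour of a heterozygous deletion,
## summed over targets, evaluated by K-point normal-quantile quadrature over
## the CN1 beta-binomial (moment-matched). Deterministic; used as the
## reference-set selection criterion.
expected_del_llr <- function(x_totals, mu, phi, K = 16L) {
  mu1 <- state_mean(mu, 1L)
  n <- x_totals[x_totals > 0]
  if (length(n) == 0L) return(0)
  z <- stats::qnorm((seq_len(K) - 0.5) / K)
  m1 <- n * mu1
  v1 <- n * mu1 * (1 - mu1) * (1 + (n - 1) * phi)
  xs <- round(outer(sqrt(v1), z) + m1)        # targets x K quadrature nodes
  nn <- matrix(n, length(n), K)
  xs <- pmin(pmax(xs, 0), nn)
  llr <- betabin_logpmf(xs, nn, mu1, phi) - betabin_logpmf(xs, nn, mu, phi)
  sum(rowMeans(matrix(llr, length(n), K)))
}

#' Select reference samples for a test sample
#'
#' Candidates are ranked by decreasing Pearson correlation with the test
#' sample; for each prefix of size k = 1..`max_refs` the chosen samples'
#' counts are summed into an aggregate reference, the beta-binomial model is
#' fitted, and the expected log-likelihood ratio in favour of a heterozygous
#' single-copy deletion (the hardest clinically relevant signal) is computed.
#' The prefix maximising this expected evidence is chosen; ties go to the
#' smaller reference set.
#'
#' @param m A `coverage_matrix` with at least 2 samples.
#' @param test_id Sample id of the sample of interest.
#' @param max_refs Maximum number of comparison samples (default 10).
#' @param trim Outlier-trimming fraction for the per-prefix model fits
#'   (default 0.06, i.e. the worst ~3 targets of a 49-target panel are
#'   excluded from the dispersion estimate so a real CNV in the test sample
#'   does not inflate `phi` and distort the selection).
#' @return List of class `reference_selection`: `test_id`, `candidate_order`,
#'   `correlations`, `chosen`, `ref_counts`, `n_comp`, `max_correlation`,
#'   `fit` (the `betabin_fit` for the chosen prefix) and `criterion` (the
#'   expected deletion evidence per prefix).
#' @export
select_reference <- function(m, test_id, max_refs = 10L, trim = 0.06) {
  r <- pairwise_correlation(m, test_id)
  if (length(r) == 0L) stop("no candidate reference samples for ", test_id)
  ord <- names(sort(r, decreasing = TRUE))
  kmax <- min(max_refs, length(ord))
  test <- m$counts[, test_id]
  crit <- rep(-Inf, kmax)
  fits <- vector("list", kmax)
  ref <- integer(nrow(m$counts))
  init <- NULL
  for (k in seq_len(kmax)) {
    ref <- ref + m$counts[, ord[k]]
    fk <- tryCatch(fit_betabin(test, ref, trim = trim, init = init),
                   error = function(e) NULL)
    if (is.null(fk)) next
    fits[[k]] <- fk
    init <- c(fk$mu, fk$phi)
    crit[k] <- expected_del_llr(test + ref, fk$mu, fk$phi)
  }
  if (all(!is.finite(crit))) stop("reference model could not be fitted for ", test_id)
  best <- which.max(crit)  # which.max takes the first (smallest k) on ties
  chosen <- ord[seq_len(best)]
  out <- list(test_id = test_id,
              candidate_order = ord,
              correlations = r[ord],
              chosen = chosen,
              ref_counts = as.integer(rowSums(m$counts[, chosen, drop = FALSE])),
              n_comp = best,
              max_correlation = unname(r[ord][1]),
              fit = fits[[best]],
              criterion = crit)
  class(out) <- "reference_selection"
  out
}

#' @export
print.reference_selection <- function(x, ...) {
  cat(sprintf(
    "reference selection for %s: %d of %d candidates (max correlation %.4f)\n",
    x$test_id, x$n_comp, length(x$candidate_order), x$max_correlation))
  invisible(x)
}
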