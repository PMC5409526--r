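## exhaustive path-score oracle for small instances
brute_force_best <- function(emissions, gaps, params) {
  K <- nrow(emissions)
  states <- as.matrix(expand.grid(rep(list(1:3), K)))
  lp0 <- log(initial_distribution(params))
  ltm <- lapply(gaps, function(d) log(transition_matrix(d, params)))
  score <- apply(states, 1, function(path) {
    s <- lp0[path[1]] + emissions[1, path[1]]
    if (K > 1L) for (t in 2:K) {
      s <- s + ltm[[t - 1L]][path[t - 1L], path[t]] + emissions[t, path[t]]
    }
    s
  })
  list(max = max(score), paths = states[score >= max(score) - 1e-9, ,
                                        drop = FALSE])
}

path_score <- function(path_idx, emissions, gaps, params) {
  K <- length(path_idx)
  s <- unname(log(initial_distribution(params))[path_idx[1]]) +
    emissions[1, path_idx[1]]
  if (K > 1L) for (t in 2:K) {
    s <- s + log(transition_matrix(gaps[t - 1L], params))[path_idx[t - 1L],
                                                          path_idx[t]] +
      emissions[t, path_idx[t]]
  }
  s
}

test_that("state_mean scales the proportion on the odds scale", {
  expect_equal(state_mean(0.5, 2L), 0.5)
  expect_equal(state_mean(0.5, 1L), 1 / 3)
  expect_equal(state_mean(0.5, 3L), 0.6)
  expect_equal(state_mean(0.2, 2L), 0.2)
  expect_error(state_mean(0.5, 4L), "copy number")
  expect_error(state_mean(1.2, 2L), "mu")
})

test_that("transition matrix honours its limits and is stochastic", {
  p <- hmm_params(q = 0.01, L = 5e4)
  t0 <- transition_matrix(0, p)
  expect_equal(unname(t0[1, 1]), 1)
  expect_equal(unname(t0[3, 3]), 1)
  tinf <- transition_matrix(Inf, p)
  prior <- c(0.01, 0.98, 0.01)
  for (r in 1:3) expect_equal(unname(tinf[r, ]), prior)
  for (d in c(0, 100, 1e4, 1e6)) {
    for (q in c(0.001, 0.01)) {
      tm <- transition_matrix(d, hmm_params(q = q, L = 5e4))
      expect_equal(unname(rowSums(tm)), c(1, 1, 1), tolerance = 1e-12)
    }
  }
})

test_that("CNV stay-probability is strictly decreasing in distance", {
  p <- hmm_params()
  ds <- c(0, 10, 1e3, 1e4, 1e5, 1e6)
  stay <- vapply(ds, function(d) transition_matrix(d, p)[1, 1], numeric(1))
  expect_true(all(diff(stay) < 0))
})

test_that("initial distribution is the prior row", {
  p <- hmm_params(q = 0.01)
  expect_equal(unname(initial_distribution(p)), c(0.01, 0.98, 0.01))
  for (q in c(0.001, 0.2)) {
    pi0 <- initial_distribution(hmm_params(q = q))
    expect_equal(sum(pi0), 1)
    expect_equal(unname(pi0), unname(transition_matrix(Inf, hmm_params(q = q))[2, ]))
  }
  expect_error(hmm_params(q = 0.6), "q must")
  expect_error(hmm_params(L = -1), "L must")
})

test_that("viterbi decodes all-normal under equal emissions", {
  p <- hmm_params()
  em <- matrix(-3, 6, 3)
  expect_equal(viterbi(em, rep(1000, 5), p), rep("normal", 6))
  expect_equal(viterbi(matrix(-1, 0, 3), numeric(0), p), character(0))
})

test_that("a single decisive emission is called", {
  p <- hmm_params(q = 0.01)
  ## threshold: delta loglik must beat log((1-2q)/q)
  thr <- log((1 - 2 * p$q) / p$q)
  em <- matrix(c(-1, -1 - thr - 0.1, -5), 1, 3)
  expect_equal(viterbi(em, numeric(0), p), "del")
  em2 <- matrix(c(-1, -1 - thr + 0.1, -5), 1, 3)
  expect_equal(viterbi(em2, numeric(0), p), "normal")
})

test_that("viterbi matches the exhaustive 3^K oracle on 50 random instances", {
  set.seed(31)
  p <- hmm_params()
  for (i in 1:50) {
    K <- sample(1:8, 1)
    em <- matrix(rnorm(K * 3, -5, 2), K, 3)
    gaps <- if (K > 1) sample(c(0, 500, 5e4, Inf), K - 1, replace = TRUE)
            else numeric(0)
    path <- viterbi(em, gaps, p)
    idx <- match(path, c("del", "normal", "dup"))
    oracle <- brute_force_best(em, gaps, p)
    expect_equal(path_score(idx, em, gaps, p), oracle$max, tolerance = 1e-9)
  }
})

test_that("viterbi validates its inputs", {
  p <- hmm_params()
  em <- matrix(-1, 3, 3)
  expect_error(viterbi(em, c(10), p), "length")
  em[2, 2] <- -Inf
  expect_error(viterbi(em, c(10, 10), p), "finite")
})

test_that("segment_calls turns runs into calls with correct arithmetic", {
  tg <- tiny_targets()
  test <- c(500L, 250L, 250L, 500L)
  ref <- c(500L, 500L, 500L, 500L)
  fit <- structure(list(mu = 0.5, phi = 0.001, loglik = 0, converged = TRUE),
                   class = "betabin_fit")
  sel <- list(test_id = "X", max_correlation = 0.999, n_comp = 3L)
  expect_equal(nrow(segment_calls(rep("normal", 4), tg, test, ref, fit, sel)),
               0L)
  calls <- segment_calls(c("normal", "del", "del", "normal"), tg, test, ref,
                         fit, sel)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_exons, 2L)
  expect_equal(calls$first_target, 2L)
  expect_equal(calls$last_target, 3L)
  expect_equal(calls$cnv_type, "deletion")
  expect_gt(calls$bf, 0)
  expect_equal(calls$start, tg$start[2] + 1L)
  expect_equal(calls$end, tg$end[3])
})

test_that("runs never span chromosome boundaries", {
  tg <- tiny_targets()   # targets 3 and 4 are on different chromosomes
  test <- c(500L, 500L, 250L, 250L)
  ref <- rep(500L, 4)
  fit <- structure(list(mu = 0.5, phi = 0.001, loglik = 0, converged = TRUE),
                   class = "betabin_fit")
  sel <- list(test_id = "X", max_correlation = 0.999, n_comp = 3L)
  calls <- segment_calls(c("normal", "normal", "del", "del"), tg, test, ref,
                         fit, sel)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$chrom, c("chr1", "chr2"))
})

test_that("a spiked 50% single-exon reduction has reads_ratio 0.5", {
  tg <- make_panel(seed = 8)[1:10, ]
  test <- rep(1000L, 10); test[4] <- 500L
  ref <- rep(1000L, 10)
  fit <- structure(list(mu = 0.5, phi = 1e-3, loglik = 0, converged = TRUE),
                   class = "betabin_fit")
  sel <- list(test_id = "X", max_correlation = 1, n_comp = 1L)
  path <- rep("normal", 10); path[4] <- "del"
  calls <- segment_calls(path, as_target_set(tg), test, ref, fit, sel)
  ## expected = round((500 + 1000) * 0.5) = 750; observed = 500
  expect_equal(calls$reads_observed, 500)
  expect_equal(calls$reads_ratio, 500 / 750)
})

test_that("cnv_call recovers an implanted 3-exon deletion exactly", {
  panel <- make_panel(seed = 7)
  pool <- simulate_pool(sim_spec(
    n_samples = 48, seed = 21,
    implants = list(list(sample = 5, gene = "GENEA", exons = c(7, 9),
                         kind = "deletion"))), panel)
  fit <- cnv_call(pool$matrix, "S05")
  expect_equal(nrow(fit$calls), 1L)
  expect_equal(fit$calls$cnv_type, "deletion")
  expect_equal(fit$calls$first_target, pool$truth$first_target)
  expect_equal(fit$calls$last_target, pool$truth$last_target)
  expect_lt(fit$calls$reads_ratio, 1)
  expect_gt(fit$calls$bf, 0)
})

test_that("a test sample identical to all references yields no calls", {
  tg <- make_panel(seed = 9)
  set.seed(5)
  base <- as.integer(round(rlnorm(nrow(tg), log(900), 0.5)))
  cnt <- cbind(A = base, B = base, C = base, D = base)
  m <- coverage_matrix(tg, cnt)
  fit <- cnv_call(m, "A")
  expect_equal(nrow(fit$calls), 0L)
})

test_that("a whole-gene duplication is called on a three-gene panel", {
  panel <- make_panel(panel3_model(), seed = 13)
  pool <- simulate_pool(sim_spec(
    n_samples = 48, seed = 22,
    implants = list(list(sample = 3, gene = "GENEB", exons = c(1, 26),
                         kind = "duplication"))), panel)
  fit <- cnv_call(pool$matrix, "S03")
  dup <- fit$calls[fit$calls$cnv_type == "duplication", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$first_target, pool$truth$first_target)
  expect_equal(dup$last_target, pool$truth$last_target)
  expect_gt(dup$reads_ratio, 1)
})

test_that("calls are invariant under reference column permutation", {
  pool <- default_pool()
  m <- pool$matrix
  sm <- spike_exon(m, spike_spec("S10", 12L, "deletion"))
  fit1 <- cnv_call(sm, "S10")
  perm <- sm
  set.seed(88)
  ord <- c("S10", sample(setdiff(colnames(sm$counts), "S10")))
  perm$counts <- sm$counts[, ord]
  fit2 <- cnv_call(perm, "S10")
  expect_equal(fit1$calls[, c("cnv_type", "first_target", "last_target")],
               fit2$calls[, c("cnv_type", "first_target", "last_target")])
  expect_equal(fit1$calls$bf, fit2$calls$bf, tolerance = 1e-6)
})

test_that("raising q never decreases the number of called segments", {
  panel <- make_panel(seed = 14)
  for (s in 1:10) {
    pool <- simulate_pool(sim_spec(n_samples = 12, seed = 300 + s), panel)
    sm <- spike_exon(pool$matrix, spike_spec("S02", 5L + s, "deletion"))
    n_calls <- vapply(c(0.001, 0.01, 0.05), function(q)
      nrow(cnv_call(sm, "S02", params = hmm_params(q = q))$calls), numeric(1))
    expect_true(all(diff(n_calls) >= 0))
  }
})

test_that("cnv_fit methods expose the model in the standard idiom", {
  pool <- default_pool()
  sm <- spike_exon(pool$matrix, spike_spec("S07", 20L, "duplication"))
  fit <- cnv_call(sm, "S07")
  expect_s3_class(fit, "cnv_fit")
  expect_named(coef(fit), c("mu", "phi"))
  expect_length(residuals(fit), nrow(sm$counts))
  expect_output(print(fit), "CNV calls for sample S07")
  expect_output(summary(fit), "max correlation")
  ## the duplicated target's ratio must exceed 1
  expect_gt(residuals(fit)[20], 1)
})
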