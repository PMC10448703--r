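test_that("relative error is exact on trivial decompositions", {
  sep <- make_separated_cp(c(6, 5, 4), 1, seed = 1)
  fit <- nn_cpd(sep$tensor, R = 1, seed = 2)
  expect_lt(relative_error(fit, sep$tensor), 1e-8)
  # an all-zero-weight model reconstructs nothing: error 1
  zfit <- fit
  zfit$lambda <- 0
  expect_equal(relative_error(zfit, sep$tensor), 1)
  expect_error(relative_error(fit, array(0, c(6, 5, 4))), "zero tensor")
})

test_that("best rank-1 fit of a perturbed rank-1 tensor stays within the
           perturbation norm", {
  set.seed(42)
  sep <- make_separated_cp(c(8, 7, 6), 1, seed = 5)
  x <- sep$tensor
  noise <- array(abs(rnorm(length(x))), dim(x))
  eps <- 0.05
  noise <- noise * (eps * sqrt(sum(x^2)) / sqrt(sum(noise^2)))
  fit <- nn_cpd(x + noise, R = 1, seed = 1)
  # Eckart-Young-type bound: the best rank-1 approximation cannot do worse
  # than the unperturbed tensor itself
  expect_lte(fit$rel_error, eps / sqrt(sum((x + noise)^2) / sum(x^2)) + 1e-6)
})

test_that("an exact nonnegative rank-1 tensor is recovered to scale", {
  a <- abs(rnorm(9)) + 0.1; b <- abs(rnorm(8)) + 0.1; c <- abs(rnorm(7)) + 0.1
  x <- outer(outer(a, b), c)
  fit <- nn_cpd(x, R = 1, seed = 3)
  expect_lt(fit$rel_error, 1e-6)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_gt(cosine(fit$factors[[1]][, 1], a), 0.999)
  expect_gt(cosine(fit$factors[[2]][, 1], b), 0.999)
  expect_gt(cosine(fit$factors[[3]][, 1], c), 0.999)
})

test_that("well-separated rank-3 factors are recovered with high congruence", {
  sep <- make_separated_cp(c(30, 20, 15, 10), 3, seed = 7)
  fit <- nn_cpd(sep$tensor, R = 3, seed = 1)
  expect_lt(fit$rel_error, 1e-6)
  for (n in 1:4) {
    cong <- congruence_match(fit$factors[[n]], sep$factors[[n]])
    expect_gt(min(cong), 0.95)
  }
})

test_that("CPD is deterministic given a seed and components are unit norm", {
  sep <- make_separated_cp(c(10, 9, 8), 2, seed = 2)
  f1 <- nn_cpd(sep$tensor, 2, seed = 11)
  f2 <- nn_cpd(sep$tensor, 2, seed = 11)
  expect_identical(f1$factors, f2$factors)
  expect_identical(f1$lambda, f2$lambda)
  for (M in f1$factors) {
    expect_true(all(M >= 0))
    expect_equal(colSums(M^2), rep(1, 2), tolerance = 1e-12)
  }
  expect_true(all(diff(f1$lambda) <= 0))
})

test_that("the ALS objective decreases monotonically", {
  set.seed(8)
  x <- array(abs(rnorm(6 * 5 * 4 * 3)), c(6, 5, 4, 3))
  fit <- nn_cpd(x, R = 3, seed = 4, max_iter = 100)
  expect_true(all(diff(fit$error_trace) <= 1e-10))
  # reported error is self-consistent with an explicit reconstruction
  recon <- cp_reconstruct_oracle(fit$factors, fit$lambda)
  direct <- sqrt(sum((x - recon)^2) / sum(x^2))
  expect_equal(fit$rel_error, direct, tolerance = 1e-12)
})

test_that("the ensemble derives distinct reproducible seeds per run", {
  sep <- make_separated_cp(c(8, 7, 6), 2, seed = 3)
  runs <- run_cpd_ensemble(sep$tensor, 2, n_runs = 10, seed = 5,
                           max_iter = 50)
  expect_length(runs, 10L)
  expect_equal(vapply(runs, `[[`, 1, "seed"), 5 + 1:10)
  runs2 <- run_cpd_ensemble(sep$tensor, 2, n_runs = 10, seed = 5,
                            max_iter = 50)
  expect_identical(lapply(runs, `[[`, "factors"),
                   lapply(runs2, `[[`, "factors"))
  expect_length(run_cpd_ensemble(sep$tensor, 2, n_runs = 1, max_iter = 5), 1L)
})

test_that("rank selection finds the true rank of a noiseless tensor", {
  sep <- make_separated_cp(c(12, 10, 8), 2, seed = 9)
  sel <- select_rank_cpd(sep$tensor, r_max = 4)
  expect_equal(sel$rank, 2L)
  expect_true(sel$met)
  # the fitted curve drops below threshold exactly at the true rank
  expect_gte(sel$error_curve[1], 0.10)
  expect_lt(sel$error_curve[2], 0.10)
  # any-fit threshold selects rank 1
  expect_equal(select_rank_cpd(sep$tensor, 4, error_threshold = 1)$rank, 1L)
  # an unreachable threshold falls back to r_max with a warning flag
  set.seed(14)
  noisy <- sep$tensor + array(abs(rnorm(length(sep$tensor))), dim(sep$tensor))
  expect_warning(sel0 <- select_rank_cpd(noisy, 2, error_threshold = 0.01,
                                         max_iter = 30))
  expect_false(sel0$met)
  expect_equal(sel0$rank, 2L)
})

test_that("HOOI is lossless at full ranks and recovers exact Tucker models", {
  set.seed(10)
  y <- array(rnorm(8 * 6 * 5), c(8, 6, 5))
  full <- orthogonal_tucker(y, c(8, 6))
  expect_lt(full$rel_error, 1e-10)

  # constructed instance with multilinear ranks (3, 2)
  G <- array(rnorm(3 * 2 * 5), c(3, 2, 5))
  At <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
  Ac <- qr.Q(qr(matrix(rnorm(7 * 2), 7, 2)))
  y2 <- G
  y2 <- ttm_oracle(y2, At, 1)
  y2 <- ttm_oracle(y2, Ac, 2)
  fit <- orthogonal_tucker(y2, c(3, 2))
  expect_lt(fit$rel_error, 1e-8)
  expect_error(orthogonal_tucker(y2, c(20, 2)), "within mode dimensions")
  expect_error(orthogonal_tucker(y2, c(3, 2, 4)), "subject mode")
})

test_that("HOOI factors are orthonormal, fit is monotone and beats HOSVD", {
  set.seed(11)
  for (i in 1:20) {
    y <- array(rnorm(10 * 8 * 6), c(10, 8, 6))
    fit <- orthogonal_tucker(y, c(3, 3))
    for (M in fit$factors[c("time", "channel")])
      expect_lt(max(abs(crossprod(M) - diag(ncol(M)))), 1e-10)
    # per-sweep residual is nonincreasing
    expect_true(all(diff(fit$fit_trace) <= 1e-12))
    # truncated-HOSVD reference: project onto leading singular subspaces
    A1 <- svd(matrix(y, 10))$u[, 1:3]
    A2 <- svd(matrix(aperm(y, c(2, 1, 3)), 8))$u[, 1:3]
    proj <- ttm_oracle(ttm_oracle(y, tcrossprod(A1), 1), tcrossprod(A2), 2)
    hosvd_err <- sqrt(sum((y - proj)^2) / sum(y^2))
    expect_lte(fit$rel_error, hosvd_err + 1e-12)
  }
})

test_that("reported Tucker error is self-consistent with reconstruction", {
  set.seed(12)
  y <- array(rnorm(9 * 7 * 4), c(9, 7, 4))
  fit <- orthogonal_tucker(y, c(4, 3))
  recon <- ttm_oracle(ttm_oracle(fit$core, fit$factors$time, 1),
                      fit$factors$channel, 2)
  expect_equal(fit$rel_error, sqrt(sum((y - recon)^2) / sum(y^2)),
               tolerance = 1e-12)
})

test_that("Tucker rank selection honours thresholds and tie-breaking", {
  set.seed(13)
  # exact multilinear rank (3, 2) instance
  G <- array(rnorm(3 * 2 * 6), c(3, 2, 6))
  At <- qr.Q(qr(matrix(rnorm(15 * 3), 15, 3)))
  Ac <- qr.Q(qr(matrix(rnorm(8 * 2), 8, 2)))
  y <- ttm_oracle(ttm_oracle(G, At, 1), Ac, 2)
  sel <- select_ranks_td(y, error_threshold = 1e-8)
  expect_equal(unname(sel$ranks), c(3, 2))
  expect_true(sel$met)
  # full ranks always satisfy any positive threshold
  expect_lt(sel$error_surface[15, 8], 1e-12)
  # impossible threshold falls back to the caps with a warning
  expect_warning(s0 <- select_ranks_td(y, rt_max = 2, rc_max = 1,
                                       error_threshold = 1e-12))
  expect_false(s0$met)
  expect_equal(unname(s0$ranks), c(2, 1))
})
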