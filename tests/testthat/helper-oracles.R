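# Independent oracles and small fixture builders used across the suite.

# --- Type III sums of squares for a 2x2 between design, via explicit
# regression projections with sum-to-zero coding (no lm/car involved).
oracle_anova_between <- function(score, a, b) {
  stopifnot(length(score) == length(a), length(a) == length(b))
  ca <- ifelse(a == sort(unique(a))[1], 1, -1)
  cb <- ifelse(b == sort(unique(b))[1], 1, -1)
  X <- cbind(1, ca, cb, ca * cb)
  rss <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    beta <- solve(crossprod(Xs), crossprod(Xs, score))
    sum((score - Xs %*% beta)^2)
  }
  full <- rss(1:4)
  df_err <- length(score) - 4
  ms_err <- full / df_err
  Fp <- function(drop_col) {
    ss <- rss(setdiff(1:4, drop_col)) - full
    F <- ss / ms_err
    c(F = F, p = stats::pf(F, 1, df_err, lower.tail = FALSE))
  }
  list(main_a = Fp(2), main_b = Fp(3), interaction = Fp(4))
}

# --- balanced mixed-model 2x2 ANOVA from the classical sums of squares
# (g: between-group label per observation, w: within level, s: subject id)
oracle_anova_mixed <- function(y, g, w, s) {
  gm <- mean(y)
  subj_means <- tapply(y, s, mean)
  subj_group <- tapply(g, s, function(v) v[1])
  groups <- sort(unique(g)); withins <- sort(unique(w))
  n_g <- table(subj_group)
  N <- length(subj_means)
  grp_means <- tapply(y, g, mean)
  w_means <- tapply(y, w, mean)
  cell_means <- tapply(y, list(g, w), mean)

  ss_g <- sum(2 * n_g[groups] * (grp_means[groups] - gm)^2)
  ss_subj <- 2 * sum((subj_means - grp_means[as.character(subj_group)])^2)
  ss_w <- sum(N * (w_means - gm)^2)
  ss_gw <- 0
  for (gg in groups) for (ww in withins)
    ss_gw <- ss_gw + n_g[[gg]] *
      (cell_means[gg, ww] - grp_means[[gg]] - w_means[[ww]] + gm)^2
  ss_err <- 0
  for (i in seq_along(y)) {
    gi <- g[i]; wi <- w[i]; si <- as.character(s[i])
    ss_err <- ss_err + (y[i] - subj_means[[si]] - cell_means[gi, wi] +
                          grp_means[[gi]])^2
  }
  df_subj <- N - length(groups)
  Fg <- (ss_g / (length(groups) - 1)) / (ss_subj / df_subj)
  Fw <- (ss_w / (length(withins) - 1)) / (ss_err / df_subj)
  Fgw <- (ss_gw / 1) / (ss_err / df_subj)
  list(
    G = c(F = Fg, p = stats::pf(Fg, 1, df_subj, lower.tail = FALSE)),
    W = c(F = Fw, p = stats::pf(Fw, 1, df_subj, lower.tail = FALSE)),
    GW = c(F = Fgw, p = stats::pf(Fgw, 1, df_subj, lower.tail = FALSE))
  )
}

# --- JZS Bayes factor via the marginal likelihood of the t statistic under
# a Cauchy effect-size prior (noncentral-t formulation, independent of the
# package's inverse-gamma integral)
oracle_jzs_bf <- function(t, n1, n2 = NULL, rscale = 0.707) {
  if (is.null(n2)) { N <- n1; df <- n1 - 1 }
  else { N <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2 }
  # dt(ncp=...) warns about precision near machine accuracy; harmless here
  m1 <- suppressWarnings(stats::integrate(function(d)
    stats::dt(t, df, ncp = d * sqrt(N)) * stats::dcauchy(d, 0, rscale),
    -Inf, Inf, rel.tol = 1e-10)$value)
  m1 / stats::dt(t, df)
}

# --- congruence (cosine) matching of estimated factor columns to ground
# truth, greedy over the best remaining pair
congruence_match <- function(est, truth) {
  cos_mat <- abs(crossprod(
    sweep(est, 2, sqrt(colSums(est^2)), `/`),
    sweep(truth, 2, sqrt(colSums(truth^2)), `/`)))
  R <- ncol(truth)
  out <- numeric(R)
  for (k in seq_len(R)) {
    i <- which(cos_mat == max(cos_mat), arr.ind = TRUE)[1, ]
    out[k] <- cos_mat[i[1], i[2]]
    cos_mat[i[1], ] <- -1
    cos_mat[, i[2]] <- -1
  }
  sort(out, decreasing = TRUE)
}

# --- random nonnegative CP tensor with well-separated factors (block
# supports) plus its generating factors
make_separated_cp <- function(dims, R, seed = 1, overlap = 0) {
  set.seed(seed)
  factors <- lapply(dims, function(In) {
    M <- matrix(0, In, R)
    cut <- floor(seq(0, In, length.out = R + 1))
    for (r in seq_len(R)) {
      idx <- (cut[r] + 1):cut[r + 1]
      M[idx, r] <- stats::runif(length(idx), 0.5, 1.5)
      if (overlap > 0) M[, r] <- M[, r] + overlap * stats::runif(In)
    }
    M
  })
  lambda <- rep(1, R)
  list(tensor = cp_reconstruct_oracle(factors), factors = factors)
}

# reconstruction by naive outer-product summation (independent of the
# package's unfolding-based reconstruction)
cp_reconstruct_oracle <- function(factors, lambda = NULL) {
  R <- ncol(factors[[1]])
  lambda <- lambda %||% rep(1, R)
  dims <- vapply(factors, nrow, 1L)
  out <- array(0, dims)
  for (r in seq_len(R)) {
    comp <- Reduce(function(acc, f) outer(acc, f[, r]), factors[-1],
                   factors[[1]][, r])
    out <- out + lambda[r] * comp
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classical pooled two-sample t statistic
two_sample_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# mode-n tensor-times-matrix, written out longhand for use as an oracle
ttm_oracle <- function(x, m, mode) {
  d <- dim(x)
  perm <- c(mode, seq_along(d)[-mode])
  xp <- aperm(x, perm)
  dim(xp) <- c(d[mode], prod(d[-mode]))
  arr <- array(m %*% xp, c(nrow(m), d[-mode]))
  aperm(arr, order(perm))
}

# small list of synthetic subject HRFs on a common epoch for tensor tests
make_hrf_set <- function(n_subjects, epoch, channels = c("ch01", "ch02"),
                         scope_a = "between", seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    la <- if (scope_a == "between") sample(c("a1", "a2"), 1) else "a1"
    subject_hrf(sprintf("s%03d", i), la, sample(c("b1", "b2"), 1),
                matrix(rnorm(epoch$n_samples * length(channels)),
                       epoch$n_samples, length(channels)),
                epoch, channels, n_trials = 3)
  })
}
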