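# Dense tensor algebra: unfoldings, Khatri-Rao products and mode products.
# Convention: unfold(x, n) puts mode n on the rows; the columns run over the
# remaining modes in their original order with the first of them varying
# fastest.  krao() builds the matching Khatri-Rao product (first matrix in
# the list varies fastest down the rows), so that a CP model satisfies
# unfold(X, n) = A[[n]] %*% diag(lambda) %*% t(krao(A[-n])).

tensor_unfold <- function(x, mode) {
  d <- dim(x)
  n <- length(d)
  stopifnot(mode >= 1, mode <= n)
  perm <- c(mode, seq_len(n)[-mode])
  m <- aperm(x, perm)
  dim(m) <- c(d[mode], prod(d[-mode]))
  m
}

tensor_fold <- function(mat, mode, dims) {
  n <- length(dims)
  arr <- array(mat, c(dims[mode], dims[-mode]))
  aperm(arr, order(c(mode, seq_len(n)[-mode])))
}

# Khatri-Rao (column-wise Kronecker) of a list of matrices with equal column
# counts; rows of mats[[1]] vary fastest.
krao <- function(mats) {
  Reduce(function(acc, m) {
    na <- nrow(acc); nm <- nrow(m)
    acc[rep(seq_len(na), times = nm), , drop = FALSE] *
      m[rep(seq_len(nm), each = na), , drop = FALSE]
  }, mats)
}

# mode-n product: tensor x multiplied by matrix m along mode `mode`
ttm <- function(x, m, mode) {
  d <- dim(x)
  res <- m %*% tensor_unfold(x, mode)
  d[mode] <- nrow(m)
  tensor_fold(res, mode, d)
}

fnorm <- function(x) sqrt(sum(x^2))

cp_reconstruct <- function(factors, lambda) {
  dims <- vapply(factors, nrow, 1L)
  m <- factors[[1]] %*% (t(krao(factors[-1])) * lambda)
  tensor_fold(m, 1L, dims)
}

tucker_reconstruct <- function(core, factors) {
  out <- core
  for (n in seq_along(factors)) out <- ttm(out, factors[[n]], n)
  out
}
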