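#' Nonnegative canonical polyadic decomposition (HALS alternating least squares)
#'
#' Fits \eqn{X \approx \sum_{r=1}^{R} \lambda_r \, u_r^{(1)} \circ \cdots
#' \circ u_r^{(N)}} with all factor entries nonnegative, by block-coordinate
#' nonnegative least squares (HALS column updates) cycling over the modes.
#' The objective is nonincreasing across iterations; on return each factor
#' column has unit L2 norm with the component magnitudes collected in
#' `lambda`, and components are ordered by decreasing `lambda`.
#'
#' @param tensor nonnegative array (3 or more modes), or a
#'   [hemodynamic_tensor()]
#' @param R number of components (>= 1)
#' @param seed seed for the random nonnegative initialisation
#' @param max_iter maximum ALS sweeps (default 500)
#' @param tol stop when the relative change of the squared residual falls
#'   below this (default 1e-8)
#' @return an object of class `nn_cpd`: factor matrices (`factors`, one per
#'   mode, unit-norm columns), `lambda`, `R`, `rel_error` (relative Frobenius
#'   reconstruction error), the per-sweep error trace, iteration count and
#'   the seed used
#' @seealso [relative_error()], [run_cpd_ensemble()], [select_rank_cpd()]
#' @examples
#' a <- abs(rnorm(6)); b <- abs(rnorm(5)); c <- abs(rnorm(4))
#' x <- outer(outer(a, b), c)
#' fit <- nn_cpd(x, R = 1, seed = 1)
#' fit$rel_error  # ~0
#' @export
nn_cpd <- function(tensor, R, seed = 1, max_iter = 500, tol = 1e-8) {
  meta <- NULL
  if (inherits(tensor, "hemodynamic_tensor")) {
    meta <- tensor[c("mode_axes", "hemisphere", "subjects", "design")]
    tensor <- tensor$data
  }
  if (!all(is.finite(tensor))) nt_stop("tensor contains non-finite entries")
  if (any(tensor < 0)) nt_stop("nonnegative CPD requires a nonnegative tensor")
  if (R < 1) nt_stop("R must be >= 1")
  d <- dim(tensor)
  N <- length(d)
  if (N < 3) nt_stop("tensor must have at least 3 modes")
  normX2 <- sum(tensor^2)
  if (normX2 == 0) nt_stop("zero tensor has no meaningful decomposition")

  unfoldings <- lapply(seq_len(N), function(n) tensor_unfold(tensor, n))

  # initialise from the absolute leading singular vectors of each unfolding,
  # with seeded multiplicative jitter so restarts explore distinct basins
  set.seed(seed)
  A <- lapply(seq_len(N), function(n) {
    Xn <- unfoldings[[n]]
    k <- min(R, dim(Xn))
    sv <- svd(Xn, nu = k, nv = 0)
    M <- matrix(stats::runif(d[n] * R), d[n], R)
    M[, seq_len(k)] <- abs(sv$u[, seq_len(k), drop = FALSE])
    M * (0.5 + stats::runif(length(M))) + 0.01 * mean(M)
  })
  # scale initial factors so the model magnitude matches the data
  s0 <- sum(Reduce(`*`, lapply(A, crossprod)))
  if (s0 > 0) A <- lapply(A, function(M) M * (normX2 / s0)^(1 / (2 * N)))
  grams <- lapply(A, crossprod)
  eps <- 1e-16
  trace <- numeric(0)
  prev_f <- Inf
  iter <- 0
  converged <- FALSE

  while (iter < max_iter) {
    iter <- iter + 1
    for (n in seq_len(N)) {
      G <- Reduce(`*`, grams[-n])              # R x R Hadamard of Grams
      W <- unfoldings[[n]] %*% krao(A[-n])     # In x R MTTKRP
      An <- A[[n]]
      for (r in seq_len(R)) {
        # tiny ridge keeps the update defined if a column collapses
        a <- An[, r] + (W[, r] - An %*% G[, r]) / (G[r, r] + 1e-12)
        a[a < 0] <- 0
        if (all(a == 0)) a[] <- eps
        An[, r] <- a
      }
      A[[n]] <- An
      grams[[n]] <- crossprod(An)
      if (n == N) {
        f <- normX2 - 2 * sum(An * W) + sum(grams[[n]] * G)
        f <- max(f, 0)
      }
    }
    trace <- c(trace, sqrt(f) / sqrt(normX2))
    if (iter >= 10 && is.finite(prev_f) &&
        abs(prev_f - f) <= tol * max(prev_f, eps)) {
      converged <- TRUE
      prev_f <- f
      break
    }
    prev_f <- f
  }

  # normalise columns to unit L2 norm; magnitudes into lambda
  lambda <- rep(1, R)
  for (n in seq_len(N)) {
    nrm <- sqrt(colSums(A[[n]]^2))
    zero <- nrm == 0
    lambda <- lambda * ifelse(zero, 0, nrm)
    A[[n]] <- sweep(A[[n]], 2, ifelse(zero, 1, nrm), `/`)
    if (any(zero)) A[[n]][, zero] <- 1 / sqrt(d[n])
  }
  ord <- order(lambda, decreasing = TRUE)
  lambda <- lambda[ord]
  A <- lapply(A, function(M) M[, ord, drop = FALSE])

  mode_names <- if (!is.null(meta)) names(meta$mode_axes)
                else paste0("mode", seq_len(N))
  names(A) <- mode_names
  fit <- structure(list(
    factors = A, lambda = lambda, R = as.integer(R), dims = d,
    rel_error = NA_real_, error_trace = trace, iterations = iter,
    converged = converged, seed = seed, meta = meta,
    call = match.call()
  ), class = "nn_cpd")
  fit$rel_error <- relative_error(fit, tensor)
  fit
}

#' Relative Frobenius reconstruction error
#'
#' `||tensor - reconstruction||_F / ||tensor||_F` for a fitted decomposition.
#'
#' @param model a fitted `nn_cpd` or `tucker_model`
#' @param tensor the array (or [hemodynamic_tensor()]) the model was fit to
#' @return scalar relative error (>= 0); errors on a zero tensor
#' @export
relative_error <- function(model, tensor) UseMethod("relative_error")

#' @export
relative_error.nn_cpd <- function(model, tensor) {
  if (inherits(tensor, "hemodynamic_tensor")) tensor <- tensor$data
  nx <- fnorm(tensor)
  if (nx == 0) nt_stop("relative error undefined for a zero tensor")
  fnorm(tensor - cp_reconstruct(model$factors, model$lambda)) / nx
}

#' Run the nonnegative CPD several times from distinct starts
#'
#' The decomposition is not unique, so it is rerun (ten times in the
#' reference analysis) from different deterministic seeds derived from the
#' master seed; consensus screening then pools the runs.
#'
#' @param tensor nonnegative array or [hemodynamic_tensor()]
#' @param R number of components per run
#' @param n_runs number of runs (>= 1, default 10)
#' @param seed master seed; run `k` uses `seed + k`
#' @param ... passed to [nn_cpd()]
#' @return list of `nn_cpd` models of length `n_runs`
#' @export
run_cpd_ensemble <- function(tensor, R, n_runs = 10, seed = 1, ...) {
  if (n_runs < 1) nt_stop("n_runs must be >= 1")
  lapply(seq_len(n_runs), function(k) nn_cpd(tensor, R, seed = seed + k, ...))
}

#' Select the CPD rank from the relative-error curve
#'
#' Fits ranks `1..r_max` (one run each, from a fixed audit seed derived from
#' the master seed and distinct from the ensemble seeds) and returns the
#' smallest rank whose relative reconstruction error drops below
#' `error_threshold` (default 10%).  If no rank qualifies, `r_max` is
#' returned with a warning flag; the full error curve is returned for audit.
#'
#' @param tensor nonnegative array or [hemodynamic_tensor()]
#' @param r_max largest rank scanned (>= 1)
#' @param error_threshold relative-error acceptance threshold (default 0.10)
#' @param seed master seed
#' @param ... passed to [nn_cpd()]
#' @return an object of class `cpd_rank_selection`: `rank`, `error_curve`,
#'   `threshold`, `met` (logical: did any rank meet the threshold)
#' @export
select_rank_cpd <- function(tensor, r_max, error_threshold = 0.10, seed = 1,
                            ...) {
  if (r_max < 1) nt_stop("r_max must be >= 1")
  audit_seed <- nt_substream(seed, 9973L)
  curve <- vapply(seq_len(r_max), function(R)
    nn_cpd(tensor, R, seed = audit_seed, ...)$rel_error, 1)
  hit <- which(curve < error_threshold)
  met <- length(hit) > 0
  if (!met)
    warning(sprintf("no rank up to %d reaches relative error < %g; using %d",
                    r_max, error_threshold, r_max), call. = FALSE)
  structure(list(rank = if (met) min(hit) else as.integer(r_max),
                 error_curve = curve, threshold = error_threshold, met = met,
                 seed = audit_seed),
            class = "cpd_rank_selection")
}

#' @export
print.cpd_rank_selection <- function(x, ...) {
  cat(sprintf("CPD rank selection: R = %d (threshold %.3g%s)\n", x$rank,
              x$threshold, if (x$met) "" else ", NOT met"))
  cat("error curve:", paste(sprintf("%.4f", x$error_curve), collapse = " "), "\n")
  invisible(x)
}
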