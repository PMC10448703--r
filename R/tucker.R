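#' Orthogonal Tucker decomposition by higher-order orthogonal iteration
#'
#' Fits \eqn{Y \approx G \times_1 A^{(t)} \times_2 A^{(c)} \times_3 A^{(s)}}
#' for a 3-way (time x channel x subject) tensor.  The temporal and channel
#' factors have orthonormal columns; the subject mode is *not* compressed
#' (its rank equals the subject dimension and \eqn{A^{(s)}} is the identity),
#' so every subject keeps its own row of core scores for the component-wise
#' ANOVA.  Initialisation is the truncated higher-order SVD, refined by
#' higher-order orthogonal iteration (HOOI); the fit is nondecreasing per
#' sweep.
#'
#' @param tensor 3-way array or [hemodynamic_tensor()]
#' @param ranks `c(Rt, Rc)` or `c(Rt, Rc, Is)`; a third entry must equal the
#'   subject dimension
#' @param tol stop when the relative change of the squared residual falls
#'   below this (default 1e-8)
#' @param max_iter maximum HOOI sweeps (default 200)
#' @return an object of class `tucker_model`: `core` (Rt x Rc x Is),
#'   `factors` (list `time`, `channel`, `subject`), `ranks`, `rel_error`,
#'   per-sweep `fit_trace`, iteration count
#' @seealso [select_ranks_td()], [relative_error()]
#' @export
orthogonal_tucker <- function(tensor, ranks, tol = 1e-8, max_iter = 200) {
  meta <- NULL
  if (inherits(tensor, "hemodynamic_tensor")) {
    meta <- tensor[c("mode_axes", "hemisphere", "subjects", "design")]
    tensor <- tensor$data
  }
  d <- dim(tensor)
  if (length(d) != 3) nt_stop("orthogonal_tucker expects a 3-way tensor")
  ranks <- unname(ranks)
  if (length(ranks) == 3) {
    if (ranks[3] != d[3])
      nt_stop("subject mode is not compressed: third rank must equal %d", d[3])
    ranks <- ranks[1:2]
  }
  if (length(ranks) != 2) nt_stop("ranks must be c(Rt, Rc) or c(Rt, Rc, Is)")
  if (ranks[1] < 1 || ranks[2] < 1 || ranks[1] > d[1] || ranks[2] > d[2])
    nt_stop("ranks (%d, %d) must lie within mode dimensions (%d, %d)",
            ranks[1], ranks[2], d[1], d[2])
  normY2 <- sum(tensor^2)
  if (normY2 == 0) nt_stop("zero tensor has no meaningful decomposition")

  # truncated HOSVD initialisation
  At <- svd(tensor_unfold(tensor, 1), nu = ranks[1], nv = 0)$u
  Ac <- svd(tensor_unfold(tensor, 2), nu = ranks[2], nv = 0)$u

  fit_trace <- numeric(0)
  prev_f <- Inf
  iter <- 0
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1
    At <- svd(tensor_unfold(ttm(tensor, t(Ac), 2), 1), nu = ranks[1], nv = 0)$u
    Ac <- svd(tensor_unfold(ttm(tensor, t(At), 1), 2), nu = ranks[2], nv = 0)$u
    core_norm2 <- sum((ttm(ttm(tensor, t(At), 1), t(Ac), 2))^2)
    f <- max(normY2 - core_norm2, 0)
    fit_trace <- c(fit_trace, sqrt(f / normY2))
    if (is.finite(prev_f) && abs(prev_f - f) <= tol * max(prev_f, 1e-300)) {
      converged <- TRUE
      prev_f <- f
      break
    }
    prev_f <- f
  }
  core <- ttm(ttm(tensor, t(At), 1), t(Ac), 2)

  factors <- list(time = At, channel = Ac, subject = diag(d[3]))
  fit <- structure(list(
    core = core, factors = factors,
    ranks = c(Rt = ranks[1], Rc = ranks[2], Is = d[3]), dims = d,
    rel_error = NA_real_, fit_trace = fit_trace, iterations = iter,
    converged = converged, meta = meta, call = match.call()
  ), class = "tucker_model")
  fit$rel_error <- relative_error(fit, tensor)
  fit
}

#' @export
relative_error.tucker_model <- function(model, tensor) {
  if (inherits(tensor, "hemodynamic_tensor")) tensor <- tensor$data
  nx <- fnorm(tensor)
  if (nx == 0) nt_stop("relative error undefined for a zero tensor")
  fnorm(tensor - tucker_reconstruct(model$core, model$factors)) / nx
}

#' Select Tucker multilinear ranks from sequentially truncated HOSVD errors
#'
#' For every `(Rt, Rc)` pair up to the caps, the relative reconstruction
#' error is estimated from the discarded singular values of the sequentially
#' truncated HOSVD (mode 1 first, then mode 2 of the projected tensor).  The
#' smallest pair with estimated error below the threshold is chosen, ordered
#' by total `Rt + Rc` first and then by smaller `Rt`.  If none qualifies the
#' caps are returned with a warning flag.
#'
#' @param tensor 3-way array or [hemodynamic_tensor()]
#' @param rt_max,rc_max scan caps (defaults: the mode dimensions)
#' @param error_threshold relative-error acceptance threshold (default 0.10)
#' @return an object of class `td_rank_selection`: `ranks` (`c(Rt, Rc)`),
#'   `error_surface` (rt_max x rc_max matrix of estimated relative errors),
#'   `threshold`, `met`
#' @export
select_ranks_td <- function(tensor, rt_max = NULL, rc_max = NULL,
                            error_threshold = 0.10) {
  if (inherits(tensor, "hemodynamic_tensor")) tensor <- tensor$data
  d <- dim(tensor)
  if (length(d) != 3) nt_stop("select_ranks_td expects a 3-way tensor")
  rt_max <- min(rt_max %||% d[1], d[1])
  rc_max <- min(rc_max %||% d[2], d[2])
  normY2 <- sum(tensor^2)
  if (normY2 == 0) nt_stop("zero tensor has no meaningful decomposition")

  sv1 <- svd(tensor_unfold(tensor, 1), nu = rt_max, nv = 0)
  tail1 <- rev(cumsum(rev(sv1$d^2)))            # tail1[k] = sum_{i>=k} s^2
  err <- matrix(NA_real_, rt_max, rc_max,
                dimnames = list(paste0("Rt", seq_len(rt_max)),
                                paste0("Rc", seq_len(rc_max))))
  for (rt in seq_len(rt_max)) {
    proj <- ttm(tensor, t(sv1$u[, seq_len(rt), drop = FALSE]), 1)
    s2 <- svd(tensor_unfold(proj, 2), nu = 0, nv = 0)$d
    tail2 <- c(rev(cumsum(rev(s2^2))), 0)
    drop1 <- if (rt < d[1]) tail1[rt + 1] else 0
    for (rc in seq_len(rc_max)) {
      drop2 <- if (rc < length(s2)) tail2[rc + 1] else 0
      err[rt, rc] <- sqrt((drop1 + drop2) / normY2)
    }
  }
  ok <- which(err < error_threshold, arr.ind = TRUE)
  met <- nrow(ok) > 0
  if (met) {
    ord <- order(ok[, 1] + ok[, 2], ok[, 1])
    ranks <- unname(ok[ord[1], ])
  } else {
    warning(sprintf(
      "no rank pair up to (%d, %d) reaches estimated error < %g; using caps",
      rt_max, rc_max, error_threshold), call. = FALSE)
    ranks <- c(rt_max, rc_max)
  }
  structure(list(ranks = c(Rt = ranks[1], Rc = ranks[2]),
                 error_surface = err, threshold = error_threshold, met = met),
            class = "td_rank_selection")
}

#' @export
print.td_rank_selection <- function(x, ...) {
  cat(sprintf("Tucker rank selection: (Rt, Rc) = (%d, %d), threshold %.3g%s\n",
              x$ranks[1], x$ranks[2], x$threshold,
              if (x$met) "" else " NOT met"))
  invisible(x)
}
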