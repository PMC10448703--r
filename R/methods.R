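# Standard modelling-object methods for the two decomposition classes.

#' @export
print.nn_cpd <- function(x, ...) {
  cat(sprintf("Nonnegative CPD: rank %d, modes %s, rel. error %.4f (%d iterations%s)\n",
              x$R, paste(x$dims, collapse = " x "), x$rel_error, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' @export
summary.nn_cpd <- function(object, ...) {
  out <- list(R = object$R, dims = object$dims, lambda = object$lambda,
              rel_error = object$rel_error, iterations = object$iterations,
              converged = object$converged, seed = object$seed)
  class(out) <- "summary.nn_cpd"
  out
}

#' @export
print.summary.nn_cpd <- function(x, ...) {
  cat(sprintf("Nonnegative CPD (rank %d, %s)\n", x$R,
              paste(x$dims, collapse = " x ")))
  cat(sprintf("  relative error: %.4f after %d iterations (seed %d)\n",
              x$rel_error, x$iterations, x$seed))
  cat("  component weights (lambda):\n")
  print(signif(x$lambda, 4))
  invisible(x)
}

#' @export
coef.nn_cpd <- function(object, ...) object$factors

#' @export
fitted.nn_cpd <- function(object, ...)
  cp_reconstruct(object$factors, object$lambda)

#' @export
residuals.nn_cpd <- function(object, tensor, ...) {
  if (inherits(tensor, "hemodynamic_tensor")) tensor <- tensor$data
  tensor - fitted(object)
}

#' @export
plot.nn_cpd <- function(x, mode = 1, ...) {
  M <- x$factors[[mode]]
  nm <- names(x$factors)[mode]
  ax <- if (!is.null(x$meta)) x$meta$mode_axes[[nm]] else seq_len(nrow(M))
  if (!is.numeric(ax)) ax <- seq_len(nrow(M))
  graphics::matplot(ax, M, type = "l", lty = 1,
                    xlab = nm %||% "index", ylab = "loading",
                    main = sprintf("CPD %s components", nm), ...)
  invisible(x)
}

#' @export
print.tucker_model <- function(x, ...) {
  cat(sprintf("Orthogonal Tucker: ranks (%d, %d, %d), modes %s, rel. error %.4f (%d sweeps%s)\n",
              x$ranks[1], x$ranks[2], x$ranks[3],
              paste(x$dims, collapse = " x "), x$rel_error, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' @export
summary.tucker_model <- function(object, ...) {
  core_energy <- apply(object$core, c(1, 2), function(v) sum(v^2))
  out <- list(ranks = object$ranks, dims = object$dims,
              rel_error = object$rel_error, iterations = object$iterations,
              core_energy = core_energy)
  class(out) <- "summary.tucker_model"
  out
}

#' @export
print.summary.tucker_model <- function(x, ...) {
  cat(sprintf("Orthogonal Tucker (ranks %d x %d x %d, tensor %s)\n",
              x$ranks[1], x$ranks[2], x$ranks[3],
              paste(x$dims, collapse = " x ")))
  cat(sprintf("  relative error: %.4f after %d sweeps\n",
              x$rel_error, x$iterations))
  cat("  core energy by (temporal, spatial) component:\n")
  print(signif(x$core_energy, 3))
  invisible(x)
}

#' @export
coef.tucker_model <- function(object, ...) object$factors

#' @export
fitted.tucker_model <- function(object, ...)
  tucker_reconstruct(object$core, object$factors)

#' @export
residuals.tucker_model <- function(object, tensor, ...) {
  if (inherits(tensor, "hemodynamic_tensor")) tensor <- tensor$data
  tensor - fitted(object)
}

#' @export
plot.tucker_model <- function(x, mode = c("time", "channel"), ...) {
  mode <- match.arg(mode)
  M <- x$factors[[mode]]
  ax <- if (!is.null(x$meta)) x$meta$mode_axes[[mode]] else seq_len(nrow(M))
  if (!is.numeric(ax)) ax <- seq_len(nrow(M))
  graphics::matplot(ax, M, type = "l", lty = 1, xlab = mode, ylab = "loading",
                    main = sprintf("Tucker %s components", mode), ...)
  invisible(x)
}
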