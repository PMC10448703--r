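# Component screening: drop components that do not look like a stimulus-
# locked hemodynamic response, then build cross-run consensus for the CPD.

# pull named mode vectors out of a decomposition component
comp_vectors <- function(model, r) {
  f <- model$factors
  nm <- names(f)
  if (is.null(nm) || !"time" %in% nm) {
    nm <- if (length(f) == 4) c("time", "freq", "channel", "subject")
          else c("time", "channel", "subject")
    names(f) <- nm
  }
  lapply(f, function(M) M[, r])
}

#' Temporal-relevance screen for one component
#'
#' A unit-L2-normalised temporal component is kept only if its mean absolute
#' value from 2 s after stimulus onset to the end of the stimulus
#' presentation reaches `threshold` (default 0.01); components with their
#' mass in the baseline period are excluded as not stimulus-locked.
#'
#' @param v temporal component vector (unit L2 norm)
#' @param times time axis of `v` in seconds relative to onset
#' @param epoch the [epoch_definition()]
#' @param threshold minimal mean absolute value (default 0.01)
#' @return list with `keep` (logical) and `statistic` (the mean |value|)
#' @export
exclude_temporal <- function(v, times, epoch, threshold = 0.01) {
  if (length(v) != length(times)) nt_stop("component and time axis differ in length")
  win <- times >= 2 & times < epoch$stimulus_s
  if (!any(win)) nt_stop("temporal screening window [2 s, stimulus end) is empty")
  stat <- mean(abs(v[win]))
  list(keep = stat >= threshold, statistic = stat)
}

#' Spectral-relevance screen for one component
#'
#' The component's dominant frequency (argmax of the magnitude by default,
#' spectral centroid optionally) must not exceed `cutoff_hz`; hemodynamic
#' responses live below ~0.1 Hz for stimulus paradigms of this length.  Ties
#' resolve to the lowest frequency.
#'
#' @param v spectral component vector
#' @param freqs strictly increasing frequency axis (Hz)
#' @param cutoff_hz exclusion cutoff (default 0.1 Hz)
#' @param method `"argmax"` (default) or `"centroid"`
#' @return list with `keep` (logical) and `peak_hz`
#' @export
exclude_spectral <- function(v, freqs, cutoff_hz = 0.1,
                             method = c("argmax", "centroid")) {
  method <- match.arg(method)
  if (length(freqs) == 0) nt_stop("empty frequency axis")
  if (length(v) != length(freqs)) nt_stop("component and frequency axis differ")
  if (is.unsorted(freqs, strictly = TRUE)) nt_stop("frequency axis must be strictly increasing")
  peak <- if (method == "argmax") freqs[which.max(abs(v))]
          else sum(freqs * abs(v)) / max(sum(abs(v)), 1e-300)
  list(keep = peak <= cutoff_hz, peak_hz = peak)
}

#' Screen the components of one or more decomposition runs
#'
#' Applies [exclude_temporal()] (and, for 4-way CPD models,
#' [exclude_spectral()]) to every component of every run and records each
#' decision with its statistic and exclusion reason (`baseline_only` or
#' `high_frequency`).
#'
#' @param models list of `nn_cpd` models (the runs), or a single model
#' @param times temporal axis of the components (s relative to onset)
#' @param epoch the [epoch_definition()]
#' @param freqs frequency axis (Hz) for 4-way models, else `NULL`
#' @param temporal_threshold,spectral_cutoff_hz,spectral_method screening
#'   parameters (see the per-component screens)
#' @return data.frame of class `screened_components` with one row per
#'   (run, component): statistics, `retained`, `reason`
#' @export
screen_components <- function(models, times, epoch, freqs = NULL,
                              temporal_threshold = 0.01,
                              spectral_cutoff_hz = 0.1,
                              spectral_method = "argmax") {
  if (inherits(models, "nn_cpd") || inherits(models, "tucker_model"))
    models <- list(models)
  rows <- list()
  for (k in seq_along(models)) {
    m <- models[[k]]
    R <- if (inherits(m, "tucker_model")) m$ranks[["Rt"]] else m$R
    for (r in seq_len(R)) {
      if (inherits(m, "tucker_model")) {
        tv <- m$factors$time[, r]; sv <- NULL
      } else {
        cv <- comp_vectors(m, r); tv <- cv$time; sv <- cv$freq
      }
      te <- exclude_temporal(tv, times, epoch, temporal_threshold)
      reason <- NA_character_
      keep <- te$keep
      peak_hz <- NA_real_
      if (!keep) reason <- "baseline_only"
      if (keep && !is.null(sv) && !is.null(freqs)) {
        se <- exclude_spectral(sv, freqs, spectral_cutoff_hz, spectral_method)
        peak_hz <- se$peak_hz
        if (!se$keep) { keep <- FALSE; reason <- "high_frequency" }
      } else if (!is.null(sv) && !is.null(freqs)) {
        peak_hz <- exclude_spectral(sv, freqs, spectral_cutoff_hz,
                                    spectral_method)$peak_hz
      }
      rows[[length(rows) + 1L]] <- data.frame(
        run = k, comp = r, temporal_stat = te$statistic, peak_hz = peak_hz,
        retained = keep, reason = reason)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("screened_components", class(out))
  out
}

# Pearson p-value via the t transform with n - 2 degrees of freedom
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  2 * stats::pt(-abs(t), n - 2)
}

#' Match CPD components across runs into consensus components
#'
#' Components from different runs are connected when their temporal vectors
#' and their spatial vectors are both positively correlated beyond
#' `r_threshold` with correlation p-value below `alpha`.  Connected
#' components of this graph that span at least two runs become consensus
#' components: their member vectors are averaged (after scale/sign
#' normalisation) and re-normalised, and the cluster is weighted by the
#' fraction of runs it appears in.
#'
#' @param models list of `nn_cpd` run models (>= 2 runs)
#' @param screened optional [screen_components()] table; only retained
#'   components enter the matching (all components if `NULL`)
#' @param r_threshold correlation threshold (default 0.5)
#' @param alpha correlation significance level (default 0.05)
#' @param mode require `"both"` temporal and spatial association (default)
#'   or `"either"`
#' @return list of `consensus_component` objects: unit-norm `temporal`,
#'   `spatial` (and `spectral`) vectors, `occurrence_weight`, `members`
#'   (run/comp table)
#' @export
match_components_across_runs <- function(models, screened = NULL,
                                         r_threshold = 0.5, alpha = 0.05,
                                         mode = c("both", "either")) {
  mode <- match.arg(mode)
  if (length(models) < 2) nt_stop("consensus matching needs >= 2 runs")
  n_runs <- length(models)
  nodes <- do.call(rbind, lapply(seq_len(n_runs), function(k)
    data.frame(run = k, comp = seq_len(models[[k]]$R))))
  if (!is.null(screened)) {
    keep <- merge(nodes, screened[, c("run", "comp", "retained")],
                  by = c("run", "comp"))
    nodes <- keep[keep$retained, c("run", "comp")]
  }
  if (nrow(nodes) == 0) return(list())
  vecs <- lapply(seq_len(nrow(nodes)), function(i)
    comp_vectors(models[[nodes$run[i]]], nodes$comp[i]))
  Tm <- vapply(vecs, `[[`, numeric(length(vecs[[1]]$time)), "time")
  Sm <- vapply(vecs, `[[`, numeric(length(vecs[[1]]$channel)), "channel")
  degen <- apply(Tm, 2, stats::sd) == 0 | apply(Sm, 2, stats::sd) == 0
  if (any(degen)) {
    warning(sprintf("%d degenerate constant component(s) skipped", sum(degen)),
            call. = FALSE)
    nodes <- nodes[!degen, , drop = FALSE]
    if (nrow(nodes) == 0) return(list())
    Tm <- Tm[, !degen, drop = FALSE]
    Sm <- Sm[, !degen, drop = FALSE]
    vecs <- vecs[!degen]
  }
  rT <- stats::cor(Tm); rS <- stats::cor(Sm)
  pT <- cor_pvalue(rT, nrow(Tm)); pS <- cor_pvalue(rS, nrow(Sm))
  okT <- rT > r_threshold & pT < alpha
  okS <- rS > r_threshold & pS < alpha
  adj <- if (mode == "both") okT & okS else okT | okS
  cross_run <- outer(nodes$run, nodes$run, `!=`)
  adj <- adj & cross_run
  diag(adj) <- FALSE

  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- list()
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    runs <- unique(nodes$run[idx])
    if (length(runs) < 2) next   # single-run orphans are never promoted
    avg <- function(mat) {
      ref <- mat[, 1]
      flip <- sign(colSums(mat * ref))
      flip[flip == 0] <- 1
      v <- rowMeans(sweep(mat, 2, flip, `*`))
      v / fnorm(v)
    }
    cc <- list(
      temporal = avg(Tm[, idx, drop = FALSE]),
      spatial = avg(Sm[, idx, drop = FALSE]),
      spectral = if (!is.null(vecs[[1]]$freq))
        avg(vapply(vecs[idx], `[[`, numeric(length(vecs[[1]]$freq)), "freq"))
        else NULL,
      occurrence_weight = length(runs) / n_runs,
      members = nodes[idx, , drop = FALSE]
    )
    class(cc) <- "consensus_component"
    out[[length(out) + 1L]] <- cc
  }
  out
}

#' @export
print.consensus_component <- function(x, ...) {
  cat(sprintf("Consensus component: %d members from %d runs (weight %.2f)\n",
              nrow(x$members), length(unique(x$members$run)),
              x$occurrence_weight))
  invisible(x)
}

#' Write a screening report as TSV
#'
#' @param screened a [screen_components()] table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_screening_report <- function(screened, path) {
  utils::write.table(screened, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
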