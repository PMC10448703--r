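# Component-wise inference: subject scores, 2x2 ANOVAs, profile summation,
# TOI/ROI determination and Bayes-factor follow-up.

#' Subject scores of one CPD component
#'
#' Column `r` of the subject-mode factor scaled by the component weight
#' \eqn{\lambda_r}; one value per subject slot.
#'
#' @param model an `nn_cpd` fit
#' @param r component index
#' @return numeric score vector (named by subject slot when available)
#' @export
subject_scores_cpd <- function(model, r) {
  if (r < 1 || r > model$R) nt_stop("component index %d out of range 1..%d", r, model$R)
  f <- model$factors
  sub <- f[[if ("subject" %in% names(f)) "subject" else length(f)]]
  sc <- model$lambda[r] * sub[, r]
  if (!is.null(model$meta)) names(sc) <- model$meta$subjects$subject_id
  sc
}

#' Subject scores of one Tucker (temporal, spatial) component pair
#'
#' The subject factor applied to the core fiber `G[rt, rc, ]`; with the
#' uncompressed subject mode this is the fiber itself, one value per
#' subject slot.
#'
#' @param model a `tucker_model` fit
#' @param rt,rc temporal and spatial component indices
#' @return numeric score vector (named by subject slot when available)
#' @export
subject_scores_td <- function(model, rt, rc) {
  if (rt < 1 || rt > model$ranks[["Rt"]]) nt_stop("rt out of range")
  if (rc < 1 || rc > model$ranks[["Rc"]]) nt_stop("rc out of range")
  sc <- as.vector(model$factors$subject %*% model$core[rt, rc, ])
  if (!is.null(model$meta)) names(sc) <- model$meta$subjects$subject_id
  sc
}

#' Two-way between-subjects 2x2 ANOVA on subject scores
#'
#' Type III sums of squares (sum-to-zero contrasts), valid for unbalanced
#' cells; F and p for both main effects and the interaction.
#'
#' @param scores numeric vector, one score per subject, named by subject id
#'   (or accompanied by `subjects`)
#' @param design a [design_info()] with both factors between
#' @param subjects optional character vector of subject ids aligned with
#'   `scores` (defaults to `names(scores)`)
#' @return data.frame of class `effect_test` with columns `effect`
#'   (`main_a`, `main_b`, `interaction`), `F`, `p`
#' @export
anova_2x2_between <- function(scores, design, subjects = NULL) {
  if (design$scope_a != "between" || design$scope_b != "between")
    nt_stop("anova_2x2_between requires both factors between-subjects")
  subjects <- subjects %||% names(scores)
  if (is.null(subjects)) nt_stop("scores must be named by subject id")
  m <- match(subjects, design$assignments$subject)
  if (anyNA(m)) nt_stop("scores include subjects missing from the design")
  df <- data.frame(
    score = as.numeric(scores),
    A = factor(design$assignments$level_a[m], levels = design$levels_a),
    B = factor(design$assignments$level_b[m], levels = design$levels_b))
  if (any(table(df$A, df$B) == 0)) nt_stop("design error: empty cell")
  fit <- stats::lm(score ~ A * B, data = df,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  tab <- car::Anova(fit, type = 3)
  pick <- function(term) {
    i <- match(term, rownames(tab))
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  out <- data.frame(
    effect = c("main_a", "main_b", "interaction"),
    F = c(pick("A")["F"], pick("B")["F"], pick("A:B")["F"]),
    p = c(pick("A")["p"], pick("B")["p"], pick("A:B")["p"]),
    row.names = NULL)
  out$F[is.na(out$F)] <- 0
  out$p[is.na(out$p)] <- 1
  class(out) <- c("effect_test", class(out))
  out
}

#' Mixed-model 2x2 ANOVA on subject scores
#'
#' One factor within-subjects (two scores per subject), the other between.
#' The between effect is tested against the subject-within-group mean
#' square; the within effect and the interaction against the within-subject
#' error mean square (balanced mixed-model ANOVA via [stats::aov()] with an
#' `Error(subject)` stratum).
#'
#' @param scores numeric vector with one score per subject slot
#' @param design a [design_info()] with exactly one within factor
#' @param subjects data.frame aligned with `scores`, columns `subject_id`,
#'   `level_a`, `level_b` (the slot table of the tensor)
#' @return data.frame of class `effect_test` (as [anova_2x2_between()])
#' @export
anova_2x2_mixed <- function(scores, design, subjects) {
  within_a <- design$scope_a == "within"
  if (!xor(within_a, design$scope_b == "within"))
    nt_stop("anova_2x2_mixed requires exactly one within factor")
  df <- data.frame(score = as.numeric(scores),
                   subject = subjects$subject_id,
                   level_a = subjects$level_a, level_b = subjects$level_b)
  df$W <- factor(if (within_a) df$level_a else df$level_b)
  df$G <- factor(if (within_a) df$level_b else df$level_a)
  counts <- table(df$subject)
  if (any(counts != 2) || any(table(df$subject, df$W) != 1))
    nt_stop("design error: every subject needs one score per within level")
  fit <- stats::aov(score ~ G * W + Error(subject), data = df)
  sm <- summary(fit)
  btab <- sm[["Error: subject"]][[1]]
  wtab <- sm[["Error: Within"]][[1]]
  ss_tot <- sum((df$score - mean(df$score))^2)
  eps <- 1e-12 * max(ss_tot, 1e-300)
  grab <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    j <- match("Residuals", trimws(rownames(tab)))
    out <- c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
    # an exactly-null stratum leaves floating-point dust in both sums of
    # squares; report F = 0 rather than a dust ratio
    if (!is.na(tab[i, "Sum Sq"]) && tab[i, "Sum Sq"] < eps &&
        tab[j, "Sum Sq"] < eps)
      out <- c(F = 0, p = 1)
    out
  }
  g <- grab(btab, "G"); w <- grab(wtab, "W"); gw <- grab(wtab, "G:W")
  res <- if (within_a)
    list(main_a = w, main_b = g) else list(main_a = g, main_b = w)
  out <- data.frame(
    effect = c("main_a", "main_b", "interaction"),
    F = c(res$main_a["F"], res$main_b["F"], gw["F"]),
    p = c(res$main_a["p"], res$main_b["p"], gw["p"]),
    row.names = NULL)
  out$F[is.na(out$F)] <- 0
  out$p[is.na(out$p)] <- 1
  class(out) <- c("effect_test", class(out))
  out
}

# dispatch on the design
anova_2x2 <- function(scores, design, subjects) {
  if (design$scope_a == "between" && design$scope_b == "between")
    anova_2x2_between(scores, design, subjects$subject_id)
  else anova_2x2_mixed(scores, design, subjects)
}

#' Sum significant components into per-effect profiles
#'
#' For each effect with at least one significant component (p < alpha), the
#' absolute temporal, spatial (and spectral) component vectors are summed,
#' weighted by each component's cross-run occurrence weight (1 for Tucker
#' components).  Profiles are nonnegative; effects without significant
#' components yield no profile.
#'
#' @param tests list of [anova_2x2_between()]/[anova_2x2_mixed()] tables,
#'   one per component
#' @param comps list parallel to `tests`; each element has `temporal`,
#'   `spatial`, optional `spectral` vectors, a `weight` and an `id`
#' @param alpha per-test significance level (default 0.05)
#' @param fdr apply Benjamini-Hochberg across components within each effect
#'   before thresholding (default `FALSE`)
#' @return named list (one entry per effect present) of `profile_set`
#'   objects: `temporal_profile`, `spatial_profile`, `spectral_profile`,
#'   `n_components` (raw count), `weighted_count`, `contributing` ids
#' @export
select_and_sum <- function(tests, comps, alpha = 0.05, fdr = FALSE) {
  stopifnot(length(tests) == length(comps))
  effects <- c("main_a", "main_b", "interaction")
  out <- list()
  for (eff in effects) {
    p <- vapply(tests, function(tt) tt$p[tt$effect == eff], 1)
    if (fdr && length(p)) p <- stats::p.adjust(p, "BH")
    sig <- which(p < alpha)
    if (length(sig) == 0) next
    wsum <- function(field) {
      vs <- lapply(sig, function(i) {
        v <- comps[[i]][[field]]
        if (is.null(v)) return(NULL)
        abs(v) * comps[[i]]$weight
      })
      vs <- vs[!vapply(vs, is.null, TRUE)]
      if (length(vs) == 0) return(NULL)
      Reduce(`+`, vs)
    }
    ps <- list(
      effect = eff,
      temporal_profile = wsum("temporal"),
      spatial_profile = wsum("spatial"),
      spectral_profile = wsum("spectral"),
      n_components = length(sig),
      weighted_count = sum(vapply(sig, function(i) comps[[i]]$weight, 1)),
      contributing = vapply(sig, function(i) comps[[i]]$id %||% as.character(i), "")
    )
    class(ps) <- "profile_set"
    out[[eff]] <- ps
  }
  out
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("Profile set for %s: %d significant component(s), weighted count %.2f\n",
              x$effect, x$n_components, x$weighted_count))
  invisible(x)
}

#' Determine the time of interest (TOI) from a temporal profile
#'
#' The TOI peak is the global argmax of the temporal profile restricted to
#' the stimulus presentation `[0, stimulus end)`; the reported window is the
#' peak +/- `half_width_s`, clipped to the stimulus period.  If the profile's
#' unrestricted global maximum lies after stimulus offset and no
#' within-stimulus value reaches `post_peak_frac` of it, no TOI is returned
#' (a purely post-stimulus peak is not a TOI).  Ties resolve to the earliest
#' peak.
#'
#' @param profile a `profile_set` (or a list with `temporal_profile`)
#' @param times time axis of the temporal profile (s relative to onset)
#' @param epoch the [epoch_definition()]
#' @param half_width_s reported half width (default 1 s, matching the
#'   follow-up window)
#' @param post_peak_frac see above (default 0.5)
#' @return list of class `toi` with `start_s`, `end_s`, `peak_time_s`, or
#'   `NULL` when no TOI is identified
#' @export
determine_toi <- function(profile, times, epoch, half_width_s = 1,
                          post_peak_frac = 0.5) {
  v <- profile$temporal_profile
  if (is.null(v) || length(v) == 0) return(NULL)
  stopifnot(length(v) == length(times))
  stim <- times >= 0 & times < epoch$stimulus_s
  if (!any(stim)) return(NULL)
  g_idx <- which.max(v)
  if (times[g_idx] >= epoch$stimulus_s && max(v[stim]) < post_peak_frac * v[g_idx])
    return(NULL)
  peak <- times[stim][which.max(v[stim])]
  structure(list(start_s = max(0, peak - half_width_s),
                 end_s = min(epoch$stimulus_s, peak + half_width_s),
                 peak_time_s = peak),
            class = "toi")
}

#' Determine the region of interest (ROI) from a spatial profile
#'
#' Channels whose spatial-profile value reaches `fraction_of_max` times the
#' maximum (default 0.5) — the channels showing the most prominent
#' difference across conditions.
#'
#' @param profile a `profile_set` (or a list with `spatial_profile`)
#' @param channels channel ids aligned with the spatial profile
#' @param fraction_of_max prominence threshold (default 0.5)
#' @return character vector of ROI channel ids (empty if no profile)
#' @export
determine_roi <- function(profile, channels, fraction_of_max = 0.5) {
  v <- profile$spatial_profile
  if (is.null(v) || length(v) == 0) return(character(0))
  stopifnot(length(v) == length(channels))
  channels[v >= fraction_of_max * max(v)]
}

#' Bayes-factor follow-up contrasts at the discovered TOI/ROI
#'
#' For every subject and condition, the HbO is averaged over
#' `[toi start - 1 s, toi end + 1 s]` and the ROI channels; requested
#' simple-effect contrasts (by default: the factor-A difference within each
#' level of factor B) are then tested with the JZS Bayes factor — paired by
#' subject when factor A is within-subjects, two-sample otherwise.
#'
#' @param hrfs list of [subject_hrf()] (any hemisphere; ROI channels must be
#'   present)
#' @param toi a `toi` object from [determine_toi()]
#' @param roi character vector of ROI channels (nonempty)
#' @param design the [design_info()]
#' @param contrasts list of contrasts, each `list(factor = "a", level_b =
#'   <level>)` (or `factor = "b"`, `level_a = <level>`); `NULL` for the
#'   default pattern
#' @param rscale Cauchy prior scale (default 0.707)
#' @return list of `bayes_result` objects: `contrast`, `BF10`, `t`, group
#'   `means`, `sds`, `n`
#' @export
bayes_followup <- function(hrfs, toi, roi, design, contrasts = NULL,
                           rscale = 0.707) {
  if (is.null(toi)) nt_stop("bayes_followup requires a TOI")
  if (length(roi) == 0) nt_stop("bayes_followup requires a nonempty ROI")
  ep <- hrfs[[1]]$epoch
  win <- ep$times >= toi$start_s - 1 & ep$times <= toi$end_s + 1
  if (!any(win)) nt_stop("follow-up window is empty")
  cells <- do.call(rbind, lapply(hrfs, function(h) {
    miss <- setdiff(roi, h$channel_ids)
    if (length(miss)) nt_stop("ROI channels %s absent from HRF",
                              paste(miss, collapse = ", "))
    data.frame(subject = h$subject_id, level_a = h$level_a,
               level_b = h$level_b,
               value = mean(h$hrf[win, roi, drop = FALSE]))
  }))
  if (is.null(contrasts))
    contrasts <- lapply(design$levels_b, function(lb)
      list(factor = "a", level_b = lb))
  lapply(contrasts, function(ct) {
    if (ct$factor == "a") {
      sub <- cells[cells$level_b == ct$level_b, , drop = FALSE]
      lv <- design$levels_a; within <- design$scope_a == "within"
      fixed <- sprintf("%s = %s", design$factor_b_name, ct$level_b)
      g1 <- sub[sub$level_a == lv[1], ]; g2 <- sub[sub$level_a == lv[2], ]
    } else {
      sub <- cells[cells$level_a == ct$level_a, , drop = FALSE]
      lv <- design$levels_b; within <- design$scope_b == "within"
      fixed <- sprintf("%s = %s", design$factor_a_name, ct$level_a)
      g1 <- sub[sub$level_b == lv[1], ]; g2 <- sub[sub$level_b == lv[2], ]
    }
    if (nrow(g1) < 2 || nrow(g2) < 2)
      nt_stop("fewer than 2 subjects per cell in follow-up contrast")
    if (within) {
      m <- match(g1$subject, g2$subject)
      if (anyNA(m)) nt_stop("within-subject contrast needs paired subjects")
      dvals <- g1$value - g2$value[m]
      tval <- mean(dvals) / (stats::sd(dvals) / sqrt(length(dvals)))
      bf <- jzs_bf(tval, length(dvals), rscale = rscale)
      n <- c(length(dvals), length(dvals))
    } else {
      tval <- two_sample_t(g1$value, g2$value)
      bf <- jzs_bf(tval, nrow(g1), nrow(g2), rscale = rscale)
      n <- c(nrow(g1), nrow(g2))
    }
    res <- list(
      contrast = sprintf("%s vs %s at %s", lv[1], lv[2], fixed),
      BF10 = bf, t = tval,
      means = stats::setNames(c(mean(g1$value), mean(g2$value)), lv),
      sds = stats::setNames(c(stats::sd(g1$value), stats::sd(g2$value)), lv),
      n = stats::setNames(n, lv))
    class(res) <- "bayes_result"
    res
  })
}

#' @export
print.bayes_result <- function(x, ...) {
  cat(sprintf("%s: BF10 = %.3g (t = %.3f; means %s)\n", x$contrast, x$BF10,
              x$t, paste(sprintf("%s=%.3f", names(x$means), x$means),
                         collapse = ", ")))
  invisible(x)
}
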