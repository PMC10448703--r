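#' Grand averaging: collapse HRFs over a predefined TOI, then ROI
#'
#' The baseline method the tensor pipeline is compared against: for every
#' subject-condition HRF, average over the predefined TOI window per channel
#' (temporal mean), then average those means over the ROI channels (spatial
#' mean), yielding one value per subject and condition.  The TOI and ROI
#' must be supplied — this method requires prior assumptions about both.
#'
#' @param hrfs list of [subject_hrf()]
#' @param toi_window `c(start_s, end_s)` relative to onset (half-open)
#' @param roi nonempty character vector of channel ids
#' @return data.frame with `subject`, `level_a`, `level_b`, `value`
#' @export
grand_average <- function(hrfs, toi_window, roi) {
  if (length(roi) == 0) nt_stop("roi must be nonempty")
  ep <- hrfs[[1]]$epoch
  win <- ep$times >= toi_window[1] & ep$times < toi_window[2]
  if (!any(win)) nt_stop("TOI window [%g, %g) contains no samples",
                         toi_window[1], toi_window[2])
  do.call(rbind, lapply(hrfs, function(h) {
    miss <- setdiff(roi, h$channel_ids)
    if (length(miss)) nt_stop("ROI channels %s absent from HRF",
                              paste(miss, collapse = ", "))
    temporal_means <- colMeans(h$hrf[win, roi, drop = FALSE])
    data.frame(subject = h$subject_id, level_a = h$level_a,
               level_b = h$level_b, value = mean(temporal_means))
  }))
}

#' ANOVA on grand-averaged spatial means
#'
#' Groups the [grand_average()] values by condition and tests them with the
#' same 2x2 between or mixed ANOVA used for the component-wise analysis.
#'
#' @param values data.frame from [grand_average()]
#' @param design the [design_info()]
#' @return an `effect_test` data.frame (effect, F, p)
#' @export
grandavg_test <- function(values, design) {
  subjects <- data.frame(subject_id = values$subject,
                         level_a = values$level_a, level_b = values$level_b)
  anova_2x2(stats::setNames(values$value, values$subject), design, subjects)
}
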