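#' Trial-average a recording into per-condition hemodynamic responses
#'
#' For every condition present in the recording's trial onsets, extracts all
#' epochs, optionally baseline-corrects each (subtracting the per-channel
#' mean of the pre-onset baseline period) and averages them arithmetically
#' into one [subject_hrf()].
#'
#' @param recording an [fnirs_recording()]
#' @param epoch an [epoch_definition()] (its `fs` must match the recording)
#' @param design a [design_info()]; the subject's conditions must map into it
#' @param baseline_correct subtract the baseline-period mean per channel and
#'   trial (default `TRUE`)
#' @return list of [subject_hrf()], one per condition present
#' @export
build_hrf <- function(recording, epoch, design, baseline_correct = TRUE) {
  validate_recording(recording, epoch)
  on <- recording$trial_onsets
  if (nrow(on) == 0)
    nt_stop("subject '%s': no trials", recording$subject_id)
  cell <- design_cell(design, recording$subject_id)
  # conditions this subject must provide
  want_a <- if (design$scope_a == "within") design$levels_a else cell$level_a
  want_b <- if (design$scope_b == "within") design$levels_b else cell$level_b
  required <- expand.grid(level_a = want_a, level_b = want_b,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  pre <- round(epoch$baseline_s * epoch$fs)
  n <- epoch$n_samples
  base_idx <- which(epoch$times < 0)

  out <- lapply(seq_len(nrow(required)), function(i) {
    la <- required$level_a[i]; lb <- required$level_b[i]
    sel <- which(on$level_a == la & on$level_b == lb)
    if (length(sel) == 0)
      nt_stop("subject '%s': zero trials for condition (%s, %s)",
              recording$subject_id, la, lb)
    acc <- matrix(0, n, length(recording$channel_ids))
    for (k in sel) {
      idx <- (on$sample[k] - pre):(on$sample[k] - pre + n - 1L)
      ep_mat <- t(recording$hbo[, idx, drop = FALSE])
      if (baseline_correct)
        ep_mat <- sweep(ep_mat, 2, colMeans(ep_mat[base_idx, , drop = FALSE]))
      acc <- acc + ep_mat
    }
    subject_hrf(recording$subject_id, la, lb, acc / length(sel), epoch,
                recording$channel_ids, n_trials = length(sel))
  })
  out
}

#' Resample a hemodynamic response to a higher sampling rate
#'
#' Linear interpolation onto the target grid (endpoints preserved exactly);
#' `"polyphase"` resampling via [signal::resample()] is available as an
#' alternative.  Downsampling is refused.
#'
#' @param hrf a [subject_hrf()]
#' @param target_fs target sampling frequency (>= current)
#' @param method `"linear"` (default) or `"polyphase"`
#' @return a [subject_hrf()] on the target grid
#' @export
resample_hrf <- function(hrf, target_fs, method = c("linear", "polyphase")) {
  method <- match.arg(method)
  stopifnot(inherits(hrf, "subject_hrf"))
  fs0 <- hrf$epoch$fs
  if (target_fs < fs0)
    nt_stop("downsampling (%g -> %g Hz) is out of scope", fs0, target_fs)
  if (isTRUE(all.equal(target_fs, fs0))) return(hrf)
  new_epoch <- epoch_definition(hrf$epoch$baseline_s, hrf$epoch$stimulus_s,
                                hrf$epoch$post_s, target_fs)
  new_hrf <- if (method == "linear") {
    apply(hrf$hrf, 2, function(col)
      stats::approx(hrf$epoch$times, col, xout = new_epoch$times, rule = 2)$y)
  } else {
    p <- round(target_fs); q <- round(fs0)
    g <- gcd_int(p, q)
    apply(hrf$hrf, 2, function(col)
      signal::resample(col, p / g, q / g)[seq_len(new_epoch$n_samples)])
  }
  subject_hrf(hrf$subject_id, hrf$level_a, hrf$level_b, new_hrf, new_epoch,
              hrf$channel_ids, hrf$n_trials, hrf$hemisphere)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Split hemodynamic responses by hemisphere
#'
#' Partitions the channels of every HRF into left and right sets according
#' to the hemisphere map, preserving within-hemisphere channel order.
#'
#' @param hrfs list of [subject_hrf()]
#' @param hemisphere_map named character vector channel id -> "left"/"right"
#' @return list with elements `left` and `right`, each a list of
#'   [subject_hrf()] restricted to that hemisphere's channels
#' @export
split_hemispheres <- function(hrfs, hemisphere_map) {
  stopifnot(length(hrfs) > 0)
  chans <- hrfs[[1]]$channel_ids
  unmapped <- setdiff(chans, names(hemisphere_map))
  if (length(unmapped))
    nt_stop("configuration error: unmapped channels %s",
            paste(unmapped, collapse = ", "))
  out <- lapply(c(left = "left", right = "right"), function(h) {
    keep <- chans[hemisphere_map[chans] == h]
    if (length(keep) == 0) {
      nt_log("split_hemispheres", hemisphere = h, note = "empty")
      return(list())
    }
    lapply(hrfs, function(x)
      subject_hrf(x$subject_id, x$level_a, x$level_b,
                  x$hrf[, keep, drop = FALSE], x$epoch, keep, x$n_trials,
                  hemisphere = h))
  })
  out
}
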