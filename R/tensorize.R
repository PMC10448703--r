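#' Short-time Fourier transform magnitudes
#'
#' Hann-windowed STFT of one channel's time series, returning coefficient
#' magnitudes at positive frequencies only (the DC bin is dropped along with
#' the negative frequencies), as a nonnegative time-frame x frequency matrix.
#'
#' @param x numeric time series
#' @param fs sampling frequency (Hz)
#' @param window_s window length in seconds (window must hold >= 4 samples
#'   and fit inside the signal)
#' @param overlap_frac fractional overlap between consecutive windows,
#'   in `[0, 1)`
#' @param t_offset time (s) of the first sample of `x`, used for the frame
#'   time axis (frames are stamped at their window centers)
#' @return list with `magnitude` (frames x frequencies, all entries >= 0),
#'   `times` (frame centers, s) and `freqs` (Hz, all > 0, max <= fs/2)
#' @export
stft_magnitude <- function(x, fs, window_s = 10, overlap_frac = 0.75,
                           t_offset = 0) {
  n <- round(window_s * fs)
  if (n < 4) nt_stop("STFT window must hold at least 4 samples")
  if (n > length(x)) nt_stop("STFT window (%d samples) longer than signal (%d)",
                             n, length(x))
  if (overlap_frac < 0 || overlap_frac >= 1)
    nt_stop("overlap_frac must be in [0, 1)")
  ov <- floor(n * overlap_frac)
  hop <- n - ov
  sp <- signal::specgram(x, n = n, Fs = fs, window = signal::hanning(n),
                         overlap = ov)
  S <- sp$S
  if (is.null(dim(S))) S <- matrix(S, ncol = 1)
  keep <- sp$f > 0
  mag <- t(abs(S[keep, , drop = FALSE]))
  starts <- round(sp$t * fs)           # 1-based start sample of each frame
  stopifnot(length(starts) == nrow(mag), all(diff(starts) == hop))
  list(magnitude = mag,
       times = t_offset + (starts - 1 + (n - 1) / 2) / fs,
       freqs = sp$f[keep])
}

#' Construct a labeled hemodynamic tensor
#'
#' @param data 3-way (time x channel x subject) or 4-way (time x frequency x
#'   channel x subject) array; 4-way tensors must be nonnegative
#' @param mode_axes named list of coordinate vectors matching `dim(data)`
#' @param hemisphere `"left"` or `"right"`
#' @param subjects data.frame mapping subject-axis slots to
#'   `(subject_id, level_a, level_b)`
#' @param design the [design_info()]
#' @return an object of class `hemodynamic_tensor`
#' @export
hemodynamic_tensor <- function(data, mode_axes, hemisphere, subjects, design) {
  d <- dim(data)
  if (length(mode_axes) != length(d))
    nt_stop("mode_axes must name one axis per tensor mode")
  lens <- vapply(mode_axes, length, 1L)
  if (!all(lens == d))
    nt_stop("axis lengths (%s) do not match tensor shape (%s)",
            paste(lens, collapse = "x"), paste(d, collapse = "x"))
  if (length(d) == 4 && any(data < 0))
    nt_stop("4-way (CPD) tensor must be nonnegative")
  if (nrow(subjects) != d[length(d)])
    nt_stop("subject table rows must match the subject mode length")
  structure(list(data = data, mode_axes = mode_axes, hemisphere = hemisphere,
                 subjects = subjects, design = design),
            class = "hemodynamic_tensor")
}

#' @export
print.hemodynamic_tensor <- function(x, ...) {
  cat(sprintf("Hemodynamic tensor (%s hemisphere): %s [%s]\n",
              x$hemisphere, paste(dim(x$data), collapse = " x "),
              paste(names(x$mode_axes), collapse = " x ")))
  invisible(x)
}

# deterministic subject-slot table: sorted by subject id, then within-level
subject_slots <- function(hrfs) {
  df <- data.frame(
    idx = seq_along(hrfs),
    subject_id = vapply(hrfs, `[[`, "", "subject_id"),
    level_a = vapply(hrfs, `[[`, "", "level_a"),
    level_b = vapply(hrfs, `[[`, "", "level_b")
  )
  df <- df[order(df$subject_id, df$level_a, df$level_b), , drop = FALSE]
  df$slot <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

check_hrf_consistency <- function(hrfs) {
  if (length(hrfs) == 0) nt_stop("no HRFs supplied")
  ep <- hrfs[[1]]$epoch; ch <- hrfs[[1]]$channel_ids
  for (x in hrfs) {
    if (!isTRUE(all.equal(x$epoch$times, ep$times)))
      nt_stop("inconsistent epochs across HRFs")
    if (!identical(x$channel_ids, ch))
      nt_stop("inconsistent channel sets across HRFs")
  }
  list(epoch = ep, channels = ch)
}

#' Build the 4-way (time x frequency x channel x subject) tensor for CPD
#'
#' Each subject-condition HRF channel is transformed with
#' [stft_magnitude()]; the magnitudes stack into a nonnegative 4-way tensor.
#' Subject slots are ordered deterministically (subject id, then
#' within-level), so a mixed design contributes one slot per subject and
#' within-level.
#'
#' @param hrfs list of [subject_hrf()] from one hemisphere
#' @param design the [design_info()]
#' @param window_s,overlap_frac STFT parameters (defaults 10 s, 75%)
#' @return a 4-way [hemodynamic_tensor()]
#' @export
build_tensor_cpd <- function(hrfs, design, window_s = 10, overlap_frac = 0.75) {
  info <- check_hrf_consistency(hrfs)
  slots <- subject_slots(hrfs)
  probe <- stft_magnitude(hrfs[[1]]$hrf[, 1], info$epoch$fs, window_s,
                          overlap_frac, t_offset = -info$epoch$baseline_s)
  arr <- array(0, c(nrow(probe$magnitude), ncol(probe$magnitude),
                    length(info$channels), nrow(slots)))
  for (s in seq_len(nrow(slots))) {
    h <- hrfs[[slots$idx[s]]]
    for (c in seq_along(info$channels))
      arr[, , c, s] <- stft_magnitude(h$hrf[, c], info$epoch$fs, window_s,
                                      overlap_frac)$magnitude
  }
  hemodynamic_tensor(
    arr,
    mode_axes = list(time = probe$times, freq = probe$freqs,
                     channel = info$channels,
                     subject = paste(slots$subject_id, slots$level_a,
                                     slots$level_b, sep = "|")),
    hemisphere = hrfs[[1]]$hemisphere %||% "left",
    subjects = slots[, c("slot", "subject_id", "level_a", "level_b")],
    design = design)
}

#' Build the 3-way (time x channel x subject) tensor for Tucker decomposition
#'
#' Stacks the signed HRF matrices directly, with the same deterministic
#' subject-slot ordering as [build_tensor_cpd()].
#'
#' @param hrfs list of [subject_hrf()] from one hemisphere
#' @param design the [design_info()]
#' @return a 3-way [hemodynamic_tensor()]
#' @export
build_tensor_td <- function(hrfs, design) {
  info <- check_hrf_consistency(hrfs)
  slots <- subject_slots(hrfs)
  arr <- array(0, c(info$epoch$n_samples, length(info$channels), nrow(slots)))
  for (s in seq_len(nrow(slots))) arr[, , s] <- hrfs[[slots$idx[s]]]$hrf
  hemodynamic_tensor(
    arr,
    mode_axes = list(time = info$epoch$times, channel = info$channels,
                     subject = paste(slots$subject_id, slots$level_a,
                                     slots$level_b, sep = "|")),
    hemisphere = hrfs[[1]]$hemisphere %||% "left",
    subjects = slots[, c("slot", "subject_id", "level_a", "level_b")],
    design = design)
}
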