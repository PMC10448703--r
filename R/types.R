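#' Define an epoch around a stimulus onset
#'
#' An epoch spans `baseline_s` seconds before onset, the stimulus
#' presentation, and `post_s` seconds after stimulus *offset*.  Time 0 is the
#' stimulus onset and windows are half-open `[start, end)`.  The sample grid
#' has `round(total * fs) + 1` points so both endpoints are on the grid.
#'
#' @param baseline_s seconds of baseline before onset (> 0)
#' @param stimulus_s seconds of stimulus presentation (> 0)
#' @param post_s seconds after stimulus offset (> 0)
#' @param fs sampling frequency in Hz (> 0)
#' @return an object of class `epoch_definition` with the sample count
#'   (`n_samples`) and the time axis in seconds relative to onset (`times`)
#' @examples
#' ep <- epoch_definition(2, 15, 10, fs = 50)
#' ep$n_samples  # 1351
#' @export
epoch_definition <- function(baseline_s = 2, stimulus_s = 15, post_s = 10,
                             fs = 50) {
  if (baseline_s <= 0 || stimulus_s <= 0 || post_s <= 0)
    nt_stop("epoch durations must all be > 0")
  if (fs <= 0) nt_stop("sampling frequency must be > 0")
  total <- baseline_s + stimulus_s + post_s
  n <- round(total * fs) + 1L
  structure(list(
    baseline_s = baseline_s, stimulus_s = stimulus_s, post_s = post_s,
    fs = fs, n_samples = as.integer(n),
    times = seq(-baseline_s, by = 1 / fs, length.out = n)
  ), class = "epoch_definition")
}

#' @export
print.epoch_definition <- function(x, ...) {
  cat(sprintf(
    "Epoch: %.3g s baseline | %.3g s stimulus | %.3g s post @ %g Hz (%d samples)\n",
    x$baseline_s, x$stimulus_s, x$post_s, x$fs, x$n_samples))
  invisible(x)
}

#' Describe a 2x2 experimental design
#'
#' Two crossed two-level factors, each either between-subjects or
#' within-subjects (at most one factor may be within; that covers both the
#' fully between-subjects and the mixed design).  For a between factor every
#' subject carries an assignment to one level; for a within factor every
#' subject contributes one hemodynamic response per level.
#'
#' @param factor_a_name,factor_b_name factor labels (e.g. "entity type",
#'   "action sequence")
#' @param scope_a,scope_b `"between"` or `"within"`
#' @param assignments data.frame with columns `subject`, and `level_a` /
#'   `level_b` for each between factor
#' @param levels_a,levels_b the two levels of each factor; for between
#'   factors they default to the sorted unique assignment values (an explicit
#'   value is useful when a subset of subjects covers only one level)
#' @param alpha significance level for component-wise tests (default 0.05)
#' @return an object of class `design_info`
#' @export
design_info <- function(factor_a_name = "factor_a", factor_b_name = "factor_b",
                        scope_a = c("between", "within"),
                        scope_b = c("between", "within"),
                        assignments, levels_a = NULL, levels_b = NULL,
                        alpha = 0.05) {
  scope_a <- match.arg(scope_a)
  scope_b <- match.arg(scope_b)
  if (scope_a == "within" && scope_b == "within")
    nt_stop("at most one factor may be within-subjects")
  if (!is.data.frame(assignments) || !"subject" %in% names(assignments))
    nt_stop("assignments must be a data.frame with a 'subject' column")
  assignments$subject <- as.character(assignments$subject)
  if (anyDuplicated(assignments$subject))
    nt_stop("duplicated subject ids in assignments")

  get_levels <- function(scope, col, levels, nm) {
    if (scope == "between") {
      if (!col %in% names(assignments))
        nt_stop("between factor '%s' needs an %s column in assignments", nm, col)
      if (anyNA(assignments[[col]]))
        nt_stop("incomplete assignment for between factor '%s'", nm)
      vals <- unique(as.character(assignments[[col]]))
      lv <- if (!is.null(levels)) as.character(levels) else sort(vals)
      if (!all(vals %in% lv))
        nt_stop("assignments use levels outside factor '%s'", nm)
    } else {
      lv <- as.character(levels %||%
        nt_stop("within factor '%s' needs explicit levels", nm))
    }
    if (length(lv) != 2) nt_stop("factor '%s' must have exactly 2 levels", nm)
    lv
  }
  levels_a <- get_levels(scope_a, "level_a", levels_a, factor_a_name)
  levels_b <- get_levels(scope_b, "level_b", levels_b, factor_b_name)
  if (alpha <= 0 || alpha >= 1) nt_stop("alpha must be in (0, 1)")

  structure(list(
    factor_a_name = factor_a_name, factor_b_name = factor_b_name,
    scope_a = scope_a, scope_b = scope_b,
    levels_a = levels_a, levels_b = levels_b,
    assignments = assignments, alpha = alpha
  ), class = "design_info")
}

#' @export
print.design_info <- function(x, ...) {
  cat(sprintf("2x2 design: %s (%s: %s) x %s (%s: %s), %d subjects, alpha=%g\n",
              x$factor_a_name, x$scope_a, paste(x$levels_a, collapse = "/"),
              x$factor_b_name, x$scope_b, paste(x$levels_b, collapse = "/"),
              nrow(x$assignments), x$alpha))
  invisible(x)
}

# condition label of a subject for each factor; within factor -> NA (varies)
design_cell <- function(design, subject) {
  row <- design$assignments[design$assignments$subject == subject, , drop = FALSE]
  if (nrow(row) != 1) nt_stop("subject '%s' not in design assignments", subject)
  list(
    level_a = if (design$scope_a == "between") as.character(row$level_a) else NA_character_,
    level_b = if (design$scope_b == "between") as.character(row$level_b) else NA_character_
  )
}

#' Default channel-to-hemisphere map
#'
#' With 2k channels, the first k are assigned to the left hemisphere and the
#' remaining k to the right (the standard 20-channel montage maps channels
#' 1-10 left and 11-20 right).
#'
#' @param channel_ids ordered channel identifiers
#' @return named character vector mapping channel id to "left"/"right"
#' @export
default_hemisphere_map <- function(channel_ids) {
  n <- length(channel_ids)
  half <- ceiling(n / 2)
  stats::setNames(rep(c("left", "right"), c(half, n - half)), channel_ids)
}

#' Construct a continuous fNIRS recording
#'
#' @param subject_id subject identifier
#' @param hbo channel x sample matrix of oxygenated-hemoglobin concentration
#'   change (micromolar); row names, if present, must equal `channel_ids`
#' @param fs sampling frequency (Hz)
#' @param trial_onsets data.frame with columns `sample` (1-based sample index
#'   of the stimulus onset), `level_a`, `level_b` (condition labels)
#' @param channel_ids ordered unique channel identifiers
#' @param hemisphere_map named character vector channel id -> "left"/"right";
#'   defaults to [default_hemisphere_map()]
#' @return an object of class `fnirs_recording`
#' @export
fnirs_recording <- function(subject_id, hbo, fs, trial_onsets, channel_ids,
                            hemisphere_map = default_hemisphere_map(channel_ids)) {
  hbo <- as.matrix(hbo)
  channel_ids <- as.character(channel_ids)
  if (anyDuplicated(channel_ids)) nt_stop("channel_ids must be unique")
  if (nrow(hbo) != length(channel_ids))
    nt_stop("hbo has %d rows but %d channel_ids", nrow(hbo), length(channel_ids))
  if (!all(channel_ids %in% names(hemisphere_map)))
    nt_stop("hemisphere map missing channels: %s",
            paste(setdiff(channel_ids, names(hemisphere_map)), collapse = ", "))
  if (!all(hemisphere_map[channel_ids] %in% c("left", "right")))
    nt_stop("hemisphere_map values must be 'left' or 'right'")
  trial_onsets <- as.data.frame(trial_onsets)
  if (nrow(trial_onsets) > 0) {
    need <- c("sample", "level_a", "level_b")
    if (!all(need %in% names(trial_onsets)))
      nt_stop("trial_onsets needs columns %s", paste(need, collapse = ", "))
    if (any(trial_onsets$sample < 1 | trial_onsets$sample > ncol(hbo)))
      nt_stop("trial onset outside recording for subject '%s'", subject_id)
  } else {
    trial_onsets <- data.frame(sample = integer(), level_a = character(),
                               level_b = character())
  }
  rownames(hbo) <- channel_ids
  structure(list(
    subject_id = as.character(subject_id), hbo = hbo, fs = fs,
    trial_onsets = trial_onsets, channel_ids = channel_ids,
    hemisphere_map = hemisphere_map[channel_ids]
  ), class = "fnirs_recording")
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("fNIRS recording '%s': %d channels x %d samples @ %g Hz, %d trial onsets\n",
              x$subject_id, nrow(x$hbo), ncol(x$hbo), x$fs, nrow(x$trial_onsets)))
  invisible(x)
}

#' Validate that every trial fits its epoch inside a recording
#'
#' @param recording an [fnirs_recording()]
#' @param epoch an [epoch_definition()]; its `fs` must equal the recording's
#' @return the recording, invisibly; errors otherwise
#' @export
validate_recording <- function(recording, epoch) {
  stopifnot(inherits(recording, "fnirs_recording"),
            inherits(epoch, "epoch_definition"))
  if (!isTRUE(all.equal(recording$fs, epoch$fs)))
    nt_stop("recording fs (%g) does not match epoch fs (%g)",
            recording$fs, epoch$fs)
  pre <- round(epoch$baseline_s * epoch$fs)
  post <- epoch$n_samples - pre - 1L
  on <- recording$trial_onsets$sample
  if (any(on - pre < 1))
    nt_stop("subject '%s': onset lacks full baseline coverage", recording$subject_id)
  if (any(on + post > ncol(recording$hbo)))
    nt_stop("subject '%s': onset + epoch length exceeds recording length",
            recording$subject_id)
  invisible(recording)
}

#' Construct a trial-averaged hemodynamic response (HRF)
#'
#' @param subject_id subject identifier
#' @param level_a,level_b condition levels of the two design factors
#' @param hrf time x channel matrix of baseline-corrected HbO (micromolar)
#' @param epoch the [epoch_definition()] the rows are aligned to
#' @param channel_ids channel identifiers (columns of `hrf`)
#' @param n_trials number of trials averaged (>= 1)
#' @param hemisphere optional hemisphere tag after splitting
#' @return an object of class `subject_hrf`
#' @export
subject_hrf <- function(subject_id, level_a, level_b, hrf, epoch, channel_ids,
                        n_trials, hemisphere = NULL) {
  hrf <- as.matrix(hrf)
  if (nrow(hrf) != epoch$n_samples)
    nt_stop("hrf has %d rows; epoch expects %d samples", nrow(hrf), epoch$n_samples)
  if (ncol(hrf) != length(channel_ids))
    nt_stop("hrf has %d columns but %d channel_ids", ncol(hrf), length(channel_ids))
  if (n_trials < 1) nt_stop("n_trials must be >= 1")
  colnames(hrf) <- channel_ids
  structure(list(
    subject_id = as.character(subject_id),
    level_a = as.character(level_a), level_b = as.character(level_b),
    hrf = hrf, epoch = epoch, channel_ids = as.character(channel_ids),
    n_trials = as.integer(n_trials), hemisphere = hemisphere
  ), class = "subject_hrf")
}

#' @export
print.subject_hrf <- function(x, ...) {
  cat(sprintf("HRF '%s' (%s, %s): %d samples x %d channels, %d trials%s\n",
              x$subject_id, x$level_a, x$level_b, nrow(x$hrf), ncol(x$hrf),
              x$n_trials,
              if (is.null(x$hemisphere)) "" else paste0(", ", x$hemisphere)))
  invisible(x)
}
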