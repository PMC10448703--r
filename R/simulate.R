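#' Canonical double-gamma hemodynamic response
#'
#' A unit-peak surrogate for the HbO impulse response: a gamma-shaped rise
#' peaking at `peak_s`, minus a later gamma undershoot scaled by
#' `undershoot_ratio`.  The curve is normalised so its maximum is exactly 1.
#'
#' @param duration_s curve length in seconds (must exceed `peak_s`)
#' @param fs sampling frequency (Hz)
#' @param peak_s time to peak in seconds (default 5, typical for infant HbO)
#' @param undershoot_ratio relative size of the post-peak undershoot
#'   (default 1/6; 0 gives an everywhere-nonnegative curve)
#' @return numeric vector of `round(duration_s * fs) + 1` samples
#' @examples
#' h <- canonical_hrf(20, fs = 10)
#' which.max(h)  # peak at ~5 s
#' @export
canonical_hrf <- function(duration_s, fs, peak_s = 5, undershoot_ratio = 1 / 6) {
  if (!(duration_s > peak_s) || peak_s <= 0)
    nt_stop("need duration_s > peak_s > 0")
  if (fs <= 0) nt_stop("fs must be > 0")
  t <- seq(0, duration_s, by = 1 / fs)
  # gamma density with rate 1 peaks at shape - 1
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = peak_s + 11, rate = 1)
  h / max(h)
}

#' Specify a planted condition effect for the simulator
#'
#' @param effect `"main_a"`, `"main_b"` or `"interaction"`
#' @param channels channel ids carrying the effect (the ground-truth ROI)
#' @param window_s `c(start_s, end_s)` relative to onset (the ground-truth
#'   TOI); must lie within the stimulus period
#' @param amplitude_delta HbO difference (micromolar) between the implicated
#'   cell means at the effect peak
#' @param cell_pattern 2x2 numeric matrix of amplitude multipliers with
#'   factor-A levels on rows and factor-B levels on columns; defaults to a
#'   one-sided pattern for main effects and a single-cell (non-additive)
#'   pattern for the interaction
#' @return an object of class `effect_spec`
#' @export
effect_spec <- function(effect = c("main_a", "main_b", "interaction"),
                        channels, window_s, amplitude_delta,
                        cell_pattern = NULL) {
  effect <- match.arg(effect)
  if (length(window_s) != 2 || window_s[1] >= window_s[2])
    nt_stop("window_s must be c(start, end) with start < end")
  if (is.null(cell_pattern)) {
    cell_pattern <- switch(effect,
      main_a = matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE),
      main_b = matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE),
      interaction = matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  }
  cell_pattern <- as.matrix(cell_pattern)
  if (!all(dim(cell_pattern) == c(2, 2)))
    nt_stop("cell_pattern must be a 2x2 matrix")
  if (effect == "interaction" &&
      abs(cell_pattern[1, 1] - cell_pattern[1, 2] -
          cell_pattern[2, 1] + cell_pattern[2, 2]) < 1e-12)
    nt_stop("interaction cell_pattern must be non-additive")
  structure(list(effect = effect, channels = as.character(channels),
                 window_s = as.numeric(window_s),
                 amplitude_delta = amplitude_delta,
                 cell_pattern = cell_pattern),
            class = "effect_spec")
}

#' Specify a synthetic multi-subject fNIRS dataset
#'
#' The defaults emulate the study conditions the pipeline targets: a 2x2
#' design with 18 subjects per cell, 20 channels (10 per hemisphere), 12
#' trials per subject, epochs of 2 s baseline / 15 s stimulus / 10 s
#' post-stimulus, a slow sinusoidal drift (~30 s period) standing in for
#' systemic physiology, and white sample noise.  Each trial's signal is the
#' sum of the planted effect waveforms scaled by the subject's cell
#' multipliers plus drift and noise; an optional condition-independent
#' response shared by all channels (`base_amp`, off by default) can be added
#' to emulate a global stimulus response.
#'
#' @param n_per_cell subjects per design cell (between factor cells)
#' @param epoch an [epoch_definition()]
#' @param n_channels number of channels (split half/half across hemispheres)
#' @param n_trials trials per subject (default 12; for a within design these
#'   are split into one block per within level)
#' @param effects list of [effect_spec()] objects
#' @param noise_sd white-noise standard deviation per sample (micromolar)
#' @param drift_amp amplitude of the sinusoidal drift (micromolar)
#' @param drift_period_s drift period in seconds
#' @param base_amp amplitude of an optional condition-independent response
#'   shared by every channel (micromolar); default 0 (none)
#' @param scope_a,scope_b `"between"` or `"within"` for the two factors
#' @param iti_s inter-trial gap appended after each epoch (s)
#' @param seed master seed; per-subject substreams are derived by fixed
#'   offsets so growing `n_per_cell` does not reshuffle existing subjects
#' @return an object of class `simulation_spec`
#' @export
simulation_spec <- function(n_per_cell = 18,
                            epoch = epoch_definition(2, 15, 10, 50),
                            n_channels = 20, n_trials = 12, effects = list(),
                            noise_sd = 1.0, drift_amp = 0.5,
                            drift_period_s = 30, base_amp = 0,
                            scope_a = "between", scope_b = "between",
                            iti_s = 2, seed = 1) {
  if (n_trials < 1) nt_stop("n_trials must be >= 1")
  if (noise_sd < 0) nt_stop("noise_sd must be >= 0")
  channel_ids <- sprintf("ch%02d", seq_len(n_channels))
  for (ef in effects) {
    stopifnot(inherits(ef, "effect_spec"))
    bad <- setdiff(ef$channels, channel_ids)
    if (length(bad))
      nt_stop("effect references nonexistent channels: %s",
              paste(bad, collapse = ", "))
    if (ef$window_s[1] < 0 || ef$window_s[2] > epoch$stimulus_s)
      nt_stop("effect window [%g, %g] must lie within the stimulus period",
              ef$window_s[1], ef$window_s[2])
  }
  if (scope_a == "within" && scope_b == "within")
    nt_stop("at most one within factor is supported")
  if (scope_a == "within" || scope_b == "within") {
    if (n_trials %% 2 != 0)
      nt_stop("a within design needs an even n_trials (one block per level)")
  }
  structure(list(
    n_per_cell = n_per_cell, epoch = epoch, n_channels = n_channels,
    channel_ids = channel_ids, n_trials = n_trials, effects = effects,
    noise_sd = noise_sd, drift_amp = drift_amp,
    drift_period_s = drift_period_s, base_amp = base_amp,
    scope_a = scope_a, scope_b = scope_b, iti_s = iti_s, seed = seed
  ), class = "simulation_spec")
}

# evaluate one planted effect's waveform on the epoch grid (0 elsewhere)
effect_waveform <- function(ef, epoch) {
  s <- ef$window_s[1]; e <- ef$window_s[2]
  mid <- (s + e) / 2
  tail_s <- epoch$stimulus_s + epoch$post_s - s
  curve <- canonical_hrf(tail_s, epoch$fs, peak_s = mid - s,
                         undershoot_ratio = 0)
  w <- numeric(epoch$n_samples)
  i0 <- round((epoch$baseline_s + s) * epoch$fs) + 1L
  idx <- i0:min(epoch$n_samples, i0 + length(curve) - 1L)
  w[idx] <- curve[seq_along(idx)]
  w
}

#' Generate a synthetic multi-subject fNIRS dataset with planted effects
#'
#' Every trial's signal is the sum of a condition-independent baseline
#' response, the planted effect waveforms scaled by the subject's cell
#' multipliers, a slow sinusoidal drift with random phase, and white noise.
#' The output is deterministic given the spec's seed.
#'
#' @param spec a [simulation_spec()]
#' @return a list of class `nirs_simulation` with elements `recordings`
#'   (list of [fnirs_recording()]), `design` (a [design_info()]),
#'   `ground_truth` (the planted [effect_spec()]s plus generator settings),
#'   `epoch`, `channel_ids` and `hemisphere_map`
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  ep <- spec$epoch
  levels_a <- c("a1", "a2"); levels_b <- c("b1", "b2")

  if (spec$scope_a == "between" && spec$scope_b == "between") {
    cells <- expand.grid(level_a = levels_a, level_b = levels_b,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    assignments <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
      data.frame(subject = character(spec$n_per_cell),
                 level_a = cells$level_a[i], level_b = cells$level_b[i])))
    assignments$subject <- sprintf("s%03d", seq_len(nrow(assignments)))
    design <- design_info("factor_a", "factor_b", "between", "between",
                          assignments = assignments)
  } else {
    # mixed design: one factor within, the other between with 2 groups
    between_is_b <- spec$scope_a == "within"
    n_sub <- 2L * spec$n_per_cell
    assignments <- data.frame(subject = sprintf("s%03d", seq_len(n_sub)))
    lv <- rep(if (between_is_b) levels_b else levels_a, each = spec$n_per_cell)
    if (between_is_b) assignments$level_b <- lv else assignments$level_a <- lv
    design <- design_info("factor_a", "factor_b", spec$scope_a, spec$scope_b,
                          assignments = assignments,
                          levels_a = levels_a, levels_b = levels_b)
  }

  base_wave <- if (spec$base_amp > 0)
    spec$base_amp * canonical_hrf(ep$stimulus_s + ep$post_s, ep$fs) else NULL
  eff_waves <- lapply(spec$effects, effect_waveform, epoch = ep)

  trial_len <- ep$baseline_s + ep$stimulus_s + ep$post_s + spec$iti_s
  lead_s <- ep$baseline_s + 1
  total_s <- lead_s + spec$n_trials * trial_len
  n_samp <- round(total_s * ep$fs) + 1L
  hemi <- default_hemisphere_map(spec$channel_ids)

  recordings <- lapply(seq_len(nrow(design$assignments)), function(si) {
    sid <- design$assignments$subject[si]
    set.seed(nt_substream(spec$seed, si))
    n_ch <- spec$n_channels
    phases <- stats::runif(n_ch, 0, 2 * pi)
    hbo <- matrix(stats::rnorm(n_ch * n_samp, sd = spec$noise_sd), n_ch, n_samp)
    tgrid <- (seq_len(n_samp) - 1) / ep$fs
    if (spec$drift_amp > 0)
      hbo <- hbo + spec$drift_amp *
        sin(outer(phases, 2 * pi * tgrid / spec$drift_period_s, `+`))

    # trial blocks: within factor levels presented block-wise
    cell <- design_cell(design, sid)
    if (spec$scope_a == "within") {
      la <- rep(levels_a, each = spec$n_trials / 2); lb <- rep(cell$level_b, spec$n_trials)
    } else if (spec$scope_b == "within") {
      la <- rep(cell$level_a, spec$n_trials); lb <- rep(levels_b, each = spec$n_trials / 2)
    } else {
      la <- rep(cell$level_a, spec$n_trials); lb <- rep(cell$level_b, spec$n_trials)
    }
    onset_samples <- integer(spec$n_trials)
    for (k in seq_len(spec$n_trials)) {
      onset_s <- lead_s + (k - 1) * trial_len
      on <- round(onset_s * ep$fs) + 1L
      onset_samples[k] <- on
      if (!is.null(base_wave)) {
        idx <- on:(on + length(base_wave) - 1L)
        hbo[, idx] <- hbo[, idx] +
          matrix(base_wave, n_ch, length(base_wave), byrow = TRUE)
      }
      for (j in seq_along(spec$effects)) {
        ef <- spec$effects[[j]]
        mult <- ef$cell_pattern[match(la[k], levels_a), match(lb[k], levels_b)]
        if (mult == 0) next
        rows <- match(ef$channels, spec$channel_ids)
        wave <- eff_waves[[j]][(round(ep$baseline_s * ep$fs) + 1L):ep$n_samples]
        idx <- on:(on + length(wave) - 1L)
        hbo[rows, idx] <- hbo[rows, idx] +
          ef$amplitude_delta * mult *
          matrix(wave, length(rows), length(wave), byrow = TRUE)
      }
    }
    fnirs_recording(sid, hbo, ep$fs,
                    data.frame(sample = onset_samples, level_a = la, level_b = lb),
                    spec$channel_ids, hemi)
  })

  structure(list(
    recordings = recordings, design = design, epoch = ep,
    channel_ids = spec$channel_ids, hemisphere_map = hemi,
    ground_truth = list(effects = spec$effects, noise_sd = spec$noise_sd,
                        drift_amp = spec$drift_amp, base_amp = spec$base_amp,
                        seed = spec$seed)
  ), class = "nirs_simulation")
}

#' @export
print.nirs_simulation <- function(x, ...) {
  cat(sprintf("Synthetic fNIRS dataset: %d subjects, %d channels, %d planted effect(s)\n",
              length(x$recordings), length(x$channel_ids),
              length(x$ground_truth$effects)))
  print(x$design)
  invisible(x)
}
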