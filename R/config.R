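#' Default pipeline configuration
#'
#' All tunable thresholds of the analysis with their defaults: relative
#' reconstruction-error threshold for rank selection (0.10), temporal
#' screening threshold on unit-norm components (0.01), spectral cutoff
#' (0.1 Hz), cross-run consensus correlation (r > 0.5), significance level
#' (0.05) and number of CPD runs (10); plus STFT, solver, TOI/ROI and
#' follow-up settings.
#'
#' @return named list of configuration values
#' @export
default_config <- function() {
  list(
    alpha = 0.05,                 # per-test significance level
    error_threshold = 0.10,       # rank selection: relative error must drop below
    temporal_threshold = 0.01,    # mean |value| during stimulus, unit-L2 components
    spectral_cutoff_hz = 0.1,     # exclude components peaking above this frequency
    consensus_r = 0.5,            # cross-run matching correlation threshold
    consensus_mode = "both",      # require temporal AND spatial match ("either" optional)
    n_runs = 10,                  # CPD restarts pooled by consensus
    r_max = 15,                   # largest CPD rank scanned
    rt_max = NULL, rc_max = NULL, # Tucker rank scan caps (NULL = mode dimension)
    stft_window_s = 10,           # STFT window length (s)
    stft_overlap = 0.75,          # fractional window overlap
    cpd_max_iter = 500, cpd_tol = 1e-8,
    td_max_iter = 200, td_tol = 1e-8,
    toi_half_width_s = 1,         # reported TOI = peak +/- this
    toi_post_peak_frac = 0.5,     # see determine_toi()
    roi_fraction = 0.5,           # ROI = channels >= fraction * max of spatial profile
    baseline_correct = TRUE,      # subtract per-channel baseline mean per trial
    resample_method = "linear",   # or "polyphase" (signal::resample)
    spectral_method = "argmax",   # or "centroid"
    bf_rscale = 0.707,            # Cauchy prior scale for JZS Bayes factors
    fdr = FALSE,                  # optional Benjamini-Hochberg across components
    hemispheres = c("left", "right")
  )
}

#' Load a pipeline configuration from YAML (or JSON)
#'
#' Missing keys take their defaults from [default_config()]; unknown keys are
#' an error (listed by name).  An empty or absent-body file yields the full
#' default configuration.
#'
#' @param path path to a YAML/JSON configuration file, or `NULL` for defaults
#' @return named configuration list
#' @examples
#' cfg <- load_config(NULL)
#' cfg$error_threshold  # 0.10
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) nt_stop("configuration file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  if (!is.list(user)) nt_stop("configuration file must contain a mapping")
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    nt_stop("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  nt_log("load_config", path = path, overridden = length(user))
  cfg
}
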