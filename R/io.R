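# Recording I/O: long-format CSV (subject, channel, time_s, hbo) with a JSON
# sidecar holding the sampling rate, trial onsets, channel order and
# hemisphere map.  The long CSV is chosen for diffability; the sidecar path
# is the CSV path with the extension replaced by .json.

sidecar_path <- function(path) sub("\\.[Cc][Ss][Vv]$", "", path) |> paste0(".json")

#' Write an fNIRS recording to disk
#'
#' @param recording an [fnirs_recording()]
#' @param path output file path (a `.csv`); a JSON sidecar with metadata is
#'   written next to it
#' @param format only `"csv"` is supported in this build (SNIRF/HDF5 export
#'   is not provided)
#' @return `path`, invisibly
#' @seealso [read_recording()]
#' @export
write_recording <- function(recording, path, format = c("csv", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf")
    nt_stop("SNIRF output is not supported in this build; use format = 'csv'")
  stopifnot(inherits(recording, "fnirs_recording"))
  n <- ncol(recording$hbo)
  times <- (seq_len(n) - 1) / recording$fs
  long <- data.frame(
    subject = recording$subject_id,
    channel = rep(recording$channel_ids, each = n),
    time_s = rep(times, times = length(recording$channel_ids)),
    hbo = as.vector(t(recording$hbo))
  )
  ok <- tryCatch({
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) nt_stop("cannot write recording to '%s'", path)
  meta <- list(
    subject_id = recording$subject_id,
    fs = recording$fs,
    n_samples = n,
    channel_ids = recording$channel_ids,
    hemisphere_map = as.list(recording$hemisphere_map),
    trial_onsets = recording$trial_onsets
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an fNIRS recording from disk
#'
#' Reads the long-format CSV written by [write_recording()] together with its
#' JSON sidecar.  Channel order is taken from the sidecar (i.e. preserved
#' from the original file).
#'
#' @param path path to the `.csv` file
#' @param format only `"csv"` is supported in this build
#' @return an [fnirs_recording()]
#' @export
read_recording <- function(path, format = c("csv", "snirf")) {
  format <- match.arg(format)
  if (format == "snirf")
    nt_stop("SNIRF input is not supported in this build; use format = 'csv'")
  if (!file.exists(path)) nt_stop("file not found: %s", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    nt_stop("configuration error: sidecar '%s' (onsets/hemisphere map) missing", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (field in c("subject_id", "fs", "n_samples", "channel_ids", "hemisphere_map"))
    if (is.null(meta[[field]]))
      nt_stop("malformed sidecar '%s': missing field '%s'", sp, field)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (field in c("subject", "channel", "time_s", "hbo"))
    if (is.null(long[[field]]))
      nt_stop("malformed recording '%s': missing column '%s'", path, field)
  channel_ids <- as.character(meta$channel_ids)
  n <- as.integer(meta$n_samples)
  if (nrow(long) != n * length(channel_ids))
    nt_stop("malformed recording '%s': %d rows, expected %d (field 'hbo')",
            path, nrow(long), n * length(channel_ids))
  hbo <- matrix(NA_real_, length(channel_ids), n,
                dimnames = list(channel_ids, NULL))
  for (ch in channel_ids) {
    rows <- long[long$channel == ch, , drop = FALSE]
    if (nrow(rows) != n)
      nt_stop("malformed recording '%s': channel '%s' has %d samples, expected %d",
              path, ch, nrow(rows), n)
    hbo[ch, ] <- rows$hbo[order(rows$time_s)]
  }
  onsets <- meta$trial_onsets
  if (is.null(onsets) || length(onsets) == 0 || NROW(onsets) == 0)
    onsets <- data.frame(sample = integer(), level_a = character(),
                         level_b = character())
  fnirs_recording(
    subject_id = meta$subject_id, hbo = hbo, fs = meta$fs,
    trial_onsets = as.data.frame(onsets), channel_ids = channel_ids,
    hemisphere_map = unlist(meta$hemisphere_map)
  )
}
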