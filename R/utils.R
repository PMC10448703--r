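#' @keywords internal
"_PACKAGE"

# Structured log line to stderr (and optional file): "stage key=value ..."
nt_log <- function(stage, ..., file = getOption("nirstensor.log_file", NULL)) {
  kv <- list(...)
  line <- paste0(
    "[nirstensor] ", stage,
    if (length(kv)) paste0(" ", paste(names(kv), vapply(kv, format, ""),
                                      sep = "=", collapse = " ")) else ""
  )
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}

nt_stop <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic substream seed, kept inside 32-bit integer range
nt_substream <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647)
}
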