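#' @keywords internal
"_PACKAGE"

# Informational logging. Quiet by default; enable with
# options(pwasoft.verbose = TRUE). Warnings always go through warning().
pwa_log <- function(...) {
  if (isTRUE(getOption("pwasoft.verbose", FALSE))) {
    message("[pwasoft] ", ...)
  }
  invisible(NULL)
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 1013 * stream) %% 2147483629L) + 1L
}

input_channels <- function() c("T", "DO", "pH", "q", "v", "p")
output_channels <- function() c("X", "P")

`%||%` <- function(a, b) if (is.null(a)) b else a
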