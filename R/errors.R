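# Classed conditions so callers (and the CLI) can map failures to exit codes:
# usage errors -> 2, file-format errors -> 3, data-integrity errors -> 4.

ukb_usage_error <- function(msg, ...) {
  abort(msg, class = "ukb_usage_error", ...)
}

ukb_format_error <- function(msg, ...) {
  abort(msg, class = "ukb_format_error", ...)
}

ukb_integrity_error <- function(msg, ...) {
  abort(msg, class = "ukb_integrity_error", ...)
}
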