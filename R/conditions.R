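# Classed error conditions so callers (and the CLI) can branch on failure mode.

qc_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "qc_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

qc_check <- function(cond, msg, class) {
  if (!isTRUE(cond)) qc_stop(msg, class)
  invisible(TRUE)
}
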