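# Classed error conditions. Every error raised by the package carries the
# class "fastsurf_error" plus a specific subclass so callers (and tests) can
# dispatch on the failure mode.

fs_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fastsurf_error"),
                      call = call))
}

fs_stopifnot <- function(cond, msg, class) {
  if (!isTRUE(cond)) fs_abort(msg, class, call = sys.call(-1))
  invisible(TRUE)
}
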