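## Structured conditions: every user-facing failure carries a class that the
## command-line front end maps to a distinct exit code.
##   usage -> 2, format -> 3, validation -> 4, anything else -> 5

stop_ligdyn <- function(type = c("validation", "format", "usage", "internal"),
                        msg, ...) {
  type <- match.arg(type)
  cond <- structure(
    class = c(paste0("ligdyn_", type, "_error"), "ligdyn_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  )
  stop(cond)
}

.ligdyn_exit_code <- function(cond) {
  if (inherits(cond, "ligdyn_usage_error")) return(2L)
  if (inherits(cond, "ligdyn_format_error")) return(3L)
  if (inherits(cond, "ligdyn_validation_error")) return(4L)
  5L
}
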