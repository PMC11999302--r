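#' @keywords internal
"_PACKAGE"

# Typed conditions so callers (and the CLI) can map failures to stages.
svi_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "svi_error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# trimmed, case-sensitive text ids (census ids are case-stable; trimming
# guards against spreadsheet artifacts)
canon_id <- function(x) trimws(as.character(x))

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stage_log <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}
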