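#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("parentA", "parentB", "hybrid")

# Errors carry a class so callers (and tests) can distinguish contract
# violations from unexpected failures.
hv_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "hvigor_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_usage  <- function(fmt, ...) hv_stop("hvigor_usage_error", fmt, ...)
stop_format <- function(fmt, ...) hv_stop("hvigor_format_error", fmt, ...)
stop_config <- function(fmt, ...) hv_stop("hvigor_config_error", fmt, ...)
stop_lookup <- function(fmt, ...) hv_stop("hvigor_lookup_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strip comment lines (leading '#') and trailing blank lines from raw
# readLines() output; all text readers share this tolerance.
drop_comment_blank <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  lines[nzchar(trimws(lines))]
}
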