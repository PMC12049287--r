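.log_level <- new.env(parent = emptyenv())
.log_level$threshold <- "info"

.level_rank <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the logging threshold
#'
#' All pipeline stages emit structured messages to `stderr`. Messages below
#' the threshold are suppressed.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous threshold, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- .log_level$threshold
  .log_level$threshold <- level
  invisible(old)
}

rf_log <- function(level, fmt, ...) {
  if (.level_rank[[level]] < .level_rank[[.log_level$threshold]]) return(invisible())
  msg <- sprintf(fmt, ...)
  cat(sprintf("[resectfit:%s] %s\n", level, msg), file = stderr())
  invisible()
}

rf_stop <- function(stage, fmt, ...) {
  stop(structure(
    class = c("resectfit_error", "error", "condition"),
    list(message = sprintf("[%s] %s", stage, sprintf(fmt, ...)), call = sys.call(-1))
  ))
}
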