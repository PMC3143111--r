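#' @keywords internal
#' Log levels: debug < info < warn.  Controlled by option "coopmods.log_level"
#' (default "info"); messages below the level are suppressed.
cm_log <- function(..., level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  threshold <- getOption("coopmods.log_level", "info")
  if (levels[[level]] >= levels[[threshold]]) {
    message(sprintf("[coopmods:%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}
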