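# Config and logging plumbing.

#' Read a YAML or JSON configuration file
#'
#' Dispatches on the file extension: `.yaml`/`.yml` via the yaml package,
#' `.json` via jsonlite. Returns a plain named list.
#'
#' @param path path to the configuration file.
#' @return named list of configuration values.
#' @export
readConfig <- function(path) {
  assert_string(path, "path")
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                stop("unsupported config extension: '.", ext,
                     "' (use .yaml, .yml or .json)"))
  if (!is.list(cfg)) stop("config must be a mapping/object at top level")
  cfg
}

KF_LOG_LEVELS <- c(debug = 10L, info = 20L, warning = 30L, error = 40L)

#' Set the package log level
#' @param level one of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @export
kfLogLevel <- function(level = c("info", "debug", "warning", "error")) {
  level <- match.arg(level)
  options(karyofuse.logLevel = level)
  invisible(level)
}

#' Emit a log message to stderr
#'
#' Messages below the level set by [kfLogLevel()] (default `"info"`) are
#' suppressed.
#'
#' @param level message severity.
#' @param ... pieces pasted into the message.
#' @export
kfLog <- function(level = c("info", "debug", "warning", "error"), ...) {
  level <- match.arg(level)
  threshold <- getOption("karyofuse.logLevel", "info")
  if (KF_LOG_LEVELS[[level]] < KF_LOG_LEVELS[[threshold]]) return(invisible())
  message(sprintf("[%s] %s %s", toupper(level),
                  format(Sys.time(), "%H:%M:%S"), paste0(..., collapse = "")))
  invisible()
}
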