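#' Read a pipeline configuration file
#'
#' YAML configuration. The main use is the site-specific mapping from
#' vendor marker strings to canonical event labels, under the key
#' `marker_map`, e.g.
#'
#' ```yaml
#' marker_map:
#'   "R128": tr_onset
#'   "S  1": stimulus
#' ```
#'
#' @param path path to a YAML file.
#' @return A named list; `$marker_map` (possibly `NULL`) is suitable for
#'   [read_eeg()].
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

.qc_env <- new.env(parent = emptyenv())
.qc_env$verbose <- FALSE

#' Toggle verbose logging
#'
#' Log lines are written to stderr with a timestamp and stage tag.
#'
#' @param on logical.
#' @return Invisibly, the previous setting.
#' @export
qc_verbose <- function(on = TRUE) {
  old <- .qc_env$verbose
  .qc_env$verbose <- isTRUE(on)
  invisible(old)
}

qc_log <- function(stage, ...) {
  if (.qc_env$verbose)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, paste0(...)))
  invisible(NULL)
}
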