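#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rpois rlnorm pchisq chisq.test runif setNames
#' @importFrom utils head
NULL

abort_schema <- function(msg, ...) abort(msg, class = "vaxtalk_schema_error", ...)
abort_validation <- function(msg, ...) abort(msg, class = "vaxtalk_validation_error", ...)
abort_config <- function(msg, ...) abort(msg, class = "vaxtalk_config_error", ...)
abort_data <- function(msg, ...) abort(msg, class = "vaxtalk_data_error", ...)
abort_param <- function(msg, ...) abort(msg, class = "vaxtalk_parameter_error", ...)

#' Canonicalize platform names
#'
#' Platform identifiers are stored in lowercase, trimmed form. The canonical
#' set covers the four large platforms commonly compared in cross-platform
#' discourse studies, but any non-empty identifier is accepted.
#'
#' @param x Character vector of platform names.
#' @return Character vector of canonical (lowercase) platform names.
#' @export
canonical_platform <- function(x) {
  out <- tolower(trimws(as.character(x)))
  if (any(is.na(out) | out == "")) {
    abort_validation("Platform names must be non-empty strings.")
  }
  out
}

#' The canonical platform set
#'
#' @return Character vector: facebook, instagram, tiktok, twitter.
#' @export
canonical_platforms <- function() c("facebook", "instagram", "tiktok", "twitter")

# first-appearance order, the deterministic platform ordering used throughout
platform_levels <- function(x) unique(x)
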