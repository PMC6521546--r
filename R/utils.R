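`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash modulo 2^31 - 1, used to derive bounded-length
#' identifiers for reified reaction nodes from their (potentially long)
#' sorted participant key lists. Stable across sessions and platforms;
#' arithmetic stays below 2^53 so doubles are exact.
#'
#' @param x character vector
#' @return character vector of 8-hex-digit hashes
#' @keywords internal
str_hash31 <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(enc2utf8(s))) h <- (h * 131 + code) %% m
    sprintf("%08x", h)
  }, character(1), USE.NAMES = FALSE)
}

#' Slugify a free-text label
#'
#' Lowercases, collapses non-alphanumeric runs to single hyphens. Used to
#' mint synthetic identifiers for entities that carry no cross-reference.
#' @param x character vector
#' @return character vector
#' @keywords internal
label_slug <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "-", x)
  x <- gsub("^-+|-+$", "", x)
  ifelse(nzchar(x), x, "unnamed")
}

stop_format <- function(...) {
  stop(structure(class = c("beltway_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

warn_beltway <- function(...) warning(paste0(...), call. = FALSE)
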