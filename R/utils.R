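#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in the yearbook tables this
#' package reproduces. Base R's `round()` rounds half to even, which disagrees
#' with printed statistical tables on exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round(0.125, 2) gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

stop_healtheil <- function(message, class = "healtheil_error", ...) {
  abort(message, class = c(class, "healtheil_error"), ...)
}

warn_healtheil <- function(message, class = "healtheil_warning", ...) {
  warn(message, class = c(class, "healtheil_warning"), ...)
}

# Parse numbers tolerating thousands separators and surrounding whitespace.
# Returns NA for cells that are not numeric after stripping separators.
parse_panel_number <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  stripped <- gsub(",", "", x, fixed = TRUE)
  suppressWarnings(as.numeric(stripped))
}
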