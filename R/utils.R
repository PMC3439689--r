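# Internal helpers shared across modules.

#' Round half away from zero, halves toward the larger value
#'
#' Classification of fractional nuclear quantities and snapping of centroids
#' onto the pixel grid both use round-half-up (0.5 rounds to 1, 2.5 to 3),
#' unlike base [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# fast tibble constructor for hot paths (skips tibble() validation)
quick_tibble <- function(lst) {
  tibble::new_tibble(lst, nrow = if (length(lst)) length(lst[[1]]) else 0L)
}

stop_cfc <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "cfcquant_error"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

CHANNELS <- c("DAPI_BLUE", "MHC_RED")

match_channel <- function(channel) {
  match.arg(toupper(channel), CHANNELS)
}

# full-precision decimal rendering for CSV round-trips
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v) && v == round(v) && abs(v) < 2^53) {
      sprintf("%.0f", v)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
}
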