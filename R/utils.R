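# Shared helpers.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (away from zero),
#' the convention used when rendering percentages in reports. `base::round()`
#' rounds halves to even, which would render 62.75 as 62.7 rather than 62.8.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Render a proportion as a percentage
#'
#' @param x proportion(s) in \[0, 1\].
#' @param digits decimal places (default 1, half-up).
#' @return percentage(s), e.g. 0.597 -> 59.7.
#' @export
as_pct <- function(x, digits = 1) round_half_up(100 * x, digits)

# Run an expression, annotating any error with the pipeline stage it came from.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}
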