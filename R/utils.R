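#' Round half away from zero
#'
#' Base `round()` rounds half to even; accuracy and sensitivity percentages
#' are conventionally reported with halves rounded up, so a dedicated helper
#' is used everywhere a metric is formatted.
#'
#' @param x Numeric vector (nonnegative in all package uses).
#' @param digits Decimal places to keep.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_up(97.35, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# derive a valid 32-bit sub-seed from a base seed and an offset
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

# stop with the pipeline stage named, so end-to-end failures are locatable
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}
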