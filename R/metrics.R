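#' Segmentation and estimation accuracy metrics
#'
#' `dice()` is the Dice coefficient `2|A∩B| / (|A|+|B|)` between two binary
#' masks (1 when both are empty); `mape()` is the mean absolute percentage
#' error of estimates against reference values, in percent.
#'
#' @param a,b Logical/0-1 masks of identical dimensions.
#' @return A scalar.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  dice_coefficient(a > 0, b > 0)
}

#' @rdname dice
#' @param estimate,truth Numeric vectors; `truth` must be non-zero.
#' @export
mape <- function(estimate, truth) {
  stopifnot(length(estimate) == length(truth), all(truth != 0))
  100 * mean(abs((estimate - truth) / truth))
}
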