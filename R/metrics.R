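#' Classification accuracy
#'
#' Fraction of predictions equal to the true labels.
#'
#' @param y_true,y_pred vectors of equal length.
#' @return scalar in [0, 1].
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ (", length(y_true), " vs ",
         length(y_pred), ")")
  mean(as.character(y_true) == as.character(y_pred))
}

#' Normalized mean squared error
#'
#' Mean squared error divided by the (population) variance of the true
#' targets, so that the trivial mean predictor scores approximately 1 and
#' smaller is better.
#'
#' @param y_true,y_pred numeric vectors of equal length; `y_true` must not be
#'   constant.
#' @return non-negative scalar.
#' @export
nmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ (", length(y_true), " vs ",
         length(y_pred), ")")
  v <- mean((y_true - mean(y_true))^2)
  if (v == 0)
    stop("y_true is constant; the NMSE normalization is undefined")
  mean((y_true - y_pred)^2) / v
}
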