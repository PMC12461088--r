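#' Activity flow mapping: predict activations from connectivity
#'
#' Predicts each node's task activation as the connectivity-weighted sum of
#' every other node's actual activation:
#' `A_hat_j = sum_(i != j) A_i * W_ij`.  A node's own activity never
#' contributes to its prediction (the FC diagonal is zero).  Columns of a
#' matrix input are treated as separate task conditions.
#'
#' @param fc An [fc_matrix] (or symmetric zero-diagonal matrix).
#' @param actual Numeric vector of node activations, or a nodes x
#'   conditions matrix.
#' @return Predicted activations, same shape as `actual`.
#' @export
predict_activations <- function(fc, actual) {
  m <- as.matrix(fc)
  a <- if (is.matrix(actual)) actual else matrix(actual, ncol = 1)
  stopifnot(nrow(a) == ncol(m))
  pred <- m %*% a
  if (is.matrix(actual)) pred else as.vector(pred)
}

#' Accuracy of activity-flow predictions
#'
#' Pearson correlation between predicted and actual activations, pooled
#' across nodes and task conditions (one value per subject in the intended
#' use).
#'
#' @param predicted,actual Vectors or nodes x conditions matrices of
#'   matching shape.
#' @return Pearson r.
#' @export
prediction_accuracy <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  cor(as.vector(as.matrix(predicted)), as.vector(as.matrix(actual)))
}
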