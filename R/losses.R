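# Loss functions of the PINN variants. All reduce to plain mean squared
# error in the documented limiting cases, which the test suite checks
# exactly.

#' Mean squared error
#' @param y,y_hat equal-length numeric vectors.
#' @return scalar MSE.
#' @export
loss_mse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("length mismatch between y and y_hat")
  mean((y - y_hat)^2)
}

#' Parallel-physics loss
#'
#' The network learns the residual of the process model: the loss compares
#' the observations with the sum of network and process predictions,
#' `MSE(y, y_NN + y_PHY)`.
#'
#' @param y observations.
#' @param y_nn network predictions.
#' @param y_phy process-model predictions.
#' @return scalar loss.
#' @export
loss_parallel <- function(y, y_nn, y_phy) {
  if (length(y) != length(y_nn) || length(y) != length(y_phy))
    abort("y, y_nn and y_phy must have equal lengths")
  loss_mse(y, y_nn + y_phy)
}

#' Physics-regularised loss
#'
#' Data term plus a consistency term tying the network to the process
#' model: `MSE(y, y_NN) + lambda * MSE(y_PHY, y_NN)`. The larger `lambda`,
#' the more strongly predictions are tied to the process model.
#'
#' @param y observations.
#' @param y_nn network predictions.
#' @param y_phy process-model predictions.
#' @param lambda regularisation weight in `[0, 1]`.
#' @return scalar loss.
#' @export
loss_regularised <- function(y, y_nn, y_phy, lambda) {
  if (lambda < 0 || lambda > 1) abort("`lambda` must be in [0, 1]")
  if (length(y) != length(y_nn) || length(y) != length(y_phy))
    abort("y, y_nn and y_phy must have equal lengths")
  loss_mse(y, y_nn) + lambda * loss_mse(y_phy, y_nn)
}

#' Physics-embedding loss
#'
#' Joint loss of the embedded architecture: the bias-correction network's
#' data term plus a regularised process contribution,
#' `MSE(y, y_NN) + lambda * MSE(y, y_PHY)`. Gradients flow into both
#' networks and through the process model.
#'
#' @param y observations.
#' @param y_nn bias-correction network predictions.
#' @param y_phy the GPP component of the embedded process-model run.
#' @param lambda weight of the process term in `[0, 1]` (default 1).
#' @return scalar loss.
#' @export
loss_embedding <- function(y, y_nn, y_phy, lambda = 1) {
  if (lambda < 0 || lambda > 1) abort("`lambda` must be in [0, 1]")
  if (length(y) != length(y_nn) || length(y) != length(y_phy))
    abort("y, y_nn and y_phy must have equal lengths")
  loss_mse(y, y_nn) + lambda * loss_mse(y, y_phy)
}
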