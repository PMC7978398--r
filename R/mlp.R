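#' Scalar output of a differentiable classifier
#'
#' Generic the attribution methods are written against: any model that can
#' report a scalar output and its input gradient can be explained. Methods
#' are provided for the `cnn1d` classifier and the toy [mlp_net()].
#'
#' @param model A supported model object.
#' @param x Numeric input vector.
#' @return A scalar model output (a probability for sigmoid-headed models).
#' @export
model_output <- function(model, x) UseMethod("model_output")

#' Gradient of the scalar model output with respect to the input
#'
#' With `guided = TRUE` the backward pass applies the guided
#' backpropagation rule at every ReLU — the signal is zeroed where either
#' the forward pre-activation or the incoming backward signal is negative —
#' and is taken on the pre-sigmoid score, the convention for guided
#' saliency.
#'
#' @inheritParams model_output
#' @param guided Apply the guided-backpropagation ReLU rule?
#' @return Numeric gradient vector, same length as `x`.
#' @export
model_input_gradient <- function(model, x, guided = FALSE) {
  UseMethod("model_input_gradient")
}

#' @export
model_output.cnn1d <- function(model, x) cnn_forward(model, x)

#' @export
model_input_gradient.cnn1d <- function(model, x, guided = FALSE) {
  fw <- cnn_forward(model, x, cache = TRUE)
  dlogit <- if (guided) 1 else fw$prob * (1 - fw$prob)
  cnn_backward_input(model, fw, dlogit = dlogit, guided = guided)
}

#' A small fully-connected network with an explicit gradient
#'
#' A zero- or one-hidden-layer network, `F(x) = w2 . act(W1 x + b1) + b2`
#' (or plain `w2 . x + b2` when `W1` is `NULL`), used as a transparent
#' testbed for the attribution contracts: completeness and
#' summation-to-delta can be checked against two forward passes, and the
#' guided-backpropagation masking rule can be verified by hand. `activation`
#' must be ReLU-family (`"relu"` or `"identity"`); saturating
#' nonlinearities are rejected by [guided_backprop()].
#'
#' @param w2 Output weight vector (length = hidden units, or input length
#'   when `W1` is `NULL`).
#' @param b2 Output bias.
#' @param W1 Optional hidden-layer weight matrix (hidden x input).
#' @param b1 Optional hidden-layer bias vector.
#' @param activation Hidden activation, `"relu"` or `"identity"`.
#' @return An object of class `mlp_net`.
#' @examples
#' lin <- mlp_net(w2 = c(1, -2, 3), b2 = 0)   # F(x) = x1 - 2 x2 + 3 x3
#' model_output(lin, c(1, 1, 1))
#' @export
mlp_net <- function(w2, b2 = 0, W1 = NULL, b1 = NULL,
                    activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (!is.null(W1) && is.null(b1)) b1 <- numeric(nrow(W1))
  structure(list(W1 = W1, b1 = b1, w2 = as.numeric(w2), b2 = b2,
                 activation = activation),
            class = "mlp_net")
}

#' @export
model_output.mlp_net <- function(model, x) {
  if (is.null(model$W1)) return(sum(model$w2 * x) + model$b2)
  z <- as.numeric(model$W1 %*% x) + model$b1
  h <- if (model$activation == "relu") relu(z) else z
  sum(model$w2 * h) + model$b2
}

#' @export
model_input_gradient.mlp_net <- function(model, x, guided = FALSE) {
  if (is.null(model$W1)) return(model$w2)
  z <- as.numeric(model$W1 %*% x) + model$b1
  dh <- model$w2
  if (model$activation == "relu") {
    dz <- dh * (z > 0)
    if (guided) dz <- dz * (dh > 0)
  } else dz <- dh
  as.numeric(crossprod(model$W1, dz))
}
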