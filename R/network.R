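#' Activation function of the network units
#'
#' All units use a steep hyperbolic tangent, `tanh(slope * x)` with slope 3 by
#' default, so activities are bounded in (-1, 1).
#'
#' @param x Pre-activation (net input), any numeric shape.
#' @param slope Slope parameter (default 3).
#' @return `tanh(slope * x)`, same shape as `x`.
#' @export
#' @examples
#' activation(0.1)
activation <- function(x, slope = 3) tanh(slope * x)

#' Derivative of the activation function
#'
#' The analytic derivative of `tanh(slope * x)` is
#' `slope * (1 - tanh(slope * x)^2)` (the default).  `derivative = "printed"`
#' drops the leading slope factor, giving `1 - tanh(slope * x)^2`; since that
#' factor is constant it is absorbable into the learning rate, and the switch
#' exists for sensitivity analysis of the update rule.
#'
#' @param x Pre-activation.
#' @inheritParams activation
#' @param derivative `"analytic"` (default) or `"printed"`.
#' @return Derivative values, same shape as `x`.
#' @export
activation_deriv <- function(x, slope = 3, derivative = c("analytic", "printed")) {
  derivative <- match.arg(derivative)
  d <- 1 - tanh(slope * x)^2
  if (derivative == "analytic") slope * d else d
}

#' Initialise a weight set
#'
#' Every weight is i.i.d. uniform on `[-init_range, init_range]`.  Layers are
#' filled in order input-to-output, each matrix column-major, so a given seed
#' always produces the same weights.
#'
#' @param layer_sizes Unit counts per layer, input first (default
#'   `c(4, 20, 20, 20, 2)`: 4 inputs, three hidden layers of 20, 2 outputs).
#' @param init_range Half-width of the uniform initialisation (default 0.01).
#' @return A list of weight matrices; element `n` has shape
#'   (units in layer n) x (units in layer n-1).
#' @export
#' @examples
#' set.seed(1)
#' w <- init_weights()
#' vapply(w, dim, integer(2))
init_weights <- function(layer_sizes = c(4, 20, 20, 20, 2), init_range = 0.01) {
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  lapply(seq_len(length(layer_sizes) - 1), function(l) {
    matrix(stats::runif(layer_sizes[l + 1] * layer_sizes[l], -init_range, init_range),
           nrow = layer_sizes[l + 1], ncol = layer_sizes[l])
  })
}

#' Forward pass through the network
#'
#' Propagates one or many input vectors through the layered network:
#' `y^n = tanh(slope * w^n %*% y^(n-1))`, with zero biases.  Optionally a
#' lesion mask zeroes the post-activation activity of selected hidden units,
#' which also removes their contribution to all downstream layers.
#'
#' @param weights List of weight matrices, as from [init_weights()].
#' @param input Numeric vector (one trial) or matrix with trials in rows.
#' @inheritParams activation
#' @param lesion Optional list of logical vectors, one per hidden layer,
#'   `TRUE` marking units whose activity is forced to 0.
#' @return A list of activity matrices (trials x units), one per layer,
#'   starting with the input layer.
#' @export
#' @examples
#' set.seed(1)
#' w <- init_weights(c(4, 3, 2))
#' forward(w, c(0.8, 0.2, 0.4, 0.4))
forward <- function(weights, input, slope = 3, lesion = NULL) {
  if (is.vector(input)) input <- matrix(input, nrow = 1)
  a <- t(input)                                    # units x trials
  out <- vector("list", length(weights) + 1)
  out[[1]] <- input
  n_hidden <- length(weights) - 1
  for (l in seq_along(weights)) {
    if (ncol(weights[[l]]) != nrow(a))
      stop("weight matrix ", l, " does not conform to layer ", l - 1, " activities")
    a <- tanh(slope * (weights[[l]] %*% a))
    if (!is.null(lesion) && l <= n_hidden && any(lesion[[l]]))
      a[lesion[[l]], ] <- 0
    out[[l + 1]] <- t(a)
  }
  out
}

#' Read the choice from the output layer
#'
#' Output unit 1 codes the right gamble and unit 2 the left gamble; the larger
#' activity wins.  Exact ties (floating equality) are broken by a fair coin,
#' supplied as uniform draws so callers control the random stream.
#'
#' @param output Numeric matrix (trials x 2) or length-2 vector of output
#'   activities `(right, left)`.
#' @param tie_u Uniform draws in \[0, 1\], one per trial, used only on ties;
#'   drawn from the current stream when missing.
#' @return Integer vector: 1 if the left gamble is chosen, 0 if the right.
#' @export
#' @examples
#' read_choice(c(0.5, 0.2))   # right -> 0
read_choice <- function(output, tie_u = NULL) {
  if (is.vector(output)) output <- matrix(output, ncol = 2)
  stopifnot(ncol(output) == 2)
  if (is.null(tie_u)) tie_u <- stats::runif(nrow(output))
  choose_left <- ifelse(output[, 1] > output[, 2], 0L,
                 ifelse(output[, 2] > output[, 1], 1L,
                        ifelse(tie_u < 0.5, 0L, 1L)))
  as.integer(choose_left)
}
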