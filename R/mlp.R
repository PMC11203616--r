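#' Specify a single-hidden-layer MLP
#'
#' Both building blocks of the models — the state-updating network(s) and
#' the output network — are MLPs with exactly one hidden layer. The hidden
#' layer and, for state-updating networks, the output layer share one
#' activation (`relu`, `tanh` or `selu`); the output network's final layer
#' uses a logistic sigmoid so that graph outputs live in (0, 1) for both
#' classification and (normalized) regression.
#'
#' @param input_dim,hidden_units,output_dim Positive integers.
#' @param hidden_activation One of `"relu"`, `"tanh"`, `"selu"`.
#' @param output_activation `"same"` (state-updating networks) or
#'   `"sigmoid"` (output network head).
#' @return An object of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim, hidden_units, output_dim,
                     hidden_activation = c("relu", "tanh", "selu"),
                     output_activation = c("same", "sigmoid")) {
  hidden_activation <- match.arg(hidden_activation)
  output_activation <- match.arg(output_activation)
  for (v in c(input_dim = input_dim, hidden_units = hidden_units,
              output_dim = output_dim)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop("MLP dimensions must be positive integers", call. = FALSE)
    }
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 output_dim = as.integer(output_dim),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation),
            class = "mlp_spec")
}

# SELU constants (self-normalizing networks, standard values)
.selu_lambda <- 1.0507009873554805
.selu_alpha <- 1.6732632423543772

activation_fun <- function(name) {
  switch(name,
         relu = function(z) pmax(z, 0),
         tanh = tanh,
         selu = function(z)
           .selu_lambda * ifelse(z > 0, z, .selu_alpha * (exp(z) - 1)),
         sigmoid = function(z) 1 / (1 + exp(-z)),
         stop("unknown activation: ", name, call. = FALSE))
}

# derivative with respect to pre-activation z
activation_grad <- function(name) {
  switch(name,
         relu = function(z) (z > 0) * 1,
         tanh = function(z) 1 - tanh(z)^2,
         selu = function(z)
           .selu_lambda * ifelse(z > 0, 1, .selu_alpha * exp(z)),
         sigmoid = function(z) { s <- 1 / (1 + exp(-z)); s * (1 - s) },
         stop("unknown activation: ", name, call. = FALSE))
}

#' Initialize the weights of an MLP
#'
#' Weights are drawn from the fan-scaled uniform distribution
#' U(-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out))) (Glorot
#' initialization); biases start at zero. Identical `(spec, seed)` pairs
#' yield bit-identical weights.
#'
#' @param spec An [mlp_spec()].
#' @param seed Integer seed.
#' @return A list with weight matrices `W1` (input x hidden), `W2`
#'   (hidden x output) and bias vectors `b1`, `b2`; the seed is kept as an
#'   attribute.
#' @export
build_mlp <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mlp_spec"))
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  w <- withr::with_seed(as.integer(seed), {
    list(W1 = glorot(spec$input_dim, spec$hidden_units),
         b1 = numeric(spec$hidden_units),
         W2 = glorot(spec$hidden_units, spec$output_dim),
         b2 = numeric(spec$output_dim))
  })
  attr(w, "seed") <- as.integer(seed)
  w
}

#' Evaluate an MLP on a batch of input rows
#'
#' @param weights Weights from [build_mlp()].
#' @param spec The owning [mlp_spec()].
#' @param input Numeric matrix with `spec$input_dim` columns (a single
#'   vector is treated as one row).
#' @param cache Keep pre-activations for backpropagation?
#' @return The output matrix (rows = input rows); with `cache = TRUE`, a
#'   list `(output, input, Z1, H, Z2)`.
#' @export
mlp_forward <- function(weights, spec, input, cache = FALSE) {
  if (is.null(dim(input))) input <- matrix(input, nrow = 1L)
  if (ncol(input) != spec$input_dim) {
    stop("input has ", ncol(input), " columns; spec expects ",
         spec$input_dim, call. = FALSE)
  }
  act <- activation_fun(spec$hidden_activation)
  out_act_name <- if (spec$output_activation == "same")
    spec$hidden_activation else "sigmoid"
  Z1 <- sweep(input %*% weights$W1, 2L, weights$b1, `+`)
  H <- act(Z1)
  Z2 <- sweep(H %*% weights$W2, 2L, weights$b2, `+`)
  out <- activation_fun(out_act_name)(Z2)
  if (!cache) return(out)
  list(output = out, input = input, Z1 = Z1, H = H, Z2 = Z2)
}

# Backward pass through one MLP. d_out = dL/d(output); returns gradient
# list (gW1, gb1, gW2, gb2) and dL/d(input).
mlp_backward <- function(weights, spec, cache, d_out) {
  out_act_name <- if (spec$output_activation == "same")
    spec$hidden_activation else "sigmoid"
  dZ2 <- d_out * activation_grad(out_act_name)(cache$Z2)
  gW2 <- crossprod(cache$H, dZ2)
  gb2 <- colSums(dZ2)
  dH <- dZ2 %*% t(weights$W2)
  dZ1 <- dH * activation_grad(spec$hidden_activation)(cache$Z1)
  gW1 <- crossprod(cache$input, dZ1)
  gb1 <- colSums(dZ1)
  d_input <- dZ1 %*% t(weights$W1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       d_input = d_input)
}
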