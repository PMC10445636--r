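# Feed-forward networks: the three skip-connection layer variants, the
# activation menu, and the type embedding.  Layers act on row-vectors, so a
# batch is an n x N1 matrix and a layer computes phi(x %*% w + b), optionally
# scaled by the "timestep" vector w-hat and combined with the identity (or
# duplicated-identity) skip when the widths allow it.

ACTIVATIONS <- c("tanh", "relu", "relu6", "softplus", "sigmoid", "gelu",
                 "identity")

act_val <- function(name, x) {
  switch(name,
    tanh = tanh(x),
    relu = pmax(x, 0),
    relu6 = pmin(pmax(x, 0), 6),
    softplus = ifelse(x > 30, x, log1p(exp(pmin(x, 30)))),
    sigmoid = stats::plogis(x),
    gelu = x * stats::pnorm(x),
    identity = x,
    stop("unknown activation function: ", name, call. = FALSE))
}

act_d1 <- function(name, x) {
  switch(name,
    tanh = 1 - tanh(x)^2,
    relu = (x > 0) + 0,
    relu6 = (x > 0 & x < 6) + 0,
    softplus = stats::plogis(x),
    sigmoid = { s <- stats::plogis(x); s * (1 - s) },
    gelu = stats::pnorm(x) + x * stats::dnorm(x),
    identity = array(1, dim(x) %||% length(x)),
    stop("unknown activation function: ", name, call. = FALSE))
}

act_d2 <- function(name, x) {
  switch(name,
    tanh = { t <- tanh(x); -2 * t * (1 - t^2) },
    relu = 0 * x,
    relu6 = 0 * x,
    softplus = { s <- stats::plogis(x); s * (1 - s) },
    sigmoid = { s <- stats::plogis(x); s * (1 - s) * (1 - 2 * s) },
    gelu = stats::dnorm(x) * (2 - x^2),
    identity = 0 * x,
    stop("unknown activation function: ", name, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# C1-smooth activations: relu/relu6 are excluded wherever smooth forces or
# compression are requested
act_is_smooth <- function(name) !(name %in% c("relu", "relu6"))

#' Evaluate an activation function
#'
#' The activation menu of the network layers: `tanh`, `relu`, `relu6`,
#' `softplus`, `sigmoid`, `gelu` (exact, error-function form) and `identity`.
#' `relu` and `relu6` are not continuous in the first derivative and are
#' rejected by operations that require smooth forces (model compression,
#' force training with smoothness guarantees).
#'
#' @param name activation name.
#' @param x numeric vector or matrix.
#' @param deriv 0, 1 or 2: value, first or second derivative.
#' @return numeric of the same shape as `x`.
#' @export
activation_fn <- function(name, x, deriv = 0L) {
  if (!name %in% ACTIVATIONS)
    stop("unknown activation function: ", name, call. = FALSE)
  switch(as.character(deriv),
         "0" = act_val(name, x),
         "1" = act_d1(name, x),
         "2" = act_d2(name, x),
         stop("deriv must be 0, 1 or 2", call. = FALSE))
}

# Layer and network construction -------------------------------------------

new_layer <- function(n_in, n_out, activation = "tanh", resnet_dt = FALSE,
                      resnet = TRUE, rng = NULL) {
  w <- matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(n_in + n_out)),
              n_in, n_out)
  b <- matrix(stats::rnorm(n_out), 1L, n_out)
  idt <- if (resnet_dt) matrix(stats::rnorm(n_out, mean = 0.1, sd = 0.001),
                               1L, n_out) else NULL
  list(w = w, b = b, idt = idt, activation = activation, resnet = resnet)
}

#' Construct a feed-forward network
#'
#' Builds the layer stack of a fitting or embedding network.  Consecutive
#' layer widths chain from `n_in` through `neuron`; when a layer has equal
#' (or doubled) input and output width and `resnet` is enabled, the identity
#' (or duplicated identity) skip connection is added.  A final linear layer
#' of width `n_out` is appended when `n_out` is not `NULL`.
#'
#' @param n_in input width.
#' @param neuron integer vector of hidden-layer widths.
#' @param n_out width of the trailing linear output layer, or `NULL`.
#' @param activation hidden-layer activation name.
#' @param resnet_dt enable the trainable "timestep" vector on skip layers.
#' @param resnet enable skip connections where widths allow.
#' @return a network object (list of layers).
#' @export
new_network <- function(n_in, neuron, n_out = NULL, activation = "tanh",
                        resnet_dt = FALSE, resnet = TRUE) {
  widths <- c(n_in, neuron)
  layers <- list()
  for (k in seq_along(neuron))
    layers[[k]] <- new_layer(widths[k], widths[k + 1L], activation,
                             resnet_dt = resnet_dt, resnet = resnet)
  if (!is.null(n_out))
    layers[[length(layers) + 1L]] <-
      new_layer(widths[length(widths)], n_out, "identity",
                resnet_dt = FALSE, resnet = FALSE)
  structure(list(layers = layers, n_in = n_in), class = "dp_network")
}

layer_mode <- function(n1, n2, resnet) {
  if (resnet && n2 == n1) "skip" else if (resnet && n2 == 2L * n1) "dup"
  else "plain"
}

#' Apply one network layer
#'
#' Computes `what ⊙ phi(x w + b)` plus the identity skip when the output
#' width equals the input width, the duplicated identity `{x, x}` when it is
#' twice the input width, and no skip otherwise.
#'
#' @param x input matrix (rows are samples).
#' @param layer a layer as produced by [new_network()].
#' @return output matrix.
#' @export
layer_forward <- function(x, layer) {
  x <- as_mat(if (is.matrix(x)) x else matrix(x, nrow = 1L))
  if (ncol(x) != nrow(layer$w))
    stop("layer_forward: input width ", ncol(x), " does not match layer (",
         nrow(layer$w), " x ", ncol(layer$w), ")", call. = FALSE)
  h <- act_val(layer$activation,
               x %*% layer$w + rep(layer$b, each = nrow(x)))
  if (!is.null(layer$idt)) h <- h * rep(as.vector(layer$idt), each = nrow(h))
  switch(layer_mode(nrow(layer$w), ncol(layer$w), layer$resnet),
         skip = h + x, dup = h + cbind(x, x), plain = h)
}

#' Evaluate a network
#'
#' @param net a network from [new_network()].
#' @param x input matrix (rows are samples) or vector (one sample).
#' @return output matrix.
#' @export
network_forward <- function(net, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  for (layer in net$layers) x <- layer_forward(x, layer)
  x
}

# Tape version: param_ids is a list per layer with nodes w, b, (idt)
net_forward_tape <- function(tape, net, x_id, param_ids) {
  for (k in seq_along(net$layers)) {
    layer <- net$layers[[k]]
    p <- param_ids$layers[[k]]
    a <- ad_addbias(tape, ad_matmul(tape, x_id, p$w), p$b)
    h <- if (layer$activation == "identity") a else
      ad_act(tape, layer$activation, a)
    if (!is.null(p$idt)) h <- ad_scale_cols(tape, h, p$idt)
    x_id <- switch(layer_mode(nrow(layer$w), ncol(layer$w), layer$resnet),
      skip = ad_add(tape, h, x_id),
      dup = ad_add(tape, h, ad_concat_cols(tape, c(x_id, x_id))),
      plain = h)
  }
  x_id
}

# Exact value/first/second derivative propagation for one-input networks,
# used by the tabulation step of model compression.  x is a numeric vector of
# scalar inputs; returns list(y, d1, d2), each length(x) x M.
net_eval_d2 <- function(net, x) {
  stopifnot(net$n_in == 1L)
  n <- length(x)
  v <- matrix(x, n, 1L); d1 <- matrix(1, n, 1L); d2 <- matrix(0, n, 1L)
  for (layer in net$layers) {
    if (!act_is_smooth(layer$activation))
      stop("network with ", layer$activation,
           " activation is not twice differentiable", call. = FALSE)
    a <- v %*% layer$w + rep(layer$b, each = n)
    a1 <- d1 %*% layer$w
    a2 <- d2 %*% layer$w
    p1 <- act_d1(layer$activation, a)
    h <- act_val(layer$activation, a)
    h1 <- p1 * a1
    h2 <- act_d2(layer$activation, a) * a1^2 + p1 * a2
    if (!is.null(layer$idt)) {
      s <- rep(as.vector(layer$idt), each = n)
      h <- h * s; h1 <- h1 * s; h2 <- h2 * s
    }
    mode <- layer_mode(nrow(layer$w), ncol(layer$w), layer$resnet)
    if (mode == "skip") {
      h <- h + v; h1 <- h1 + d1; h2 <- h2 + d2
    } else if (mode == "dup") {
      h <- h + cbind(v, v); h1 <- h1 + cbind(d1, d1); h2 <- h2 + cbind(d2, d2)
    }
    v <- h; d1 <- h1; d2 <- h2
  }
  list(y = v, d1 = d1, d2 = d2)
}

# Type embedding ------------------------------------------------------------

#' Construct a type-embedding network
#'
#' Maps the one-hot encoding of a chemical species to a learned embedding
#' vector, so that all species can share a single embedding or fitting
#' network.
#'
#' @param n_types number of chemical species.
#' @param neuron layer widths of the embedding network.
#' @param activation activation name.
#' @param resnet_dt enable trainable timesteps.
#' @return a type-embedding object.
#' @export
new_type_embedding <- function(n_types, neuron = c(8L), activation = "tanh",
                               resnet_dt = FALSE) {
  structure(list(net = new_network(n_types, neuron, n_out = NULL,
                                   activation = activation,
                                   resnet_dt = resnet_dt),
                 n_types = n_types, dim = neuron[length(neuron)]),
            class = "dp_type_embedding")
}

#' Evaluate the type embedding of one or more species
#'
#' @param alpha integer vector of 0-based species indices.
#' @param te a type embedding from [new_type_embedding()].
#' @return matrix with one embedding row per entry of `alpha`.
#' @export
type_embedding <- function(alpha, te) {
  if (any(alpha < 0L) || any(alpha >= te$n_types))
    stop("species index out of range [0, ", te$n_types, ")", call. = FALSE)
  onehot <- diag(te$n_types)[alpha + 1L, , drop = FALSE]
  network_forward(te$net, onehot)
}
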