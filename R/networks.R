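# Activation functions -------------------------------------------------------

act_fun <- function(name) {
  switch(name,
    elu = function(z) ifelse(z > 0, z, exp(z) - 1),
    relu = function(z) pmax(z, 0),
    tanh = tanh,
    identity = identity,
    stop("unknown activation: ", name)
  )
}

act_grad <- function(name) {
  switch(name,
    elu = function(z) ifelse(z > 0, 1, exp(z)),
    relu = function(z) (z > 0) * 1,
    tanh = function(z) 1 - tanh(z)^2,
    identity = function(z) rep(1, length(z)),
    stop("unknown activation: ", name)
  )
}

# default activation schedule: nonlinear hidden layers, linear last layer
default_activations <- function(n_layers, hidden = "elu") {
  c(rep(hidden, max(0, n_layers - 1)), "identity")
}

check_layer_dims <- function(W, b, input_dim, layer) {
  if (ncol(W) != input_dim)
    stop("shape error at layer ", layer, ": weight expects input dim ",
         ncol(W), ", got ", input_dim)
  if (length(b) != nrow(W))
    stop("shape error at layer ", layer, ": bias length ", length(b),
         " != output dim ", nrow(W))
}

#' Graph-convolutional forward pass
#'
#' Each layer computes `phi_l(W_l %*% (H_{l-1} %*% A_norm) + b_l)`: features
#' are linearly mapped and smoothed over the symmetric normalised adjacency
#' (features on the left, the N x N graph operator on the right).
#'
#' @param X input matrix (features x spots), layer 0 of the stack.
#' @param A_norm symmetric normalised adjacency ([normalize_adjacency()]) or
#'   a `spatial_graph`.
#' @param layers list of `list(W, b)` per layer, input to latent.
#' @param activations character vector of activation names per layer
#'   (default: ELU on hidden layers, identity at the latent layer).
#' @return List of layer representations `H[[1]] .. H[[K]]` (layer 0 = `X`
#'   is not repeated).
#' @export
gcn_forward <- function(X, A_norm, layers,
                        activations = default_activations(length(layers))) {
  if (inherits(A_norm, "spatial_graph")) A_norm <- A_norm$A_norm
  H <- X
  out <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    check_layer_dims(layers[[l]]$W, layers[[l]]$b, nrow(H), l)
    Z <- layers[[l]]$W %*% as.matrix(H %*% A_norm) + layers[[l]]$b
    H <- act_fun(activations[l])(Z)
    out[[l]] <- H
  }
  out
}

#' Multilayer-perceptron forward pass
#'
#' Standard affine + activation stack, `phi_l(W_l %*% H_{l-1} + b_l)`, used
#' for the image-feature branch (and the spatial branch under the
#' no-spatial ablation).
#'
#' @inheritParams gcn_forward
#' @return List of layer representations.
#' @export
mlp_forward <- function(X, layers,
                        activations = default_activations(length(layers))) {
  H <- X
  out <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    check_layer_dims(layers[[l]]$W, layers[[l]]$b, nrow(H), l)
    Z <- layers[[l]]$W %*% H + layers[[l]]$b
    H <- act_fun(activations[l])(Z)
    out[[l]] <- H
  }
  out
}

#' Variational encoder forward pass
#'
#' Deterministic hidden layers followed by two affine heads producing the
#' posterior mean and log-variance; the latent sample is drawn by the
#' reparameterisation `mu + sigma * eps` with standard-normal `eps` under
#' the given seed. In eval mode (`sample = FALSE`) the mean is returned as
#' the latent representation, deterministically.
#'
#' @param X input matrix (genes x spots).
#' @param hidden list of `list(W, b)` for the deterministic hidden layers.
#' @param mu_head,logvar_head `list(W, b)` for the two heads at layer K.
#' @param activation hidden-layer activation name (default `"elu"`).
#' @param seed RNG seed for the reparameterisation draw.
#' @param sample logical; FALSE returns `mu` as the latent layer.
#' @return List with `H` (layer list 1..K, the last entry the latent
#'   sample or mean), `mu`, `logvar`, `eps`.
#' @export
vae_encode <- function(X, hidden, mu_head, logvar_head, activation = "elu",
                       seed = 0, sample = TRUE) {
  H <- X
  out <- vector("list", length(hidden) + 1)
  for (l in seq_along(hidden)) {
    check_layer_dims(hidden[[l]]$W, hidden[[l]]$b, nrow(H), l)
    H <- act_fun(activation)(hidden[[l]]$W %*% H + hidden[[l]]$b)
    out[[l]] <- H
  }
  mu <- mu_head$W %*% H + mu_head$b
  logvar <- logvar_head$W %*% H + logvar_head$b
  eps <- NULL
  if (sample) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    z <- mu + exp(logvar / 2) * eps
  } else {
    z <- mu
  }
  out[[length(hidden) + 1]] <- z
  list(H = out, mu = mu, logvar = logvar, eps = eps)
}

#' Attention fusion of modality-specific representations
#'
#' Per spot, each modality's latent column `h` is scored by the shared
#' attention vector as `w_att' tanh(W h + b)`; a softmax over the modality
#' scores yields per-spot weights `alpha` (a probability simplex), and the
#' fused representation is the alpha-weighted sum of the modality columns.
#'
#' @param H_list list of latent matrices (latent_dim x N), one per modality.
#' @param W attention projection, D' x latent_dim.
#' @param w_att shared attention vector, length D'.
#' @param b attention bias, length D'.
#' @return List with `H` (latent_dim x N fused representation) and `alpha`
#'   (modalities x N weights, columns summing to 1).
#' @export
attention_fuse <- function(H_list, W, w_att, b) {
  m <- length(H_list)
  N <- ncol(H_list[[1]])
  scores <- matrix(0, m, N)
  for (j in seq_len(m)) {
    T_j <- tanh(W %*% H_list[[j]] + b)
    scores[j, ] <- colSums(w_att * T_j)
  }
  alpha <- col_softmax(scores)
  H <- matrix(0, nrow(H_list[[1]]), N)
  for (j in seq_len(m)) H <- H + H_list[[j]] * rep(alpha[j, ], each = nrow(H))
  list(H = H, alpha = alpha)
}

# column-wise softmax with max-shift for numerical stability
col_softmax <- function(S) {
  S <- S - rep(apply(S, 2, max), each = nrow(S))
  E <- exp(S)
  E / rep(colSums(E), each = nrow(S))
}

#' Decoder forward pass
#'
#' Affine stack mapping the fused latent representation back to expression
#' space; the final layer is linear, producing the mean of the Gaussian
#' reconstruction likelihood.
#'
#' @param H fused latent representation (latent_dim x N).
#' @param layers list of `list(W, b)`, latent back to gene space.
#' @param activations activation names per layer (default: ELU hidden,
#'   identity output).
#' @return Reconstructed expression matrix (genes x spots).
#' @export
decode_latent <- function(H, layers,
                          activations = default_activations(length(layers))) {
  out <- mlp_forward(H, layers, activations)
  out[[length(out)]]
}

# Glorot-uniform initialisation ----------------------------------------------

glorot <- function(nout, nin) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -r, r), nout, nin)
}
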