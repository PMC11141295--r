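#' Gaussian kernel between two vectors
#'
#' `K(x, y) = exp(-||x - y||^2 / (2 * bandwidth^2))`; bandwidth 1 gives the
#' canonical `exp(-||x - y||^2 / 2)` kernel used throughout the alignment
#' losses.
#'
#' @param x,y numeric vectors of equal length.
#' @param bandwidth positive kernel bandwidth (default 1).
#' @return A real in (0, 1].
#' @export
gaussian_kernel <- function(x, y, bandwidth = 1) {
  if (length(x) != length(y)) stop("shape error: x and y must have equal length")
  if (bandwidth <= 0) stop("parameter error: bandwidth must be positive")
  exp(-sum((x - y)^2) / (2 * bandwidth^2))
}

# Gaussian kernel matrix between columns of X (d x n) and Y (d x m)
kernel_matrix <- function(X, Y, bandwidth = 1) {
  exp(-sq_dist(X, Y) / (2 * bandwidth^2))
}

#' Squared maximum mean discrepancy between two samples
#'
#' Columns of `X` and `Y` are sample points. Under the default
#' `standard_biased` estimator the biased V-statistic is used:
#' `(1/n^2) sum K(x, x') - (2/(n m)) sum K(x, y) + (1/m^2) sum K(y, y')`,
#' which is zero when the two empirical samples coincide. The `as_printed`
#' estimator applies coefficient 1 to the cross term (and requires
#' `n == m`); it does not vanish for identical samples and is retained only
#' as a diagnostic variant. Multiple bandwidths are averaged.
#'
#' @param X d x n matrix of sample columns.
#' @param Y d x m matrix of sample columns.
#' @param bandwidths positive reals (default 1).
#' @param estimator `"standard_biased"` (default) or `"as_printed"`.
#' @return Non-negative real (for the standard estimator).
#' @export
mmd2 <- function(X, Y, bandwidths = 1,
                 estimator = c("standard_biased", "as_printed")) {
  estimator <- match.arg(estimator)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("shape error: X and Y must share dimension")
  n <- ncol(X); m <- ncol(Y)
  if (n < 1 || m < 1) stop("parameter error: empty sample")
  if (estimator == "as_printed" && n != m)
    stop("as_printed estimator requires equal sample sizes")
  cross_coef <- if (estimator == "standard_biased") 2 else 1
  val <- 0
  for (bw in bandwidths) {
    val <- val +
      sum(kernel_matrix(X, X, bw)) / n^2 -
      cross_coef * sum(kernel_matrix(X, Y, bw)) / (n * m) +
      sum(kernel_matrix(Y, Y, bw)) / m^2
  }
  val / length(bandwidths)
}

# Weighted MMD^2 machinery ----------------------------------------------------
#
# Both alignment losses reduce to the same bilinear form: given a symmetric
# non-negative weight matrix C over spot pairs,
#   f(X, Y) = sum(C * Kxx) - 2 * sum(C * Kxy) + sum(C * Kyy).
# The global loss uses C = 1/N^2 (all pairs); the spatially local loss uses
# C = sum_i m_i m_i' / k^2 where m_i indicates the neighbour set of spot i,
# which reproduces the per-spot neighbour MMD summed over spots. Gradients
# with respect to the sample columns are returned for backpropagation.

# C for the local loss from neighbour index lists (dense N x N, symmetric)
local_weight_matrix <- function(neighbors, spots = NULL) {
  N <- length(neighbors)
  C <- matrix(0, N, N)
  idx <- if (is.null(spots)) seq_len(N) else spots
  for (i in idx) {
    s <- neighbors[[i]]
    C[s, s] <- C[s, s] + 1 / length(s)^2
  }
  C
}

# f and gradients for weighted MMD^2; C symmetric. cross_coef is the
# coefficient on the cross term (2 = standard biased V-statistic, 1 = the
# diagnostic variant). Returns list(value, gX, gY).
weighted_mmd_grad <- function(X, Y, C, bandwidths = 1, want_grad = TRUE,
                              cross_coef = 2) {
  val <- 0
  gX <- if (want_grad) matrix(0, nrow(X), ncol(X)) else NULL
  gY <- if (want_grad) matrix(0, nrow(Y), ncol(Y)) else NULL
  for (bw in bandwidths) {
    ib2 <- 1 / bw^2
    Kxx <- kernel_matrix(X, X, bw)
    Kxy <- kernel_matrix(X, Y, bw)
    Kyy <- kernel_matrix(Y, Y, bw)
    val <- val + sum(C * Kxx) - cross_coef * sum(C * Kxy) + sum(C * Kyy)
    if (want_grad) {
      P <- C * Kxx          # symmetric
      Q <- C * Kxy
      R <- C * Kyy          # symmetric
      rsP <- rowSums(P); rsQ <- rowSums(Q); csQ <- colSums(Q); rsR <- rowSums(R)
      # d/dX [sum(C*Kxx)]            = (2/bw^2) (X P - X diag(rsP))
      # d/dX [-cc sum(C*Kxy)]        = (cc/bw^2) (X diag(rsQ) - Y t(Q))
      gX <- gX + ib2 * (2 * (X %*% P - X * rep(rsP, each = nrow(X))) +
                        cross_coef * (X * rep(rsQ, each = nrow(X)) - Y %*% t(Q)))
      gY <- gY + ib2 * (2 * (Y %*% R - Y * rep(rsR, each = nrow(Y))) +
                        cross_coef * (Y * rep(csQ, each = nrow(Y)) - X %*% Q))
    }
  }
  list(value = val / length(bandwidths),
       gX = if (want_grad) gX / length(bandwidths) else NULL,
       gY = if (want_grad) gY / length(bandwidths) else NULL)
}

#' Global distribution-alignment loss
#'
#' Sums, over encoder layers `l = 1..K`, the squared MMD between the
#' expression-branch representation and each of the other branches:
#' `sum_l MMD^2(H2_l, H1_l) + MMD^2(H2_l, H3_l)`, treating spots as sample
#' points. A missing branch (ablation) contributes zero.
#'
#' @param H2 list of layer representations (each latent x spots) for the
#'   expression (VAE) branch, layers 1..K.
#' @param H1 list for the spatial (GCN) branch, or NULL.
#' @param H3 list for the image branch, or NULL.
#' @param bandwidths kernel bandwidths (default 1).
#' @param estimator MMD estimator, see [mmd2()].
#' @return Non-negative real.
#' @export
global_alignment_loss <- function(H2, H1 = NULL, H3 = NULL, bandwidths = 1,
                                  estimator = "standard_biased") {
  loss <- 0
  for (l in seq_along(H2)) {
    if (!is.null(H1))
      loss <- loss + mmd2(H2[[l]], H1[[l]], bandwidths, estimator)
    if (!is.null(H3))
      loss <- loss + mmd2(H2[[l]], H3[[l]], bandwidths, estimator)
  }
  loss
}

#' Spatially local distribution-alignment loss
#'
#' For every layer `l` and every spot `i`, the squared MMD between the
#' columns of the expression-branch representation restricted to spot i's
#' spatial neighbours and the same columns of each other branch, summed over
#' layers and spots. With `spot_subsample` set, a seeded subsample of spots
#' is averaged and rescaled by N, which is unbiased for the full sum.
#'
#' @param H2,H1,H3 per-layer representation lists as in
#'   [global_alignment_loss()]; H1/H3 may be NULL (ablations).
#' @param neighbors spatial neighbour lists ([spatial_knn()]) or a
#'   `spatial_graph`.
#' @param bandwidths kernel bandwidths (default 1).
#' @param spot_subsample optional number of spots to sample per evaluation.
#' @param seed RNG seed for the subsample.
#' @param estimator MMD estimator, see [mmd2()].
#' @return Non-negative real.
#' @export
local_alignment_loss <- function(H2, H1 = NULL, H3 = NULL, neighbors,
                                 bandwidths = 1, spot_subsample = NULL,
                                 seed = 0, estimator = "standard_biased") {
  cc <- if (identical(estimator, "as_printed")) 1 else 2
  if (inherits(neighbors, "spatial_graph")) neighbors <- neighbors$neighbors
  N <- length(neighbors)
  spots <- seq_len(N)
  scale <- 1
  if (!is.null(spot_subsample) && spot_subsample < N) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    spots <- sample.int(N, spot_subsample)
    scale <- N / spot_subsample
  }
  C <- local_weight_matrix(neighbors, spots)
  loss <- 0
  for (l in seq_along(H2)) {
    if (!is.null(H1))
      loss <- loss + weighted_mmd_grad(H2[[l]], H1[[l]], C, bandwidths,
                                       want_grad = FALSE, cross_coef = cc)$value
    if (!is.null(H3))
      loss <- loss + weighted_mmd_grad(H2[[l]], H3[[l]], C, bandwidths,
                                       want_grad = FALSE, cross_coef = cc)$value
  }
  loss * scale
}

# save/restore the global RNG state so internal seeding is side-effect free
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
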