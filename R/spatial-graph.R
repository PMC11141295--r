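#' k-nearest spatial neighbours
#'
#' Euclidean k-nearest neighbours of each spot (self excluded). Ties are
#' broken in favour of the lower spot index, so the result is deterministic.
#'
#' @param coords N x 2 coordinate matrix.
#' @param k number of neighbours; must satisfy `k < N`.
#' @return A list of length N of integer vectors, each ordered by increasing
#'   distance.
#' @export
spatial_knn <- function(coords, k) {
  coords <- as.matrix(coords)
  N <- nrow(coords)
  if (k >= N) stop("parameter error: k must be smaller than the number of spots")
  if (k < 1) stop("parameter error: k must be positive")
  d2 <- sq_dist(t(coords), t(coords))
  lapply(seq_len(N), function(i) {
    di <- d2[i, ]
    di[i] <- Inf
    # order() is stable: equal distances resolve to the lower index
    order(di)[seq_len(k)]
  })
}

# pairwise squared Euclidean distances between columns of X (d x n) and Y (d x m)
sq_dist <- function(X, Y) {
  n <- ncol(X)
  d2 <- -2 * crossprod(X, Y)
  d2 <- d2 + colSums(X^2)                 # recycled down columns
  d2 <- d2 + rep(colSums(Y^2), each = n)  # one value per column
  d2[d2 < 0] <- 0
  d2
}

#' Expression-similarity weights on the spatial neighbour graph
#'
#' For each spot i and each of its spatial neighbours j, a similarity
#' `D_ij = exp(2 - d)` is computed from the PCA embedding of expression and
#' normalised over the neighbour support of each column so that every
#' column of the resulting weight matrix sums to 1 on its support.
#'
#' Under the default `"cosine_distance"` convention, `d = 1 - cos(U_i, U_j)`
#' (the cosine distance, in `[0, 2]`), so similar neighbours receive larger
#' weight. Under `"as_printed"`, `d = cos(U_i, U_j)` — the cosine similarity
#' itself enters the exponent, giving larger weight to anti-correlated
#' neighbours; this variant is kept for comparison.
#'
#' Zero-norm embedding columns yield a similarity of 0 for the affected
#' pairs (with a message).
#'
#' @param U a `pca_embedding` or an n_pcs x N score matrix, columns aligned
#'   to spots.
#' @param neighbors neighbour lists from [spatial_knn()].
#' @param convention `"cosine_distance"` (default) or `"as_printed"`.
#' @return A sparse N x N [Matrix::dgCMatrix-class]; entry (i, j) is the
#'   weight of neighbour pair i -> j, column-normalised on the neighbour
#'   support.
#' @export
similarity_weights <- function(U, neighbors,
                               convention = c("cosine_distance", "as_printed")) {
  convention <- match.arg(convention)
  if (inherits(U, "pca_embedding")) U <- U$U
  U <- as.matrix(U)
  N <- length(neighbors)
  if (ncol(U) != N) stop("U columns must align with spots")
  norms <- sqrt(colSums(U^2))
  zero <- norms == 0
  if (any(zero)) message(sum(zero), " spot(s) with zero-norm embedding; ",
                         "their similarities are set to 0")
  ii <- rep.int(seq_len(N), lengths(neighbors))
  jj <- unlist(neighbors, use.names = FALSE)
  cosv <- colSums(U[, ii, drop = FALSE] * U[, jj, drop = FALSE]) /
    (norms[ii] * norms[jj])
  w <- ifelse(zero[ii] | zero[jj], 0,
              if (convention == "cosine_distance") exp(2 - (1 - cosv))
              else exp(2 - cosv))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(N, N))
  # normalise each column over its neighbour support (sum over i of D_ij)
  cs <- Matrix::colSums(A)
  cs[cs == 0] <- 1
  A %*% Matrix::Diagonal(N, 1 / cs)
}

#' Symmetric normalisation of the adjacency matrix
#'
#' Symmetrises `A` as `(A + t(A)) / 2`, adds self-loops (`A + I`), and
#' returns `D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal of row sums.
#' Row sums are at least 1 after adding the identity, so the normalisation is
#' always defined.
#'
#' @param A non-negative sparse or dense N x N weight matrix.
#' @return A symmetric sparse N x N normalised adjacency matrix.
#' @export
normalize_adjacency <- function(A) {
  A <- methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix")
  if (any(A@x < 0)) stop("A must be non-negative")
  N <- nrow(A)
  As <- (A + Matrix::t(A)) / 2
  At <- As + Matrix::Diagonal(N)
  dinv <- 1 / sqrt(Matrix::rowSums(At))
  Dm <- Matrix::Diagonal(N, dinv)
  Dm %*% At %*% Dm
}

#' Build the spatial graph used by the model
#'
#' Convenience wrapper: spatial kNN, expression-similarity weights, and the
#' symmetric normalisation, bundled with the neighbour index lists used by
#' the spatially local alignment loss.
#'
#' @param coords N x 2 spot coordinates.
#' @param U PCA embedding of expression ([compute_pca()]) or a score matrix.
#' @param k number of spatial neighbours (default 6, the hexagonal Visium
#'   neighbourhood).
#' @param convention similarity convention, see [similarity_weights()].
#' @return An object of class `spatial_graph`: list with `neighbors`, `A`
#'   (column-normalised similarity weights), `A_norm` (symmetric normalised
#'   adjacency) and `k`.
#' @export
build_spatial_graph <- function(coords, U, k = 6,
                                convention = c("cosine_distance", "as_printed")) {
  convention <- match.arg(convention)
  neighbors <- spatial_knn(coords, k)
  A <- similarity_weights(U, neighbors, convention)
  structure(list(neighbors = neighbors, A = A,
                 A_norm = normalize_adjacency(A), k = k),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph: ", length(x$neighbors), " spots, k = ", x$k, "\n", sep = "")
  invisible(x)
}
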