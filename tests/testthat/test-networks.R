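ident_layer <- function(d) list(W = diag(d), b = numeric(d))

test_that("GCN layer reduces to identity on an edgeless graph", {
  X <- matrix(rnorm(12), 3, 4)
  A_norm <- as.matrix(normalize_adjacency(matrix(0, 4, 4)))   # identity
  H <- gcn_forward(X, A_norm, list(ident_layer(3)), activations = "identity")
  expect_equal(H[[1]], X)
})

test_that("GCN layer averages over a two-spot complete graph", {
  X <- cbind(0, 2)
  A_norm <- matrix(0.5, 2, 2)
  H <- gcn_forward(X, A_norm, list(ident_layer(1)), activations = "identity")
  expect_equal(H[[1]], cbind(1, 1))
})

test_that("GCN forward matches a scalar-loop oracle", {
  set.seed(31)
  X <- matrix(rnorm(5 * 10), 5, 10)
  co <- matrix(runif(20), 10, 2)
  g <- build_spatial_graph(co, matrix(rnorm(30), 3, 10), k = 3)
  A <- as.matrix(g$A_norm)
  layers <- list(list(W = matrix(rnorm(20), 4, 5), b = rnorm(4)),
                 list(W = matrix(rnorm(8), 2, 4), b = rnorm(2)))
  H <- gcn_forward(X, g, layers)
  elu_ref <- function(z) ifelse(z > 0, z, exp(z) - 1)
  H1_ref <- bf_gcn_layer(X, A, layers[[1]]$W, layers[[1]]$b, elu_ref)
  H2_ref <- bf_gcn_layer(H1_ref, A, layers[[2]]$W, layers[[2]]$b)
  expect_equal(H[[1]], H1_ref, tolerance = 1e-6)
  expect_equal(H[[2]], H2_ref, tolerance = 1e-6)
  expect_error(gcn_forward(matrix(0, 3, 10), g, layers), "shape error")
})

test_that("MLP forward matches identities, bias-only nets and the oracle", {
  X <- matrix(rnorm(8), 2, 4)
  expect_equal(mlp_forward(X, list(ident_layer(2)), "identity")[[1]], X)
  b <- c(1.5, -2)
  bias_only <- list(list(W = matrix(0, 2, 2), b = b))
  expect_equal(mlp_forward(X, bias_only, "identity")[[1]],
               matrix(b, 2, 4), ignore_attr = TRUE)
  set.seed(32)
  layers <- list(list(W = matrix(rnorm(6), 3, 2), b = rnorm(3)),
                 list(W = matrix(rnorm(6), 2, 3), b = rnorm(2)))
  H <- mlp_forward(X, layers)
  elu_ref <- function(z) ifelse(z > 0, z, exp(z) - 1)
  H1_ref <- bf_mlp_layer(X, layers[[1]]$W, layers[[1]]$b, elu_ref)
  expect_equal(H[[1]], H1_ref, tolerance = 1e-6)
  expect_equal(H[[2]], bf_mlp_layer(H1_ref, layers[[2]]$W, layers[[2]]$b),
               tolerance = 1e-6)
})

test_that("variational encoder honours eval mode, small sigma and seeding", {
  set.seed(33)
  X <- matrix(rnorm(20), 5, 4)
  hidden <- list(list(W = matrix(rnorm(15), 3, 5), b = rnorm(3)))
  mu_head <- list(W = matrix(rnorm(6), 2, 3), b = rnorm(2))
  lv_head <- list(W = matrix(0, 2, 3), b = rep(0, 2))
  ev <- vae_encode(X, hidden, mu_head, lv_head, sample = FALSE)
  expect_equal(ev$H[[2]], ev$mu)
  # sigma -> 0: sample collapses onto the mean
  lv_small <- list(W = matrix(0, 2, 3), b = rep(-30, 2))
  sm <- vae_encode(X, hidden, mu_head, lv_small, seed = 1)
  expect_equal(sm$H[[2]], sm$mu, tolerance = 1e-5)
  # fixed seed: bit-identical draws
  s1 <- vae_encode(X, hidden, mu_head, lv_head, seed = 7)
  s2 <- vae_encode(X, hidden, mu_head, lv_head, seed = 7)
  expect_identical(s1$H[[2]], s2$H[[2]])
})

test_that("attention weights form a simplex and respect symmetry", {
  set.seed(34)
  H <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(9), 3, 3); v <- rnorm(3); b <- rnorm(3)
  f <- attention_fuse(list(H, H, H), W, v, b)
  expect_equal(colSums(f$alpha), rep(1, 4), tolerance = 1e-6)
  expect_equal(f$alpha, matrix(1 / 3, 3, 4), tolerance = 1e-12)
  expect_equal(f$H, H, tolerance = 1e-12)
  # constant scores give uniform weights regardless of their value
  f0 <- attention_fuse(list(H, H + 0), W * 0, v, b)   # scores all equal
  expect_equal(f0$alpha, matrix(0.5, 2, 4), tolerance = 1e-12)
  # random inputs still live on the simplex
  g <- attention_fuse(list(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4)),
                      W, v, b)
  expect_true(all(g$alpha >= 0))
  expect_equal(colSums(g$alpha), rep(1, 4), tolerance = 1e-6)
})

test_that("attention fusion matches a hand-evaluated two-spot instance", {
  H1 <- cbind(c(1, 0), c(0, 1))
  H2 <- cbind(c(0, 1), c(1, 0))
  W <- matrix(c(1, 0, 0, 1), 2, 2)
  v <- c(1, -1)
  b <- c(0.5, -0.5)
  f <- attention_fuse(list(H1, H2), W, v, b)
  # scalar evaluation, spot by spot
  for (i in 1:2) {
    s1 <- sum(v * tanh(W %*% H1[, i] + b))
    s2 <- sum(v * tanh(W %*% H2[, i] + b))
    a <- exp(c(s1, s2)) / sum(exp(c(s1, s2)))
    expect_equal(f$alpha[, i], a, tolerance = 1e-12)
    expect_equal(f$H[, i], a[1] * H1[, i] + a[2] * H2[, i], tolerance = 1e-12)
  }
})

test_that("decoder maps zero latent to its bias and matches the oracle", {
  b <- c(0.3, -1, 2)
  dec <- list(list(W = matrix(rnorm(6), 3, 2), b = b))
  X <- decode_latent(matrix(0, 2, 5), dec)
  expect_equal(X, matrix(b, 3, 5), ignore_attr = TRUE)
  set.seed(35)
  H <- matrix(rnorm(10), 2, 5)
  dec2 <- list(list(W = matrix(rnorm(8), 4, 2), b = rnorm(4)),
               list(W = matrix(rnorm(12), 3, 4), b = rnorm(3)))
  out <- decode_latent(H, dec2)
  elu_ref <- function(z) ifelse(z > 0, z, exp(z) - 1)
  ref <- bf_mlp_layer(bf_mlp_layer(H, dec2[[1]]$W, dec2[[1]]$b, elu_ref),
                      dec2[[2]]$W, dec2[[2]]$b)
  expect_equal(out, ref, tolerance = 1e-6)
})

test_that("forward passes are permutation-equivariant in spots", {
  set.seed(36)
  N <- 8
  X <- matrix(rnorm(4 * N), 4, N)
  co <- matrix(runif(2 * N), N, 2)
  g <- build_spatial_graph(co, matrix(rnorm(3 * N), 3, N), k = 2)
  A <- as.matrix(g$A_norm)
  layers <- list(list(W = matrix(rnorm(12), 3, 4), b = rnorm(3)))
  perm <- sample(N)
  H <- gcn_forward(X, A, layers)[[1]]
  Hp <- gcn_forward(X[, perm], A[perm, perm], layers)[[1]]
  expect_equal(Hp, H[, perm], tolerance = 1e-10)
  Hm <- mlp_forward(X, layers)[[1]]
  expect_equal(mlp_forward(X[, perm], layers)[[1]], Hm[, perm],
               tolerance = 1e-12)
  W <- matrix(rnorm(9), 3, 3); v <- rnorm(3); b <- rnorm(3)
  f <- attention_fuse(list(H, Hm), W, v, b)
  fp <- attention_fuse(list(H[, perm], Hm[, perm]), W, v, b)
  expect_equal(fp$H, f$H[, perm], tolerance = 1e-10)
})
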