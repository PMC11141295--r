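test_that("gaussian kernel matches direct substitution and is symmetric", {
  x <- c(1, 2, 3)
  expect_equal(gaussian_kernel(x, x), 1)
  # squared distance 2 at bandwidth 1
  expect_equal(gaussian_kernel(c(0, 0), c(1, 1)), exp(-1), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(gaussian_kernel(a, b), gaussian_kernel(b, a))
    expect_equal(gaussian_kernel(a, b), bf_gaussian_kernel(a, b))
  }
  expect_error(gaussian_kernel(1:2, 1:3), "shape error")
  expect_error(gaussian_kernel(1:2, 2:3, bandwidth = 0), "positive")
})

test_that("mmd2 vanishes for identical samples and obeys the 1-sample form", {
  set.seed(42)
  X <- matrix(rnorm(3 * 6), 3, 6)
  expect_lt(abs(mmd2(X, X)), 1e-10)
  # two single points at squared distance d^2: MMD^2 = 2 - 2 exp(-d^2/2)
  for (d2 in c(0.5, 2, 7)) {
    x <- matrix(0, 2, 1)
    y <- matrix(c(sqrt(d2), 0), 2, 1)
    expect_equal(mmd2(x, y), 2 - 2 * exp(-d2 / 2), tolerance = 1e-12)
  }
  expect_error(mmd2(X, X[, 0, drop = FALSE]), "empty sample")
})

test_that("mmd2 agrees with the double-loop oracle and is symmetric", {
  set.seed(43)
  X <- matrix(rnorm(4 * 8), 4, 8)
  Y <- matrix(rnorm(4 * 8), 4, 8) + 0.5
  expect_equal(mmd2(X, Y), bf_mmd2(X, Y), tolerance = 1e-8)
  expect_equal(mmd2(X, Y), mmd2(Y, X), tolerance = 1e-12)
  # unequal sample sizes are handled by the standard estimator
  Z <- matrix(rnorm(4 * 5), 4, 5)
  expect_equal(mmd2(X, Z), bf_mmd2(X, Z), tolerance = 1e-8)
})

test_that("the printed-coefficient variant does not vanish at X = Y", {
  set.seed(44)
  X <- matrix(rnorm(3 * 5), 3, 5)
  v <- mmd2(X, X, estimator = "as_printed")
  # with cross coefficient 1 the three terms collapse to one kernel mean
  K <- sapply(1:5, function(i) sapply(1:5, function(j)
    bf_gaussian_kernel(X[, i], X[, j])))
  expect_equal(v, sum(K) / 25, tolerance = 1e-10)
  expect_gt(v, 0)
  expect_equal(mmd2(X, X + 1, estimator = "as_printed"),
               bf_mmd2(X, X + 1, cross_coef = 1), tolerance = 1e-8)
})

test_that("global alignment sums per-layer discrepancies", {
  set.seed(45)
  H2 <- list(matrix(rnorm(12), 3, 4), matrix(rnorm(8), 2, 4))
  expect_equal(global_alignment_loss(H2, H1 = H2, H3 = H2), 0, tolerance = 1e-10)
  H1 <- list(H2[[1]] + 1, H2[[2]] - 0.5)
  a <- mmd2(H2[[1]], H1[[1]])
  b <- mmd2(H2[[2]], H1[[2]])
  expect_equal(global_alignment_loss(H2, H1 = H1), a + b, tolerance = 1e-12)
  # missing branch contributes zero
  expect_equal(global_alignment_loss(H2, H1 = H1, H3 = NULL), a + b)
  H3 <- list(H2[[1]] * 2, H2[[2]] * 0.3)
  expect_equal(global_alignment_loss(H2, H1 = H1, H3 = H3),
               a + b + mmd2(H2[[1]], H3[[1]]) + mmd2(H2[[2]], H3[[2]]),
               tolerance = 1e-8)
})

test_that("local alignment matches a per-spot neighbour-set oracle", {
  set.seed(46)
  co <- matrix(runif(12), 6, 2)
  nb <- spatial_knn(co, 2)
  H2 <- list(matrix(rnorm(18), 3, 6), matrix(rnorm(12), 2, 6))
  H1 <- list(H2[[1]] + rnorm(18, sd = 0.5), H2[[2]] + rnorm(12, sd = 0.5))
  expect_equal(local_alignment_loss(H2, H1 = H2, neighbors = nb), 0,
               tolerance = 1e-10)
  got <- local_alignment_loss(H2, H1 = H1, neighbors = nb)
  want <- 0
  for (l in 1:2) for (i in 1:6) {
    s <- nb[[i]]
    want <- want + bf_mmd2(H2[[l]][, s, drop = FALSE], H1[[l]][, s, drop = FALSE])
  }
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("two-spot local alignment equals hand-summed one-sample terms", {
  H2 <- list(cbind(c(0, 0), c(1, 0)))
  H1 <- list(cbind(c(0, 1), c(1, 1)))
  nb <- list(2L, 1L)
  # each spot's neighbour set is the other spot: two 1-sample MMD^2 terms,
  # both equal to 2 - 2 exp(-d^2/2) with d^2 = 1
  got <- local_alignment_loss(H2, H1 = H1, neighbors = nb)
  expect_equal(got, 2 * (2 - 2 * exp(-0.5)), tolerance = 1e-12)
})

test_that("subsampling that covers all spots equals the exact local sum", {
  set.seed(47)
  co <- matrix(runif(16), 8, 2)
  nb <- spatial_knn(co, 3)
  H2 <- list(matrix(rnorm(24), 3, 8))
  H1 <- list(matrix(rnorm(24), 3, 8))
  full <- local_alignment_loss(H2, H1 = H1, neighbors = nb)
  sub <- local_alignment_loss(H2, H1 = H1, neighbors = nb,
                              spot_subsample = 8, seed = 5)
  expect_equal(full, sub, tolerance = 1e-8)
})

test_that("alignment losses are invariant to consistent spot permutation", {
  set.seed(48)
  co <- matrix(runif(14), 7, 2)
  nb <- spatial_knn(co, 2)
  H2 <- list(matrix(rnorm(21), 3, 7))
  H1 <- list(matrix(rnorm(21), 3, 7))
  perm <- sample(7)
  nb_p <- spatial_knn(co[perm, ], 2)
  g1 <- global_alignment_loss(H2, H1 = H1)
  g2 <- global_alignment_loss(lapply(H2, function(h) h[, perm]),
                              H1 = lapply(H1, function(h) h[, perm]))
  expect_equal(g1, g2, tolerance = 1e-10)
  l1 <- local_alignment_loss(H2, H1 = H1, neighbors = nb)
  l2 <- local_alignment_loss(lapply(H2, function(h) h[, perm]),
                             H1 = lapply(H1, function(h) h[, perm]),
                             neighbors = nb_p)
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("compiled alignment layer agrees with the reference implementation", {
  set.seed(49)
  N <- 12
  X <- matrix(rnorm(4 * N), 4, N)
  Ys <- list(H1 = matrix(rnorm(4 * N), 4, N), H3 = matrix(rnorm(4 * N), 4, N))
  nb <- spatial_knn(matrix(runif(2 * N), N, 2), 3)
  Cl <- stmda:::local_weight_matrix(nb)
  ap <- stmda:::make_align_pre(matrix(1 / N^2, N, N), Cl, TRUE, 1, N)
  for (bws in list(1, c(0.5, 2))) {
    a <- stmda:::align_layer(X, Ys, ap$wg, ap$cl_idx, ap$clx, ap$Ceff,
                             bws, 2, TRUE)
    b <- stmda:::align_layer_ref(X, Ys, ap$wg, ap$cl_idx, ap$clx, ap$Ceff,
                                 bws, 2, TRUE)
    expect_equal(a$vg, b$vg, tolerance = 1e-10)
    expect_equal(a$vl, b$vl, tolerance = 1e-10)
    expect_equal(a$gX, b$gX, tolerance = 1e-8)
    expect_equal(a$gY$H1, b$gY$H1, tolerance = 1e-8)
    expect_equal(a$gY$H3, b$gY$H3, tolerance = 1e-8)
  }
})

test_that("mmd gradients match central finite differences", {
  set.seed(50)
  X <- matrix(rnorm(6), 3, 2)
  Y <- matrix(rnorm(6), 3, 2)
  C <- matrix(runif(4), 2, 2)
  C <- (C + t(C)) / 2
  r <- stmda:::weighted_mmd_grad(X, Y, C)
  h <- 1e-6
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + h
    Xm <- X; Xm[i] <- Xm[i] - h
    fd <- (stmda:::weighted_mmd_grad(Xp, Y, C, want_grad = FALSE)$value -
           stmda:::weighted_mmd_grad(Xm, Y, C, want_grad = FALSE)$value) / (2 * h)
    expect_equal(r$gX[i], fd, tolerance = 1e-4)
  }
  for (i in seq_along(Y)) {
    Yp <- Y; Yp[i] <- Yp[i] + h
    Ym <- Y; Ym[i] <- Ym[i] - h
    fd <- (stmda:::weighted_mmd_grad(X, Yp, C, want_grad = FALSE)$value -
           stmda:::weighted_mmd_grad(X, Ym, C, want_grad = FALSE)$value) / (2 * h)
    expect_equal(r$gY[i], fd, tolerance = 1e-4)
  }
})
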