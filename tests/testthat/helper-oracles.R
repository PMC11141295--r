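# Independent brute-force oracles. These deliberately use scalar loops and
# textbook formulas, never the package's vectorised implementations.

bf_gaussian_kernel <- function(x, y, bw = 1) exp(-sum((x - y)^2) / (2 * bw^2))

bf_mmd2 <- function(X, Y, bw = 1, cross_coef = 2) {
  n <- ncol(X); m <- ncol(Y)
  t1 <- 0; t2 <- 0; t3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    t1 <- t1 + bf_gaussian_kernel(X[, i], X[, j], bw)
  for (i in seq_len(n)) for (j in seq_len(m))
    t2 <- t2 + bf_gaussian_kernel(X[, i], Y[, j], bw)
  for (i in seq_len(m)) for (j in seq_len(m))
    t3 <- t3 + bf_gaussian_kernel(Y[, i], Y[, j], bw)
  t1 / n^2 - cross_coef * t2 / (n * m) + t3 / m^2
}

bf_knn <- function(coords, k) {
  N <- nrow(coords)
  lapply(seq_len(N), function(i) {
    d <- sqrt(rowSums((coords - rep(coords[i, ], each = N))^2))
    d[i] <- Inf
    order(d)[seq_len(k)]
  })
}

# scalar-loop GCN layer: phi(W H A + b)
bf_gcn_layer <- function(H, A, W, b, phi = identity) {
  HA <- matrix(0, nrow(H), ncol(H))
  for (i in seq_len(nrow(H))) for (j in seq_len(ncol(A)))
    HA[i, j] <- sum(H[i, ] * A[, j])
  Z <- matrix(0, nrow(W), ncol(H))
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(H)))
    Z[i, j] <- sum(W[i, ] * HA[, j]) + b[i]
  phi(Z)
}

bf_mlp_layer <- function(H, W, b, phi = identity) {
  Z <- matrix(0, nrow(W), ncol(H))
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(H)))
    Z[i, j] <- sum(W[i, ] * H[, j]) + b[i]
  phi(Z)
}

bf_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - exp_idx) / (max_idx - exp_idx)
}

bf_purity <- function(labels, reference) {
  total <- 0
  for (cl in unique(labels)) {
    ref_in <- reference[labels == cl]
    total <- total + max(table(ref_in))
  }
  total / length(labels)
}

bf_silhouette <- function(labels, coords) {
  N <- length(labels)
  d <- as.matrix(dist(coords))
  s <- numeric(N)
  for (i in seq_len(N)) {
    own <- which(labels == labels[i] & seq_len(N) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

bf_davies_bouldin <- function(labels, coords) {
  uc <- unique(labels)
  K <- length(uc)
  cent <- lapply(uc, function(cl) colMeans(coords[labels == cl, , drop = FALSE]))
  S <- sapply(seq_len(K), function(ki) {
    pts <- coords[labels == uc[ki], , drop = FALSE]
    mean(apply(pts, 1, function(p) sqrt(sum((p - cent[[ki]])^2))))
  })
  mean(sapply(seq_len(K), function(i) {
    max(sapply(setdiff(seq_len(K), i), function(j) {
      (S[i] + S[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
    }))
  }))
}

bf_morans_i <- function(values, coords, k) {
  nb <- bf_knn(as.matrix(coords), k)
  N <- length(values)
  z <- values - mean(values)
  num <- 0; W <- 0
  for (i in seq_len(N)) for (j in nb[[i]]) {
    num <- num + z[i] * z[j]
    W <- W + 1
  }
  (N / W) * num / sum(z^2)
}

# small deterministic dataset used across io/preprocessing tests
tiny_counts <- function() {
  m <- matrix(c(5, 0, 2, 1,
                0, 3, 0, 4,
                1, 1, 1, 1,
                8, 2, 0, 0,
                0, 0, 6, 2,
                2, 5, 3, 0), nrow = 6, byrow = TRUE)
  rownames(m) <- paste0("g", 1:6)
  colnames(m) <- paste0("s", 1:4)
  m
}

tiny_dataset <- function() {
  srt_dataset(tiny_counts(),
              coords = cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)))
}

# shared small simulation for fit-level tests (kept small for speed)
small_sim <- function(seed = 1) {
  simulate_srt(synthetic_spec(n_domains = 3, grid = c(10, 10), n_genes = 40,
                              n_markers_per_domain = 5, dropout_rate = 0.2,
                              seed = seed))
}

# 4-spot engine instance for gradient and loss tests
tiny_engine <- function(lambda = 1, seed = 2, use_image = TRUE) {
  cfg <- stmda:::engine_config(M = 5, F_dim = if (use_image) 3 else NULL,
                               N = 4, hidden_dim = 4, latent_dim = 3,
                               attention_hidden = 3, lambda = lambda,
                               seed = seed, use_image = use_image)
  set.seed(seed)
  params <- stmda:::init_params(cfg)
  X1 <- matrix(runif(20), 5, 4)
  X2 <- if (use_image) matrix(rnorm(12), 3, 4) else NULL
  coords <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  nb <- spatial_knn(coords, 2)
  G <- as.matrix(normalize_adjacency(similarity_weights(matrix(rnorm(8), 2, 4), nb)))
  eps <- matrix(rnorm(12), 3, 4)
  list(cfg = cfg, params = params, X1 = X1, X2 = X2, G = G,
       XG = X1 %*% G, eps = eps, neighbors = nb,
       C_global = matrix(1 / 16, 4, 4),
       C_local = stmda:::local_weight_matrix(nb))
}

tiny_loss <- function(inst, params = inst$params) {
  stmda:::forward_backward(params, inst$X1, inst$X2, inst$G, inst$XG,
                           inst$cfg, eps = inst$eps,
                           C_global = inst$C_global, C_local = inst$C_local,
                           want_grad = FALSE)$loss
}
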