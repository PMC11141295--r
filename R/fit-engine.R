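# Internal optimisation engine: hand-written forward and backward passes for
# the three-branch architecture, the attention fusion, the decoder, and the
# ELBO + MMD-alignment objective, optimised with Adam. All parameter matrices
# live in a flat named list so the whole gradient can be checked against
# finite differences.

elu <- function(z) {
  neg <- which(z < 0)                 # NA-safe: non-finite entries pass through
  z[neg] <- exp(z[neg]) - 1
  z
}
elu_grad <- function(z) {
  g <- array(1, dim(z))
  neg <- which(z < 0)
  g[neg] <- exp(z[neg])
  g
}

engine_config <- function(M, F_dim, N, hidden_dim = 128, latent_dim = 10,
                          attention_hidden = latent_dim, lambda = 1,
                          epochs = 500, learning_rate = 1e-3, seed = 0,
                          use_image = TRUE, use_spatial = TRUE,
                          use_deep_alignment = TRUE, use_any_alignment = TRUE,
                          mmd_bandwidths = 1,
                          mmd_estimator = "standard_biased",
                          local_subsample = NULL, logvar_clamp = 10,
                          verbose = FALSE) {
  if (lambda < 0) stop("parameter error: lambda must be non-negative")
  if (is.null(F_dim)) use_image <- FALSE
  # auto subsample policy for the local loss: exact below 2000 spots
  if (is.null(local_subsample)) local_subsample <- if (N > 2000) 512L else NA
  list(M = M, F_dim = F_dim, N = N, hidden_dim = hidden_dim,
       latent_dim = latent_dim, attention_hidden = attention_hidden,
       lambda = lambda, epochs = epochs, learning_rate = learning_rate,
       seed = seed, use_image = use_image, use_spatial = use_spatial,
       use_deep_alignment = use_deep_alignment,
       use_any_alignment = use_any_alignment,
       mmd_bandwidths = mmd_bandwidths,
       cross_coef = if (identical(mmd_estimator, "as_printed")) 1 else 2,
       local_subsample = local_subsample, logvar_clamp = logvar_clamp,
       verbose = verbose)
}

init_params <- function(cfg) {
  h <- cfg$hidden_dim; d <- cfg$latent_dim; dp <- cfg$attention_hidden
  p <- list(
    g_W1 = glorot(h, cfg$M), g_b1 = numeric(h),
    g_W2 = glorot(d, h),     g_b2 = numeric(d),
    e_W1 = glorot(h, cfg$M), e_b1 = numeric(h),
    e_Wmu = glorot(d, h),    e_bmu = numeric(d),
    e_Wlv = glorot(d, h),    e_blv = numeric(d),
    a_W = glorot(dp, d), a_b = numeric(dp), a_v = glorot(dp, 1)[, 1],
    d_W1 = glorot(h, d),     d_b1 = numeric(h),
    d_W2 = glorot(cfg$M, h), d_b2 = numeric(cfg$M)
  )
  if (cfg$use_image) {
    p$m_W1 <- glorot(h, cfg$F_dim); p$m_b1 <- numeric(h)
    p$m_W2 <- glorot(d, h);         p$m_b2 <- numeric(d)
  }
  p
}

zero_like <- function(params) lapply(params, function(x) x * 0)

# Precompute the fused alignment weights: gradients are linear in the pair
# weights, so the global (constant 1/N^2) and local (neighbourhood-pair)
# weights combine into one matrix Ceff; the sparse support of the local
# weights (cl_idx, clx) is kept for the separate loss-component values.
make_align_pre <- function(C_global, C_local, use_sp, local_scale, N) {
  wg <- if (is.null(C_global)) 0 else 1 / N^2
  local_on <- !is.null(C_local) && use_sp
  cl_idx <- if (local_on) which(C_local != 0) else NULL
  list(wg = wg, cl_idx = cl_idx,
       clx = if (local_on) C_local[cl_idx] else NULL,
       Ceff = if (local_on) wg + local_scale * C_local else wg)
}

# One alignment layer: MMD^2 terms between the expression branch (X) and
# each other branch (Ys), under the global (constant wg = 1/N^2) and local
# (sparse neighbourhood-pair) weights simultaneously. Kernel matrices are
# computed once per pair and reused for both weightings; gradients use the
# fused weight matrix Ceff (global + scaled local). Values are averaged over
# bandwidths like mmd2().
align_layer <- function(X, Ys, wg, cl_idx, clx, Ceff, bws, cc, want_grad) {
  r <- align_layer_cpp(X, unname(Ys), wg,
                       if (is.null(cl_idx)) integer(0) else cl_idx - 1L,
                       if (is.null(clx)) numeric(0) else clx,
                       if (is.matrix(Ceff)) Ceff else NULL,
                       if (is.matrix(Ceff)) 0 else Ceff,
                       bws, cc, want_grad)
  if (want_grad) names(r$gY) <- names(Ys)
  r
}

# Reference R implementation of the same computation; retained for
# cross-checking the compiled path.
align_layer_ref <- function(X, Ys, wg, cl_idx, clx, Ceff, bws, cc, want_grad) {
  d <- nrow(X)
  vg <- 0; vl <- 0
  gX <- if (want_grad) matrix(0, d, ncol(X)) else NULL
  gY <- if (want_grad) lapply(Ys, function(y) matrix(0, nrow(y), ncol(y))) else NULL
  for (bw in bws) {
    ib2 <- 1 / bw^2
    Kxx <- kernel_matrix(X, X, bw)
    sKxx <- sum(Kxx)
    lKxx <- if (!is.null(cl_idx)) sum(clx * Kxx[cl_idx]) else 0
    gX_xx <- NULL
    if (want_grad) {
      P <- Ceff * Kxx
      rsP <- rowSums(P)
      gX_xx <- 2 * ib2 * (X %*% P - X * rep(rsP, each = d))
    }
    for (nm in names(Ys)) {
      Y <- Ys[[nm]]
      Kxy <- kernel_matrix(X, Y, bw)
      Kyy <- kernel_matrix(Y, Y, bw)
      vg <- vg + wg * (sKxx - cc * sum(Kxy) + sum(Kyy))
      if (!is.null(cl_idx))
        vl <- vl + lKxx - cc * sum(clx * Kxy[cl_idx]) + sum(clx * Kyy[cl_idx])
      if (want_grad) {
        Q <- Ceff * Kxy
        R <- Ceff * Kyy
        rsQ <- rowSums(Q); csQ <- colSums(Q); rsR <- rowSums(R)
        gX <- gX + gX_xx +
          ib2 * cc * (X * rep(rsQ, each = d) - Y %*% t(Q))
        gY[[nm]] <- gY[[nm]] +
          ib2 * (2 * (Y %*% R - Y * rep(rsR, each = d)) +
                 cc * (Y * rep(csQ, each = d) - X %*% Q))
      }
    }
  }
  nb <- length(bws)
  list(vg = vg / nb, vl = vl / nb,
       gX = if (want_grad) gX / nb else NULL,
       gY = if (want_grad) lapply(gY, function(g) g / nb) else NULL)
}

# Forward pass + loss + (optionally) full analytic gradient.
# eps: latent_dim x N noise matrix for the reparameterisation (NULL = eval
# mode, latent = mu). C_global / C_local: symmetric pair-weight matrices for
# the two alignment losses (NULL disables the corresponding term).
forward_backward <- function(params, X1, X2, G, XG, cfg, eps = NULL,
                             C_global = NULL, C_local = NULL,
                             local_scale = 1, want_grad = TRUE,
                             align_pre = NULL) {
  N <- ncol(X1)
  dN <- nrow(params$e_Wmu)
  use_sp <- cfg$use_spatial
  use_im <- cfg$use_image

  # --- branch 1: spatial (GCN; plain MLP under the no-spatial ablation)
  in1 <- if (use_sp) XG else X1
  Zg1 <- params$g_W1 %*% in1 + params$g_b1
  Hg1 <- elu(Zg1)
  Hg1p <- if (use_sp) as.matrix(Hg1 %*% G) else Hg1
  H1K <- params$g_W2 %*% Hg1p + params$g_b2          # identity latent layer

  # --- branch 2: VAE encoder on expression
  Ze1 <- params$e_W1 %*% X1 + params$e_b1
  He1 <- elu(Ze1)
  mu <- params$e_Wmu %*% He1 + params$e_bmu
  lv_raw <- params$e_Wlv %*% He1 + params$e_blv
  lv <- pmin(pmax(lv_raw, -cfg$logvar_clamp), cfg$logvar_clamp)
  lv_mask <- (lv_raw > -cfg$logvar_clamp & lv_raw < cfg$logvar_clamp) * 1
  if (is.null(eps)) {
    z <- mu
  } else {
    z <- mu + exp(lv / 2) * eps
  }

  # --- branch 3: image MLP
  if (use_im) {
    Zm1 <- params$m_W1 %*% X2 + params$m_b1
    Hm1 <- elu(Zm1)
    H3K <- params$m_W2 %*% Hm1 + params$m_b2
  }

  # --- attention fusion over the available modalities
  H_list <- if (use_im) list(H1K, z, H3K) else list(H1K, z)
  nm <- length(H_list)
  Tm <- vector("list", nm)
  scores <- matrix(0, nm, N)
  for (j in seq_len(nm)) {
    Tm[[j]] <- tanh(params$a_W %*% H_list[[j]] + params$a_b)
    scores[j, ] <- colSums(params$a_v * Tm[[j]])
  }
  alpha <- col_softmax(scores)
  Hf <- matrix(0, dN, N)
  for (j in seq_len(nm)) Hf <- Hf + H_list[[j]] * rep(alpha[j, ], each = dN)

  # --- decoder
  Zd1 <- params$d_W1 %*% Hf + params$d_b1
  Hd1 <- elu(Zd1)
  Xhat <- params$d_W2 %*% Hd1 + params$d_b2

  # --- losses
  recon <- sum((Xhat - X1)^2) / N
  kl <- sum(0.5 * (mu^2 + exp(lv) - lv - 1)) / N

  align_on <- cfg$use_any_alignment && cfg$lambda > 0
  layers_idx <- if (cfg$use_deep_alignment) 1:2 else 2
  H2list <- list(He1, z)
  H1list <- list(Hg1, H1K)
  H3list <- if (use_im) list(Hm1, H3K) else NULL

  g_global <- 0; g_local <- 0
  mmd_gH2 <- list(NULL, NULL); mmd_gH1 <- list(NULL, NULL); mmd_gH3 <- list(NULL, NULL)
  if (align_on) {
    if (is.null(align_pre))
      align_pre <- make_align_pre(C_global, C_local, use_sp, local_scale, N)
    wg <- align_pre$wg
    cl_idx <- align_pre$cl_idx
    clx <- align_pre$clx
    Ceff <- align_pre$Ceff
    for (l in layers_idx) {
      Ys <- list(H1 = H1list[[l]])
      if (use_im) Ys$H3 <- H3list[[l]]
      r <- align_layer(H2list[[l]], Ys, wg, cl_idx, clx, Ceff,
                       cfg$mmd_bandwidths, cfg$cross_coef, want_grad)
      g_global <- g_global + r$vg
      g_local <- g_local + r$vl * local_scale
      if (want_grad) {
        mmd_gH2[[l]] <- r$gX
        mmd_gH1[[l]] <- r$gY$H1
        if (use_im) mmd_gH3[[l]] <- r$gY$H3
      }
    }
  }
  total <- recon + kl + cfg$lambda * (g_global + g_local)

  out <- list(loss = total, recon = recon, kl = kl,
              align_global = g_global, align_local = g_local,
              Xhat = Xhat, mu = mu, logvar = lv, z = z, alpha = alpha,
              H = Hf, H1K = H1K, H3K = if (use_im) H3K else NULL)
  if (!want_grad) return(out)

  # ------------------------------- backward ---------------------------------
  gr <- zero_like(params)
  lam <- cfg$lambda

  # decoder
  dXhat <- 2 * (Xhat - X1) / N
  gr$d_W2 <- dXhat %*% t(Hd1)
  gr$d_b2 <- rowSums(dXhat)
  dHd1 <- crossprod(params$d_W2, dXhat)
  dZd1 <- dHd1 * elu_grad(Zd1)
  gr$d_W1 <- dZd1 %*% t(Hf)
  gr$d_b1 <- rowSums(dZd1)
  dHf <- crossprod(params$d_W1, dZd1)

  # attention fusion
  dH_list <- vector("list", nm)
  dalpha <- matrix(0, nm, N)
  for (j in seq_len(nm)) {
    dH_list[[j]] <- dHf * rep(alpha[j, ], each = dN)
    dalpha[j, ] <- colSums(dHf * H_list[[j]])
  }
  inner <- colSums(alpha * dalpha)
  dscores <- alpha * (dalpha - rep(inner, each = nm))
  for (j in seq_len(nm)) {
    dT <- outer(params$a_v, dscores[j, ])
    dZa <- dT * (1 - Tm[[j]]^2)
    gr$a_W <- gr$a_W + dZa %*% t(H_list[[j]])
    gr$a_b <- gr$a_b + rowSums(dZa)
    gr$a_v <- gr$a_v + as.numeric(Tm[[j]] %*% dscores[j, ])
    dH_list[[j]] <- dH_list[[j]] + crossprod(params$a_W, dZa)
  }
  dH1K <- dH_list[[1]]
  dz <- dH_list[[2]]
  dH3K <- if (use_im) dH_list[[3]] else NULL

  # MMD gradients enter at the layer outputs
  if (align_on && want_grad) {
    if (!is.null(mmd_gH2[[2]])) dz <- dz + lam * mmd_gH2[[2]]
    if (!is.null(mmd_gH1[[2]])) dH1K <- dH1K + lam * mmd_gH1[[2]]
    if (use_im && !is.null(mmd_gH3[[2]])) dH3K <- dH3K + lam * mmd_gH3[[2]]
  }

  # branch 2 (VAE): latent sample, KL, heads, hidden layer
  dmu <- dz + mu / N
  dlv <- 0.5 * (exp(lv) - 1) / N
  if (!is.null(eps)) dlv <- dlv + dz * eps * 0.5 * exp(lv / 2)
  dlv <- dlv * lv_mask
  gr$e_Wmu <- dmu %*% t(He1)
  gr$e_bmu <- rowSums(dmu)
  gr$e_Wlv <- dlv %*% t(He1)
  gr$e_blv <- rowSums(dlv)
  dHe1 <- crossprod(params$e_Wmu, dmu) + crossprod(params$e_Wlv, dlv)
  if (align_on && want_grad && !is.null(mmd_gH2[[1]]))
    dHe1 <- dHe1 + lam * mmd_gH2[[1]]
  dZe1 <- dHe1 * elu_grad(Ze1)
  gr$e_W1 <- dZe1 %*% t(X1)
  gr$e_b1 <- rowSums(dZe1)

  # branch 1 (spatial)
  gr$g_W2 <- dH1K %*% t(Hg1p)
  gr$g_b2 <- rowSums(dH1K)
  dHg1p <- crossprod(params$g_W2, dH1K)
  dHg1 <- if (use_sp) as.matrix(dHg1p %*% G) else dHg1p   # G symmetric
  if (align_on && want_grad && !is.null(mmd_gH1[[1]]))
    dHg1 <- dHg1 + lam * mmd_gH1[[1]]
  dZg1 <- dHg1 * elu_grad(Zg1)
  gr$g_W1 <- dZg1 %*% t(in1)
  gr$g_b1 <- rowSums(dZg1)

  # branch 3 (image)
  if (use_im) {
    gr$m_W2 <- dH3K %*% t(Hm1)
    gr$m_b2 <- rowSums(dH3K)
    dHm1 <- crossprod(params$m_W2, dH3K)
    if (align_on && want_grad && !is.null(mmd_gH3[[1]]))
      dHm1 <- dHm1 + lam * mmd_gH3[[1]]
    dZm1 <- dHm1 * elu_grad(Zm1)
    gr$m_W1 <- dZm1 %*% t(X2)
    gr$m_b1 <- rowSums(dZm1)
  }

  out$grads <- gr
  out
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Full training loop. X1: genes x spots (log1p), X2: features x spots or
# NULL, G: normalised adjacency (or NULL when use_spatial = FALSE),
# neighbors: spatial neighbour lists. Deterministic given cfg$seed.
fit_engine <- function(X1, X2, G, neighbors, cfg) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  N <- ncol(X1)
  params <- init_params(cfg)
  state <- adam_init(params)
  XG <- if (cfg$use_spatial) as.matrix(X1 %*% G) else NULL

  align_on <- cfg$use_any_alignment && cfg$lambda > 0
  C_global <- if (align_on) matrix(1 / N^2, N, N) else NULL
  subsampling <- align_on && cfg$use_spatial && !is.na(cfg$local_subsample) &&
    cfg$local_subsample < N
  C_local <- NULL
  local_scale <- 1
  align_pre <- NULL
  if (align_on && cfg$use_spatial && !subsampling)
    C_local <- local_weight_matrix(neighbors)
  if (align_on && !subsampling)
    align_pre <- make_align_pre(C_global, C_local, cfg$use_spatial, 1, N)

  hist <- matrix(NA_real_, cfg$epochs, 5,
                 dimnames = list(NULL, c("total", "recon", "kl",
                                         "align_global", "align_local")))
  for (ep in seq_len(cfg$epochs)) {
    eps <- matrix(stats::rnorm(cfg$latent_dim * N), cfg$latent_dim, N)
    if (subsampling) {
      spots <- sample.int(N, cfg$local_subsample)
      C_local <- local_weight_matrix(neighbors, spots)
      local_scale <- N / cfg$local_subsample
      align_pre <- make_align_pre(C_global, C_local, cfg$use_spatial,
                                  local_scale, N)
    }
    fb <- forward_backward(params, X1, X2, G, XG, cfg, eps = eps,
                           C_global = C_global, C_local = C_local,
                           local_scale = local_scale, want_grad = TRUE,
                           align_pre = align_pre)
    comps <- c(fb$loss, fb$recon, fb$kl, fb$align_global, fb$align_local)
    if (any(!is.finite(comps))) {
      bad <- colnames(hist)[which(!is.finite(comps))[1]]
      stop("training diverged at epoch ", ep, ": component '", bad,
           "' is not finite")
    }
    hist[ep, ] <- comps
    upd <- adam_step(params, fb$grads, state, lr = cfg$learning_rate)
    params <- upd$params
    state <- upd$state
    if (cfg$verbose && (ep %% 50 == 0 || ep == 1))
      message(sprintf("epoch %d | total %.4f recon %.4f kl %.4f mmd_g %.4f mmd_l %.4f",
                      ep, fb$loss, fb$recon, fb$kl, fb$align_global, fb$align_local))
  }

  # eval-mode pass: latent = mu, exact local loss, no gradient
  C_local_eval <- if (align_on && cfg$use_spatial)
    local_weight_matrix(neighbors) else NULL
  ev <- forward_backward(params, X1, X2, G, XG, cfg, eps = NULL,
                         C_global = C_global, C_local = C_local_eval,
                         local_scale = 1, want_grad = FALSE)
  list(params = params,
       history = as.data.frame(cbind(epoch = seq_len(cfg$epochs), hist)),
       embedding = ev$H, denoised = ev$Xhat, alpha = ev$alpha,
       mu = ev$mu, logvar = ev$logvar, eval_loss = ev$loss, config = cfg)
}

# Flatten/unflatten helpers used by the finite-difference gradient check.
flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(vec, template) {
  out <- template
  pos <- 1
  for (nm in names(template)) {
    n <- length(template[[nm]])
    piece <- vec[pos:(pos + n - 1)]
    out[[nm]] <- if (is.matrix(template[[nm]]))
      matrix(piece, nrow(template[[nm]]), ncol(template[[nm]])) else piece
    pos <- pos + n
  }
  out
}
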