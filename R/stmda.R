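#' Fit the multi-modal domain-adaptation model
#'
#' Fits a joint latent representation of an SRT dataset from up to three
#' modalities: expression (a variational autoencoder), spatial coordinates (a
#' graph convolutional network over the k-nearest-neighbour spot graph) and
#' image features (a multilayer perceptron). The expression branch is treated
#' as the source domain; during training its per-layer representations are
#' aligned with the other branches by Gaussian-kernel MMD losses, both over
#' all spots (global) and within each spot's spatial neighbourhood (local).
#' The branch latents are fused per spot by a shared attention mechanism and
#' decoded to reconstruct expression. The objective is
#' `ELBO + lambda * (global + local alignment)`, minimised with Adam
#' (full batch) for `epochs` iterations; the run is deterministic given
#' `seed`.
#'
#' Preprocessing (HVG selection and log1p) is applied automatically when the
#' dataset still holds raw counts. Ablation flags reproduce the model
#' variants: `use_image = FALSE` drops the image branch and its MMD terms;
#' `use_spatial = FALSE` replaces the GCN with an MLP on expression and drops
#' the local alignment; `use_deep_alignment = FALSE` aligns at the latent
#' layer only instead of summing over encoder layers; `use_any_alignment =
#' FALSE` removes both alignment losses entirely.
#'
#' @param ds an [srt_dataset] (raw counts or already log-transformed).
#' @param k number of spatial neighbours for the graph (default 6).
#' @param lambda non-negative weight of the alignment losses (default 1).
#' @param epochs optimisation steps (default 500).
#' @param learning_rate Adam step size (default 1e-3, the optimiser default).
#' @param seed integer seed controlling initialisation, reparameterisation
#'   noise and any subsampling.
#' @param hidden_dim hidden-layer width (default 128).
#' @param latent_dim latent width (default 10).
#' @param attention_hidden attention hidden width (default `latent_dim`).
#' @param n_top_hvgs genes kept by HVG selection when preprocessing runs
#'   (default 3000).
#' @param n_pcs principal components for the similarity graph (default 15).
#' @param normalize library-size normalise before log1p (default FALSE).
#' @param use_image,use_spatial,use_deep_alignment,use_any_alignment ablation
#'   switches, see Details.
#' @param similarity_convention graph-weight convention, see
#'   [similarity_weights()].
#' @param mmd_estimator `"standard_biased"` (default) or `"as_printed"`.
#' @param mmd_bandwidths Gaussian-kernel bandwidths (default 1).
#' @param local_subsample spots sampled per step for the local loss; default:
#'   exact sum up to 2000 spots, 512 sampled spots beyond.
#' @param embedder tile embedder used if the dataset carries an image but no
#'   feature matrix (default [summary_stat_embedder()]).
#' @param tile_side tile side length in pixels for on-the-fly embedding.
#' @param verbose print progress every 50 epochs.
#'
#' @return An object of class `stmda`: list with `embedding` (latent x spots,
#'   eval-mode fused representation), `denoised` (genes x spots reconstructed
#'   expression), `alpha` (modality attention weights, modalities x spots),
#'   `history` (per-epoch loss components), `params`, `graph`, `dataset`
#'   (the preprocessed dataset), `config` and `call`.
#' @seealso [cluster_domains()], [denoise()], [select_lambda()]
#' @export
stmda <- function(ds, k = 6, lambda = 1, epochs = 500, learning_rate = 1e-3,
                  seed = 0, hidden_dim = 128, latent_dim = 10,
                  attention_hidden = latent_dim, n_top_hvgs = 3000,
                  n_pcs = 15, normalize = FALSE, use_image = TRUE,
                  use_spatial = TRUE, use_deep_alignment = TRUE,
                  use_any_alignment = TRUE,
                  similarity_convention = c("cosine_distance", "as_printed"),
                  mmd_estimator = c("standard_biased", "as_printed"),
                  mmd_bandwidths = 1, local_subsample = NULL,
                  embedder = summary_stat_embedder(), tile_side = 32,
                  verbose = FALSE) {
  stopifnot(inherits(ds, "srt_dataset"))
  similarity_convention <- match.arg(similarity_convention)
  mmd_estimator <- match.arg(mmd_estimator)
  cl <- match.call()

  if (!ds$log_transformed)
    ds <- preprocess_srt(ds, n_top_hvgs = n_top_hvgs, normalize = normalize)
  X1 <- ds$expression

  # image-feature matrix: precomputed > embedded-from-raster > absent
  X2 <- NULL
  if (use_image) {
    if (!is.null(ds$image_features)) {
      X2 <- standardize_features(ds$image_features)
    } else if (!is.null(ds$image) && !is.null(ds$pixel_coords)) {
      X2 <- standardize_features(
        embed_tiles(extract_tiles(ds, side = tile_side), embedder))
    } else {
      use_image <- FALSE
    }
  }

  pca <- compute_pca(ds, n_pcs = min(n_pcs, min(dim(X1))))
  graph <- build_spatial_graph(ds$coords, pca, k = k,
                               convention = similarity_convention)
  cfg <- engine_config(M = nrow(X1),
                       F_dim = if (is.null(X2)) NULL else nrow(X2),
                       N = ncol(X1), hidden_dim = hidden_dim,
                       latent_dim = latent_dim,
                       attention_hidden = attention_hidden, lambda = lambda,
                       epochs = epochs, learning_rate = learning_rate,
                       seed = seed, use_image = use_image,
                       use_spatial = use_spatial,
                       use_deep_alignment = use_deep_alignment,
                       use_any_alignment = use_any_alignment,
                       mmd_bandwidths = mmd_bandwidths,
                       mmd_estimator = mmd_estimator,
                       local_subsample = local_subsample, verbose = verbose)
  eng <- fit_engine(X1, X2, if (use_spatial) graph$A_norm else NULL,
                    graph$neighbors, cfg)
  rownames(eng$denoised) <- ds$gene_ids
  colnames(eng$denoised) <- ds$spot_ids
  modalities <- if (use_image) c("spatial", "expression", "image")
                else c("spatial", "expression")
  rownames(eng$alpha) <- modalities
  structure(list(embedding = eng$embedding, denoised = eng$denoised,
                 alpha = eng$alpha, mu = eng$mu, history = eng$history,
                 params = eng$params, graph = graph, dataset = ds, X2 = X2,
                 config = cfg, call = cl),
            class = "stmda")
}

#' @export
print.stmda <- function(x, ...) {
  cfg <- x$config
  cat("stmda fit: ", cfg$M, " genes x ", cfg$N, " spots, latent dim ",
      cfg$latent_dim, "\n", sep = "")
  cat("  modalities:", paste(rownames(x$alpha), collapse = ", "), "\n")
  cat("  lambda = ", cfg$lambda, ", epochs = ", cfg$epochs,
      ", seed = ", cfg$seed, "\n", sep = "")
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final loss %.4f (recon %.4f, kl %.4f, mmd global %.4f, mmd local %.4f)\n",
              h$total, h$recon, h$kl, h$align_global, h$align_local))
  invisible(x)
}

#' @export
summary.stmda <- function(object, ...) {
  h <- object$history
  out <- list(config = object$config,
              first_epoch = h[1, ], last_epoch = h[nrow(h), ],
              alpha_means = rowMeans(object$alpha))
  class(out) <- "summary.stmda"
  out
}

#' @export
print.summary.stmda <- function(x, ...) {
  cat("Multi-modal domain-adaptation fit\n")
  cat("  lambda =", x$config$lambda, " epochs =", x$config$epochs, "\n")
  cat("Loss (epoch 1 -> final):\n")
  for (nm in c("total", "recon", "kl", "align_global", "align_local"))
    cat(sprintf("  %-12s %10.4f -> %10.4f\n", nm, x$first_epoch[[nm]],
                x$last_epoch[[nm]]))
  cat("Mean attention weight per modality:\n")
  for (nm in names(x$alpha_means))
    cat(sprintf("  %-12s %.3f\n", nm, x$alpha_means[[nm]]))
  invisible(x)
}

#' @export
plot.stmda <- function(x, which = c("loss", "attention"), ...) {
  which <- match.arg(which)
  h <- x$history
  if (which == "loss") {
    comp <- c("total", "recon", "kl", "align_global", "align_local")
    cols <- c("black", "steelblue", "darkorange", "forestgreen", "purple")
    graphics::matplot(h$epoch, h[, comp], type = "l", lty = 1, col = cols,
                      xlab = "epoch", ylab = "loss component", ...)
    graphics::legend("topright", legend = comp, col = cols, lty = 1, bty = "n")
  } else {
    graphics::boxplot(t(x$alpha), ylab = "attention weight",
                      names = rownames(x$alpha), ...)
  }
  invisible(x)
}

#' @export
fitted.stmda <- function(object, ...) object$denoised

#' @export
residuals.stmda <- function(object, ...) {
  object$dataset$expression - object$denoised
}

#' @export
coef.stmda <- function(object, ...) object$alpha

#' @export
predict.stmda <- function(object,
                          type = c("embedding", "denoised", "domains"),
                          ...) {
  type <- match.arg(type)
  switch(type,
    embedding = object$embedding,
    denoised = object$denoised,
    domains = cluster_domains(object, ...)
  )
}

#' Denoised expression from a fitted model
#'
#' Returns the eval-mode reconstruction of expression (the decoder output
#' from the mean-based fused representation), used as the denoised
#' expression profile.
#'
#' @param fit a fitted `stmda` object.
#' @return genes x spots numeric matrix.
#' @export
denoise <- function(fit) {
  stopifnot(inherits(fit, "stmda"))
  fit$denoised
}

#' Evidence-lower-bound components
#'
#' Gaussian reconstruction term (squared error summed over genes, averaged
#' over spots) and the KL divergence of the diagonal-Gaussian posterior from
#' the standard-normal prior, `sum_d (mu_d^2 + sigma_d^2 - log sigma_d^2 - 1)
#' / 2`, averaged over spots.
#'
#' @param X1 observed expression (genes x spots).
#' @param X1_hat reconstruction (genes x spots).
#' @param mu,logvar variational posterior parameters (latent x spots).
#' @return list with `reconstruction` and `kl`.
#' @export
elbo_loss <- function(X1, X1_hat, mu, logvar) {
  N <- ncol(X1)
  list(reconstruction = sum((X1_hat - X1)^2) / N,
       kl = sum(0.5 * (mu^2 + exp(logvar) - logvar - 1)) / N)
}

#' Total training objective
#'
#' `reconstruction + kl + lambda * (global + local alignment)`. With
#' `lambda = 0` the alignment terms vanish and the objective reduces to the
#' ELBO.
#'
#' @param elbo list with `reconstruction` and `kl` ([elbo_loss()]).
#' @param align_global,align_local alignment loss values.
#' @param lambda non-negative alignment weight.
#' @return single numeric loss value.
#' @export
total_loss <- function(elbo, align_global, align_local, lambda = 1) {
  if (lambda < 0) stop("parameter error: lambda must be non-negative")
  elbo$reconstruction + elbo$kl + lambda * (align_global + align_local)
}

#' Grid search for the alignment weight
#'
#' Fits the model for each candidate `lambda` (same seed and settings),
#' clusters the resulting embedding to the number of reference classes, and
#' scores the clustering against the reference labels by ARI or purity. The
#' candidate with the highest score is returned; ties resolve to the
#' smallest lambda.
#'
#' @param ds an [srt_dataset].
#' @param reference_labels per-spot reference labels (annotation or
#'   diagram-derived classes).
#' @param candidates candidate lambda values (default a grid in `[0, 3]`).
#' @param criterion `"ari"` (default) or `"purity"`.
#' @param ... further arguments passed to [stmda()] (e.g. `epochs`, `seed`).
#' @return list with `best` (selected lambda), `scores` (named numeric) and
#'   `fits` (list of fitted models).
#' @export
select_lambda <- function(ds, reference_labels,
                          candidates = c(0, 0.5, 1, 2, 3),
                          criterion = c("ari", "purity"), ...) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0) stop("parameter error: empty candidate list")
  nd <- length(unique(reference_labels))
  scores <- numeric(length(candidates))
  fits <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    fit <- stmda(ds, lambda = candidates[i], ...)
    dom <- cluster_domains(fit, target_domains = nd)
    scores[i] <- if (criterion == "ari") ari(dom$labels, reference_labels)
                 else purity(dom$labels, reference_labels)
    fits[[i]] <- fit
  }
  names(scores) <- candidates
  ord <- order(-scores, candidates)
  list(best = candidates[ord[1]], scores = scores, fits = fits)
}
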