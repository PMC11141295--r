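#' Select highly variable genes
#'
#' Ranks genes by a dispersion criterion on the log1p scale: per-gene mean and
#' dispersion (variance/mean) are computed on `log1p(counts)`, genes are
#' binned into up to 20 equal-frequency bins by mean (fewer on small gene
#' sets, so that each bin keeps enough genes for stable statistics), and the
#' dispersion is z-scored within each bin. The `n_top` genes with the largest
#' normalised dispersion are retained, in their original order.
#'
#' When fewer than `n_top` genes are available the full gene set is kept with
#' a warning (soft failure).
#'
#' @param ds an [srt_dataset] holding raw counts.
#' @param n_top number of genes to keep (default 3000).
#' @param n_bins number of mean-expression bins for dispersion normalisation.
#' @return The dataset restricted to the selected genes.
#' @export
select_hvgs <- function(ds, n_top = 3000, n_bins = 20) {
  if (!is.numeric(n_top) || length(n_top) != 1 || n_top <= 0)
    stop("parameter error: n_top must be a positive integer")
  M <- nrow(ds$expression)
  if (M <= n_top) {
    if (M < n_top) warning("fewer genes (", M, ") than n_top (", n_top,
                           "); keeping all")
    return(ds)
  }
  score <- hvg_dispersion(ds$expression, n_bins = n_bins)
  keep <- sort(order(score, decreasing = TRUE)[seq_len(n_top)])
  subset_genes(ds, keep)
}

#' Normalised dispersion score used for HVG ranking
#'
#' @param counts genes x spots matrix of raw counts.
#' @param n_bins number of mean bins.
#' @return numeric vector of per-gene normalised dispersions.
#' @export
hvg_dispersion <- function(counts, n_bins = 20, min_bin_size = 20) {
  lx <- log1p(counts)
  mu <- rowMeans(lx)
  v <- apply(lx, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # bin statistics are only meaningful with enough genes per bin; shrink the
  # bin count on small gene sets rather than z-scoring within tiny bins
  n_bins <- max(1L, min(n_bins, nrow(counts) %/% min_bin_size,
                        length(unique(mu))))
  breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(mu, breaks = breaks, include.lowest = TRUE)
  score <- disp
  for (b in levels(bins)) {
    i <- which(bins == b)
    s <- stats::sd(disp[i])
    m <- mean(disp[i])
    score[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  score
}

# restrict a dataset to a gene index vector, preserving order
subset_genes <- function(ds, idx) {
  ds$expression <- ds$expression[idx, , drop = FALSE]
  ds$gene_ids <- ds$gene_ids[idx]
  ds
}

#' Log-transform expression
#'
#' Entrywise `log(1 + x)`. Refuses to run twice: the dataset records whether
#' it is already transformed.
#'
#' @param ds an [srt_dataset] with raw expression.
#' @return The dataset with `expression = log1p(expression)` and the
#'   `log_transformed` flag set.
#' @export
log1p_transform <- function(ds) {
  if (isTRUE(ds$log_transformed))
    stop("expression is already log-transformed")
  ds$expression <- log1p(ds$expression)
  ds$log_transformed <- TRUE
  ds
}

#' Optional library-size normalisation
#'
#' Scales each spot's counts to the median total count across spots. Off by
#' default in the pipeline; provided because public preprocessing pipelines
#' differ on whether it precedes the log transform.
#'
#' @param ds an [srt_dataset] with raw counts.
#' @return The dataset with normalised counts.
#' @export
normalize_total <- function(ds) {
  if (isTRUE(ds$log_transformed)) stop("normalize before log transformation")
  tot <- colSums(ds$expression)
  target <- stats::median(tot)
  ds$expression <- sweep(ds$expression, 2, tot / target, "/")
  ds
}

#' Principal-component embedding of expression
#'
#' Gene-centred PCA of the (log-transformed) expression matrix. Scores are
#' returned as an `n_pcs` x N matrix; the sign of each component is fixed by
#' forcing its largest-magnitude gene loading to be positive, making the
#' embedding deterministic.
#'
#' @param ds an [srt_dataset] (log-transformed expression expected).
#' @param n_pcs number of components (default 15).
#' @return A list of class `pca_embedding` with `U` (n_pcs x N scores),
#'   `explained_variance` (length n_pcs) and `loadings` (genes x n_pcs).
#' @export
compute_pca <- function(ds, n_pcs = 15) {
  X <- ds$expression
  if (n_pcs > min(dim(X)))
    stop("parameter error: n_pcs exceeds min(genes, spots)")
  Xc <- X - rowMeans(X)
  # SVD of the spots x genes centred matrix
  sv <- svd(t(Xc), nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)   # spots x n_pcs
  load <- sv$v                                           # genes x n_pcs
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  N <- ncol(X)
  structure(list(U = t(scores),
                 explained_variance = sv$d[seq_len(n_pcs)]^2 / max(1, N - 1),
                 loadings = load),
            class = "pca_embedding")
}

#' Standard preprocessing pipeline
#'
#' HVG selection, optional library-size normalisation, log1p transform.
#'
#' @param ds an [srt_dataset] with raw counts.
#' @param n_top_hvgs number of highly variable genes to keep (default 3000).
#' @param normalize whether to library-size normalise before the log
#'   transform (default FALSE).
#' @return The preprocessed dataset.
#' @export
preprocess_srt <- function(ds, n_top_hvgs = 3000, normalize = FALSE) {
  ds <- select_hvgs(ds, n_top = n_top_hvgs)
  if (normalize) ds <- normalize_total(ds)
  log1p_transform(ds)
}
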