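#' Detect spatial domains from the joint embedding
#'
#' Builds a k-nearest-neighbour graph on the embedding columns (Euclidean,
#' default 15 neighbours) and partitions it with the Leiden algorithm
#' (modularity objective). Either a fixed `resolution` is used, or
#' `target_domains` triggers a bisection search over resolutions in
#' `[0.01, 5]` until the cluster count matches the target (at most 40
#' iterations); if the exact count is unreachable the closest partition is
#' returned with `warning_flag = TRUE`, never an error.
#'
#' Labels are relabelled to `0 .. n_domains - 1` in decreasing cluster size.
#'
#' @param x a fitted `stmda` object or a latent x spots embedding matrix.
#' @param n_neighbors embedding-graph neighbours (default 15).
#' @param target_domains desired number of domains (exclusive with
#'   `resolution`).
#' @param resolution fixed Leiden resolution (exclusive with
#'   `target_domains`).
#' @param seed RNG seed for Leiden.
#' @return An object of class `stmda_domains`: list with `labels` (integer,
#'   0-based), `n_domains`, `resolution_used`, `warning_flag`, `embedding`,
#'   and — when `x` is a fitted model — `denoised`, `spot_ids`, `gene_ids`,
#'   `coords`.
#' @export
cluster_domains <- function(x, n_neighbors = 15, target_domains = NULL,
                            resolution = NULL, seed = 0) {
  fit <- NULL
  if (inherits(x, "stmda")) {
    fit <- x
    H <- x$embedding
  } else H <- as.matrix(x)
  if (is.null(target_domains) == is.null(resolution))
    stop("give exactly one of target_domains or resolution")
  N <- ncol(H)
  g <- embedding_knn_graph(H, n_neighbors)

  run <- function(res) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    memb <- igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 5))
    as.integer(memb)
  }

  warning_flag <- FALSE
  if (!is.null(resolution)) {
    labels <- run(resolution)
    res_used <- resolution
  } else {
    lo <- 0.01; hi <- 5
    labels_lo <- run(lo); n_lo <- length(unique(labels_lo))
    labels_hi <- run(hi); n_hi <- length(unique(labels_hi))
    best <- NULL; best_res <- NA; best_gap <- Inf
    note <- function(lab, res) {
      gap <- abs(length(unique(lab)) - target_domains)
      if (gap < best_gap) { best <<- lab; best_res <<- res; best_gap <<- gap }
    }
    note(labels_lo, lo); note(labels_hi, hi)
    it <- 0
    while (best_gap > 0 && it < 40) {
      mid <- (lo + hi) / 2
      lab <- run(mid); n_mid <- length(unique(lab))
      note(lab, mid)
      if (n_mid < target_domains) lo <- mid else hi <- mid
      it <- it + 1
    }
    labels <- best
    res_used <- best_res
    if (best_gap > 0) {
      warning_flag <- TRUE
      warning("resolution search could not reach ", target_domains,
              " domains; returning ", length(unique(labels)))
    }
  }
  labels <- relabel_by_size(labels)
  out <- list(labels = labels, n_domains = length(unique(labels)),
              resolution_used = res_used, warning_flag = warning_flag,
              embedding = H)
  if (!is.null(fit)) {
    out$denoised <- fit$denoised
    out$spot_ids <- fit$dataset$spot_ids
    out$gene_ids <- fit$dataset$gene_ids
    out$coords <- fit$dataset$coords
  }
  structure(out, class = "stmda_domains")
}

#' @export
print.stmda_domains <- function(x, ...) {
  cat("stmda_domains: ", length(x$labels), " spots in ", x$n_domains,
      " domains (resolution ", signif(x$resolution_used, 4), ")\n", sep = "")
  print(table(domain = x$labels))
  invisible(x)
}

# undirected kNN graph on embedding columns
embedding_knn_graph <- function(H, n_neighbors) {
  N <- ncol(H)
  k <- min(n_neighbors, N - 1)
  d2 <- sq_dist(H, H)
  edges <- matrix(0L, nrow = N * k, ncol = 2)
  for (i in seq_len(N)) {
    di <- d2[i, ]; di[i] <- Inf
    nb <- order(di)[seq_len(k)]
    edges[((i - 1) * k + 1):(i * k), ] <- cbind(i, nb)
  }
  igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
}

# 0-based labels ordered by decreasing cluster size (ties: first appearance)
relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab) - 1L, names(tab))
  as.integer(map[as.character(labels)])
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions under the
#' permutation-model expectation; 1 for identical partitions (up to label
#' permutation), around 0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return real value, at most 1.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Clustering purity
#'
#' For each cluster, the size of its largest overlap with a reference class,
#' summed over clusters and divided by the number of observations.
#'
#' @param labels candidate cluster labels.
#' @param reference reference class labels of equal length.
#' @return real in `[0, 1]`.
#' @export
purity <- function(labels, reference) {
  if (length(labels) != length(reference))
    stop("label vectors must have equal length")
  tab <- table(labels, reference)
  sum(apply(tab, 1, max)) / length(labels)
}

#' Mean silhouette coefficient on spatial coordinates
#'
#' Per-spot silhouette `(b - a) / max(a, b)` computed on Euclidean distances
#' over the spot coordinates (not the embedding), where `a` is the mean
#' distance to the spot's own domain and `b` the minimal mean distance to
#' any other domain; averaged over spots. Values near 1 indicate spatially
#' compact, well-separated domains.
#'
#' @param labels domain labels (at least two distinct).
#' @param coords N x 2 spot coordinates.
#' @return real in `[-1, 1]`.
#' @export
silhouette_spatial <- function(labels, coords) {
  labels <- as.vector(labels)
  coords <- as.matrix(coords)
  uc <- unique(labels)
  if (length(uc) < 2) stop("silhouette undefined for a single cluster")
  N <- length(labels)
  d <- as.matrix(stats::dist(coords))
  s <- numeric(N)
  for (i in seq_len(N)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { s[i] <- 0; next }
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(uc[uc != labels[i]],
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index on spatial coordinates
#'
#' Standard Davies-Bouldin index: per-cluster mean distance to the centroid
#' (dispersion), the pairwise ratio `(S_i + S_j) / d(c_i, c_j)`, maximised
#' over partners and averaged over clusters. Lower is better; the index is
#' invariant to a global rescaling of the coordinates.
#'
#' @param labels domain labels (at least two distinct).
#' @param coords N x 2 spot coordinates.
#' @return non-negative real.
#' @export
davies_bouldin_spatial <- function(labels, coords) {
  labels <- as.vector(labels)
  coords <- as.matrix(coords)
  uc <- unique(labels)
  K <- length(uc)
  if (K < 2) stop("Davies-Bouldin undefined for a single cluster")
  cent <- t(vapply(uc, function(cl) colMeans(coords[labels == cl, , drop = FALSE]),
                   numeric(ncol(coords))))
  S <- vapply(seq_len(K), function(ki) {
    pts <- coords[labels == uc[ki], , drop = FALSE]
    mean(sqrt(rowSums((pts - rep(cent[ki, ], each = nrow(pts)))^2)))
  }, numeric(1))
  R <- numeric(K)
  for (i in seq_len(K)) {
    R[i] <- max(vapply(setdiff(seq_len(K), i), function(j) {
      (S[i] + S[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }
  mean(R)
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N / W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with binary
#' spatial-kNN weights (`w_ij = 1` when j is among the k nearest spatial
#' neighbours of i), the same neighbourhood scheme as the model's spatial
#' graph. Positive for spatially smooth signals, negative for checkerboard
#' patterns.
#'
#' @param values per-spot values (non-constant).
#' @param coords N x 2 spot coordinates.
#' @param k number of spatial neighbours (default 6).
#' @return real value.
#' @export
morans_i <- function(values, coords, k = 6) {
  values <- as.numeric(values)
  if (stats::sd(values) == 0) stop("Moran's I undefined for a constant vector")
  nb <- spatial_knn(coords, k)
  z <- values - mean(values)
  N <- length(values)
  num <- 0
  for (i in seq_len(N)) num <- num + z[i] * sum(z[nb[[i]]])
  W <- sum(lengths(nb))
  (N / W) * num / sum(z^2)
}

#' Per-gene log fold change for one domain
#'
#' `log2((mean within domain + eps) / (mean outside + eps))` per gene, with
#' `eps = 1e-9`; positive values mark genes enriched in the domain.
#'
#' @param expr genes x spots expression matrix (denoised or original).
#' @param labels per-spot domain labels.
#' @param domain the domain to contrast.
#' @param eps pseudocount guarding against zero means.
#' @return named numeric vector of length `nrow(expr)`.
#' @export
domain_log_fold_change <- function(expr, labels, domain, eps = 1e-9) {
  inside <- labels == domain
  if (!any(inside)) stop("domain ", domain, " not present in labels")
  if (all(inside)) stop("empty out-group for domain ", domain)
  # denoised (reconstructed) expression may dip below zero on the log scale;
  # clamp so the ratio stays defined
  m_in <- pmax(rowMeans(expr[, inside, drop = FALSE]), 0)
  m_out <- pmax(rowMeans(expr[, !inside, drop = FALSE]), 0)
  stats::setNames(log2((m_in + eps) / (m_out + eps)), rownames(expr))
}

#' Domain marker genes by log-fold-change threshold
#'
#' Filter utility over [domain_log_fold_change()]: genes whose log2 fold
#' change for the domain exceeds the threshold (default 1, i.e. a two-fold
#' enrichment).
#'
#' @inheritParams domain_log_fold_change
#' @param threshold minimum log2 fold change (exclusive, default 1).
#' @return character vector of gene ids (or indices when `expr` has no
#'   rownames).
#' @export
domain_degs <- function(expr, labels, domain, threshold = 1) {
  lfc <- domain_log_fold_change(expr, labels, domain)
  idx <- which(lfc > threshold)
  if (is.null(rownames(expr))) idx else rownames(expr)[idx]
}
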