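#' Specification for a synthetic SRT dataset
#'
#' Describes a lattice of spots partitioned into spatial domains, a count
#' model with domain-specific marker genes, dropout, and domain-correlated
#' image features. The generator emulates the structure the model is meant
#' to recover — spatially contiguous expression domains observed through
#' sparse noisy counts — not any platform's exact depth profile.
#'
#' @param n_domains number of spatial domains (>= 2).
#' @param layout `"stripes"` (vertical bands), `"blobs"` (Voronoi cells of
#'   random centres) or `"rings"` (concentric annuli).
#' @param grid integer vector `c(rows, cols)` of the spot lattice.
#' @param n_genes total genes.
#' @param n_markers_per_domain marker genes up-shifted in each domain
#'   (disjoint sets).
#' @param marker_log_effect natural-log fold increase of marker means inside
#'   their domain (default 1.5).
#' @param base_mean baseline Poisson/NB mean per gene per spot (default 1).
#' @param dropout_rate probability of zeroing each count (default 0).
#' @param image_feature_dim image-feature dimension (default 16).
#' @param image_signal strength of the domain signal in image features;
#'   features are domain means plus Gaussian noise with sd `1/image_signal`
#'   (0 disables the domain signal entirely).
#' @param noise `"poisson"` or `"nb"`; `nb_dispersion` is the NB size
#'   parameter (smaller = more overdispersed).
#' @param nb_dispersion NB size parameter (default 2).
#' @param seed RNG seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_domains = 3, layout = c("stripes", "blobs", "rings"),
                           grid = c(30, 30), n_genes = 100,
                           n_markers_per_domain = 10, marker_log_effect = 1.5,
                           base_mean = 1, dropout_rate = 0,
                           image_feature_dim = 16, image_signal = 2,
                           noise = c("poisson", "nb"), nb_dispersion = 2,
                           seed = 0) {
  layout <- match.arg(layout)
  noise <- match.arg(noise)
  if (n_domains < 2) stop("parameter error: n_domains must be at least 2")
  if (n_markers_per_domain * n_domains > n_genes)
    stop("parameter error: markers x domains exceeds the number of genes")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("parameter error: dropout_rate must be in [0, 1)")
  structure(as.list(environment()), class = "synthetic_spec")
}

# domain label for each lattice spot under the chosen layout
layout_labels <- function(spec, coords) {
  rows <- spec$grid[1]; cols <- spec$grid[2]
  switch(spec$layout,
    stripes = {
      band <- ceiling(coords[, 1] / cols * spec$n_domains)
      pmin(pmax(band, 1), spec$n_domains) - 1L
    },
    blobs = {
      centers <- cbind(stats::runif(spec$n_domains, 1, cols),
                       stats::runif(spec$n_domains, 1, rows))
      d2 <- sq_dist(t(coords), t(centers))
      max.col(-d2, ties.method = "first") - 1L
    },
    rings = {
      cx <- (cols + 1) / 2; cy <- (rows + 1) / 2
      r <- sqrt((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2)
      br <- stats::quantile(r, probs = seq(0, 1, length.out = spec$n_domains + 1))
      as.integer(cut(r, breaks = unique(br), include.lowest = TRUE)) - 1L
    })
}

#' Generate a synthetic SRT dataset with known domains
#'
#' Spots lie on a `rows x cols` lattice and carry a domain label determined
#' by the layout. Counts are drawn per gene and spot from the noise model
#' with mean `base_mean`, multiplied by `exp(marker_log_effect)` for each
#' domain's marker genes within that domain; dropout zeroes each count
#' independently with probability `dropout_rate`. Image features are the
#' domain's mean vector (standard-normal draws per domain and feature) plus
#' Gaussian noise with sd `1/image_signal`. Fully deterministic given the
#' spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (an [srt_dataset]) and `labels` (integer
#'   domain labels, 0-based).
#' @export
simulate_srt <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(spec$seed)
  rows <- spec$grid[1]; cols <- spec$grid[2]
  coords <- cbind(x = rep(seq_len(cols), each = rows),
                  y = rep(seq_len(rows), times = cols))
  N <- nrow(coords)
  labels <- layout_labels(spec, coords)

  M <- spec$n_genes
  mean_mat <- matrix(spec$base_mean, M, N)
  marker_sets <- split(seq_len(spec$n_markers_per_domain * spec$n_domains),
                       rep(seq_len(spec$n_domains),
                           each = spec$n_markers_per_domain))
  for (d in seq_len(spec$n_domains)) {
    in_d <- labels == (d - 1L)
    mean_mat[marker_sets[[d]], in_d] <-
      mean_mat[marker_sets[[d]], in_d] * exp(spec$marker_log_effect)
  }
  counts <- if (spec$noise == "poisson") {
    matrix(stats::rpois(M * N, mean_mat), M, N)
  } else {
    matrix(stats::rnbinom(M * N, size = spec$nb_dispersion, mu = mean_mat), M, N)
  }
  if (spec$dropout_rate > 0) {
    keep <- matrix(stats::runif(M * N) >= spec$dropout_rate, M, N)
    counts <- counts * keep
  }
  gene_ids <- paste0("gene", seq_len(M))
  spot_ids <- paste0("spot", seq_len(N))

  dom_means <- matrix(stats::rnorm(spec$image_feature_dim * spec$n_domains),
                      spec$image_feature_dim, spec$n_domains)
  noise_sd <- if (spec$image_signal > 0) 1 / spec$image_signal else 1
  feat <- dom_means[, labels + 1L, drop = FALSE] *
    (if (spec$image_signal > 0) 1 else 0) +
    matrix(stats::rnorm(spec$image_feature_dim * N, sd = noise_sd),
           spec$image_feature_dim, N)

  ds <- srt_dataset(counts, coords, gene_ids = gene_ids, spot_ids = spot_ids,
                    image_features = feat, drop_empty_spots = FALSE)
  list(dataset = ds, labels = labels, marker_sets = marker_sets)
}

#' Paint a synthetic histology raster for a labelled lattice
#'
#' Builds a small RGB image in which each domain has a distinct base colour
#' plus pixel noise, together with per-spot pixel coordinates, so the tile
#' extraction and embedding path can be exercised without real images.
#'
#' @param coords N x 2 lattice coordinates.
#' @param labels per-spot domain labels (0-based).
#' @param px pixels per lattice unit (default 8).
#' @param noise_sd pixel noise sd (default 0.02).
#' @param seed RNG seed.
#' @return list with `image` (height x width x 3 array in `[0, 1]`) and
#'   `pixel_coords` (N x 2).
#' @export
paint_domain_raster <- function(coords, labels, px = 8, noise_sd = 0.02,
                                seed = 0) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  nd <- length(unique(labels))
  base_cols <- grDevices::col2rgb(grDevices::hcl.colors(max(nd, 2), "Dark 3")) / 255
  w <- (max(coords[, 1]) + 1) * px
  h <- (max(coords[, 2]) + 1) * px
  img <- array(0.5, c(h, w, 3))
  half <- px %/% 2
  for (i in seq_len(nrow(coords))) {
    cx <- round(coords[i, 1] * px); cy <- round(coords[i, 2] * px)
    rr <- max(1, cy - half):min(h, cy + half)
    cc <- max(1, cx - half):min(w, cx + half)
    col <- base_cols[, labels[i] + 1L]
    for (ch in 1:3) img[rr, cc, ch] <- col[ch]
  }
  img <- img + array(stats::rnorm(length(img), sd = noise_sd), dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img,
       pixel_coords = cbind(coords[, 1] * px, coords[, 2] * px))
}

#' Write a synthetic dataset as a CSV fixture bundle
#'
#' Writes `expression.csv` (genes x spots with spot-id header),
#' `coords.csv`, `features.csv` (if present) and `labels.csv`;
#' [read_csv_bundle()] round-trips the bundle.
#'
#' @param ds an [srt_dataset].
#' @param labels per-spot domain labels.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_fixture <- function(ds, labels, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "expression.csv")
  utils::write.csv(data.frame(gene_id = ds$gene_ids, ds$expression,
                              check.names = FALSE),
                   p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "coords.csv")
  utils::write.csv(data.frame(spot_id = ds$spot_ids, x = ds$coords[, 1],
                              y = ds$coords[, 2]),
                   p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  if (!is.null(ds$image_features)) {
    p <- file.path(dir, "features.csv")
    fm <- ds$image_features
    dimnames(fm) <- list(paste0("f", seq_len(nrow(fm))), ds$spot_ids)
    utils::write.csv(data.frame(feature_id = rownames(fm), fm,
                                check.names = FALSE),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(spot_id = ds$spot_ids, domain = labels),
                   p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
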