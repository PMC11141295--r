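#' Read a PNG or TIFF histology raster
#'
#' Thin wrapper over the png/tiff packages returning a height x width x 3
#' array with values in `[0, 1]`. Grayscale images are expanded to three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path image file (.png, .tif, .tiff).
#' @return numeric array, height x width x 3.
#' @export
read_image_raster <- function(path) {
  if (!file.exists(path)) stop("I/O error: image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Extract per-spot image tiles
#'
#' Crops a square `side` x `side` tile centred on each spot's pixel
#' coordinates. Tiles that extend past the image border are zero-padded so
#' all tiles share the same shape. Pixel coordinates are interpreted as
#' (x = column, y = row) into the raster.
#'
#' @param ds an [srt_dataset] with `image` and `pixel_coords` set.
#' @param side tile side length in pixels.
#' @return An object of class `spot_tile_set`: list with `tiles` (a list of
#'   side x side x 3 arrays, one per spot) and `side`.
#' @export
extract_tiles <- function(ds, side = 32) {
  if (is.null(ds$image) || is.null(ds$pixel_coords))
    stop("modality absent: no image/pixel coordinates; ",
         "fit without the image branch (use_image = FALSE)")
  img <- ds$image
  h <- dim(img)[1]; w <- dim(img)[2]
  half <- side %/% 2
  tiles <- lapply(seq_len(nrow(ds$pixel_coords)), function(i) {
    cx <- round(ds$pixel_coords[i, 1]); cy <- round(ds$pixel_coords[i, 2])
    rows <- (cy - half):(cy - half + side - 1)
    cols <- (cx - half):(cx - half + side - 1)
    tile <- array(0, c(side, side, 3))
    rok <- rows >= 1 & rows <= h
    cok <- cols >= 1 & cols <= w
    if (any(rok) && any(cok))
      tile[which(rok), which(cok), ] <- img[rows[rok], cols[cok], , drop = FALSE]
    tile
  })
  structure(list(tiles = tiles, side = side), class = "spot_tile_set")
}

#' Deterministic summary-statistic tile embedder
#'
#' A hand-crafted, fully deterministic embedder used in place of a
#' pretrained CNN: per-channel means and standard deviations (6 values)
#' plus a 10-bin intensity histogram of the channel-averaged tile
#' (normalised to proportions), giving a 16-dimensional feature vector.
#' Any function with the same `(tiles) -> output_dim x N` contract can be
#' substituted, e.g. an adapter around a pretrained network.
#'
#' @return An object of class `tile_embedder`: list with `output_dim = 16`
#'   and `embed(tiles)`, mapping a list of tiles to a 16 x N matrix.
#' @export
summary_stat_embedder <- function() {
  embed1 <- function(tile) {
    ch_mean <- apply(tile, 3, mean)
    ch_sd <- apply(tile, 3, stats::sd)
    gray <- (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
    hist10 <- tabulate(pmin(10L, 1L + as.integer(pmax(0, pmin(1, gray)) * 10)),
                       nbins = 10L) / length(gray)
    c(ch_mean, ch_sd, hist10)
  }
  structure(list(
    output_dim = 16L,
    embed = function(tiles) {
      if (inherits(tiles, "spot_tile_set")) tiles <- tiles$tiles
      out <- vapply(tiles, embed1, numeric(16L))
      matrix(out, nrow = 16L)
    }
  ), class = "tile_embedder")
}

#' Embed spot tiles into an image-feature matrix
#'
#' Applies a pluggable embedder to every tile, producing the per-spot
#' image-feature matrix (columns follow spot order). Feature extraction is
#' pure — no training happens here — and the resulting matrix is fixed
#' before optimisation.
#'
#' @param tiles a `spot_tile_set` from [extract_tiles()] (or a plain list of
#'   tile arrays).
#' @param embedder a `tile_embedder`; defaults to [summary_stat_embedder()].
#' @return output_dim x N numeric matrix.
#' @export
embed_tiles <- function(tiles, embedder = summary_stat_embedder()) {
  out <- tryCatch(embedder$embed(tiles),
                  error = function(e) stop("embedder failure: ", conditionMessage(e)))
  if (anyNA(out) || any(!is.finite(out))) {
    bad <- which(apply(out, 2, function(v) anyNA(v) || any(!is.finite(v))))[1]
    stop("embedder produced non-finite features at spot ", bad)
  }
  out
}

#' Per-feature standardisation of image features
#'
#' Z-scores each feature across spots (constant features are left at zero).
#' Image-feature scales are arbitrary; standardisation keeps the alignment
#' losses numerically comparable across modalities.
#'
#' @param X2 features x spots matrix.
#' @return The standardised matrix.
#' @export
standardize_features <- function(X2) {
  mu <- rowMeans(X2)
  s <- apply(X2, 1, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  (X2 - mu) / s
}
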