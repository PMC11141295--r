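#' Construct a spatially resolved transcriptomics dataset
#'
#' The central data container of the package: a genes x spots expression
#' matrix together with per-spot spatial coordinates and, optionally, a
#' histology raster with per-spot pixel coordinates or a precomputed
#' per-spot image-feature matrix.
#'
#' Expression is stored genes x spots (M x N). Spots with zero total counts
#' are dropped at construction time (a message reports how many), because the
#' downstream similarity graph normalises over neighbour sums and an all-zero
#' spot would propagate NaN.
#'
#' @param expression numeric matrix, genes x spots, non-negative.
#' @param coords numeric matrix or data frame with one row per spot and two
#'   columns (x, y); array/tissue coordinates in arbitrary length units.
#' @param gene_ids character vector of length `nrow(expression)`; defaults to
#'   rownames.
#' @param spot_ids character vector of length `ncol(expression)`, unique;
#'   defaults to colnames.
#' @param pixel_coords optional numeric matrix, spots x 2, positions of spot
#'   centres in the image raster.
#' @param image optional array, height x width x 3, values in `[0, 1]` or
#'   8-bit integers.
#' @param image_features optional numeric matrix, features x spots (F x N).
#' @param log_transformed logical flag recording whether `expression` is
#'   already log1p-transformed.
#' @param drop_empty_spots logical; drop spots whose total count is zero.
#'
#' @return An object of class `srt_dataset`: a list with fields
#'   `expression`, `gene_ids`, `spot_ids`, `coords`, `pixel_coords`, `image`,
#'   `image_features`, `log_transformed`.
#' @export
srt_dataset <- function(expression, coords, gene_ids = rownames(expression),
                        spot_ids = colnames(expression), pixel_coords = NULL,
                        image = NULL, image_features = NULL,
                        log_transformed = FALSE, drop_empty_spots = TRUE) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (any(expression < 0)) stop("expression must be non-negative")
  M <- nrow(expression); N <- ncol(expression)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(M))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(N))
  gene_ids <- as.character(gene_ids); spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != M) stop("gene_ids length must equal nrow(expression)")
  if (length(spot_ids) != N) stop("spot_ids length must equal ncol(expression)")
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != N || ncol(coords) != 2)
    stop("coords must have one row per spot and two columns")
  if (!is.null(pixel_coords)) {
    pixel_coords <- as.matrix(pixel_coords)
    storage.mode(pixel_coords) <- "double"
    if (nrow(pixel_coords) != N || ncol(pixel_coords) != 2)
      stop("pixel_coords must be N x 2")
  }
  if (!is.null(image_features)) {
    image_features <- as.matrix(image_features)
    storage.mode(image_features) <- "double"
    if (ncol(image_features) != N)
      stop("image_features must have one column per spot")
  }
  if (drop_empty_spots && !log_transformed) {
    tot <- colSums(expression)
    if (any(tot == 0)) {
      keep <- tot > 0
      message(sum(!keep), " spot(s) with zero total counts dropped")
      expression <- expression[, keep, drop = FALSE]
      spot_ids <- spot_ids[keep]
      coords <- coords[keep, , drop = FALSE]
      if (!is.null(pixel_coords)) pixel_coords <- pixel_coords[keep, , drop = FALSE]
      if (!is.null(image_features)) image_features <- image_features[, keep, drop = FALSE]
    }
  }
  dimnames(expression) <- list(gene_ids, spot_ids)
  structure(list(expression = expression, gene_ids = gene_ids,
                 spot_ids = spot_ids, coords = coords,
                 pixel_coords = pixel_coords, image = image,
                 image_features = image_features,
                 log_transformed = isTRUE(log_transformed)),
            class = "srt_dataset")
}

#' @export
print.srt_dataset <- function(x, ...) {
  cat("srt_dataset: ", nrow(x$expression), " genes x ", ncol(x$expression),
      " spots", if (x$log_transformed) " (log1p)" else " (raw counts)", "\n",
      sep = "")
  if (!is.null(x$image_features))
    cat("  image features: ", nrow(x$image_features), " per spot\n", sep = "")
  if (!is.null(x$image))
    cat("  image: ", dim(x$image)[1], " x ", dim(x$image)[2], " px\n", sep = "")
  invisible(x)
}

#' @export
dim.srt_dataset <- function(x) dim(x$expression)

#' Spots x genes view of the expression matrix
#'
#' Expression is stored genes x spots internally; this accessor returns the
#' transposed view used by most of the R single-cell ecosystem.
#' @param ds an [srt_dataset].
#' @return spots x genes numeric matrix.
#' @export
spots_by_genes <- function(ds) t(ds$expression)

# locate the first existing file among candidates (gz-transparent)
.find_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

.read_table_gz <- function(path, ...) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  utils::read.table(con, stringsAsFactors = FALSE, ...)
}

#' Read a 10x-Genomics-style spatial directory
#'
#' Expects an MTX triplet (`matrix.mtx[.gz]`, `features.tsv[.gz]` or
#' `genes.tsv[.gz]`, `barcodes.tsv[.gz]`) plus a Space Ranger tissue-positions
#' file (`tissue_positions.csv` with header, or headerless
#' `tissue_positions_list.csv`). Spots are restricted to in-tissue barcodes
#' and aligned to the positions file by barcode, never by file order. Array
#' (row, col) coordinates become `coords`; full-resolution pixel positions
#' become `pixel_coords`. An optional image can be supplied separately via
#' [read_image_raster()].
#'
#' @param path directory containing the files above.
#' @return An [srt_dataset].
#' @export
read_visium <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  mtx <- .find_file(path, c("matrix.mtx", "matrix.mtx.gz"))
  if (is.null(mtx)) stop("format error: missing matrix.mtx[.gz] in ", path)
  feat <- .find_file(path, c("features.tsv", "features.tsv.gz",
                             "genes.tsv", "genes.tsv.gz"))
  if (is.null(feat)) stop("format error: missing features.tsv/genes.tsv in ", path)
  bc <- .find_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(bc)) stop("format error: missing barcodes.tsv in ", path)
  pos <- .find_file(path, c("tissue_positions.csv", "tissue_positions.csv.gz",
                            "tissue_positions_list.csv",
                            "tissue_positions_list.csv.gz"))
  if (is.null(pos)) stop("format error: missing tissue positions csv in ", path)

  m <- as.matrix(Matrix::readMM(mtx))
  features <- .read_table_gz(feat, sep = "\t")
  barcodes <- .read_table_gz(bc, sep = "\t")[[1]]
  if (nrow(m) != nrow(features)) stop("format error: features/matrix row mismatch")
  if (ncol(m) != length(barcodes)) stop("format error: barcodes/matrix column mismatch")

  headerless <- grepl("tissue_positions_list", basename(pos))
  positions <- .read_table_gz(pos, sep = ",", header = !headerless)
  if (headerless) {
    names(positions) <- c("barcode", "in_tissue", "array_row", "array_col",
                          "pxl_row_in_fullres", "pxl_col_in_fullres")
  }
  positions <- positions[positions$in_tissue == 1, , drop = FALSE]
  unmatched <- sum(!(positions$barcode %in% barcodes))
  if (unmatched > 0)
    stop("alignment error: ", unmatched,
         " in-tissue barcode(s) in positions file absent from matrix")
  idx <- match(positions$barcode, barcodes)
  srt_dataset(
    expression = m[, idx, drop = FALSE],
    gene_ids = make.unique(as.character(features[[1]])),
    spot_ids = positions$barcode,
    coords = cbind(positions$array_col, positions$array_row),
    pixel_coords = cbind(positions$pxl_col_in_fullres,
                         positions$pxl_row_in_fullres)
  )
}

#' Read an expression/coordinates/feature CSV bundle
#'
#' `expr` is a genes x spots CSV with a header row of spot ids and gene ids in
#' the first column. `coords` has columns spot id, x, y (header optional but
#' the first row is treated as a header when non-numeric). `features`, if
#' given, is features x spots with the same header convention as `expr`.
#' Spots are aligned across files by id.
#'
#' @param expr path to the expression CSV.
#' @param coords path to the coordinates CSV.
#' @param features optional path to an image-feature CSV.
#' @return An [srt_dataset].
#' @export
read_csv_bundle <- function(expr, coords, features = NULL) {
  for (p in c(expr, coords, features))
    if (!file.exists(p)) stop("format error: file not found: ", p)
  e <- utils::read.csv(expr, row.names = 1, check.names = FALSE)
  if (anyDuplicated(colnames(e))) stop("duplicate spot ids in ", expr)
  em <- as.matrix(e)
  if (!is.numeric(em)) {
    bad <- which(!vapply(e, is.numeric, logical(1)))[1]
    stop("parse error: non-numeric values in column ", bad, " of ", expr)
  }
  co <- utils::read.csv(coords, check.names = FALSE)
  if (ncol(co) < 3) stop("format error: coords needs spot id, x, y columns")
  if (anyDuplicated(co[[1]])) stop("duplicate spot ids in ", coords)
  ids <- colnames(em)
  idx <- match(ids, as.character(co[[1]]))
  if (anyNA(idx))
    stop("alignment error: ", sum(is.na(idx)),
         " spot id(s) in expression absent from coordinates")
  cm <- as.matrix(co[idx, 2:3])
  fm <- NULL
  if (!is.null(features)) {
    f <- utils::read.csv(features, row.names = 1, check.names = FALSE)
    fidx <- match(ids, colnames(f))
    if (anyNA(fidx))
      stop("alignment error: ", sum(is.na(fidx)),
           " spot id(s) absent from feature file")
    fm <- as.matrix(f)[, fidx, drop = FALSE]
  }
  srt_dataset(em, cm, gene_ids = rownames(em), spot_ids = ids,
              image_features = fm)
}

#' Write domain-detection results to disk
#'
#' Writes a labels CSV (`spot_id, domain`), an embedding CSV (`spot_id` plus
#' one column per latent dimension), and the denoised expression as a
#' MatrixMarket triplet (`denoised.mtx`, `denoised_genes.tsv`,
#' `denoised_spots.tsv`).
#'
#' @param result a domain result as returned by [cluster_domains()], or any
#'   list with `labels`, `embedding` (latent x spots), `denoised`
#'   (genes x spots), `spot_ids` and `gene_ids`.
#' @param outdir output directory, created if needed.
#' @return Invisibly, a character vector of written paths.
#' @export
write_outputs <- function(result, outdir) {
  if (!nzchar(outdir)) stop("I/O error: empty output directory path")
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", outdir)
  }
  spot_ids <- result$spot_ids
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_along(result$labels))
  paths <- character(0)
  p <- file.path(outdir, "domains.csv")
  utils::write.csv(data.frame(spot_id = spot_ids, domain = result$labels),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(result$embedding)) {
    emb <- t(result$embedding)
    colnames(emb) <- paste0("latent", seq_len(ncol(emb)))
    p <- file.path(outdir, "embedding.csv")
    utils::write.csv(data.frame(spot_id = spot_ids, emb, check.names = FALSE),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(result$denoised)) {
    p <- file.path(outdir, "denoised.mtx")
    Matrix::writeMM(methods::as(Matrix::Matrix(result$denoised, sparse = TRUE),
                                "generalMatrix"), p)
    gene_ids <- result$gene_ids
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(result$denoised)))
    writeLines(gene_ids, file.path(outdir, "denoised_genes.tsv"))
    writeLines(spot_ids, file.path(outdir, "denoised_spots.tsv"))
    paths <- c(paths, p, file.path(outdir, "denoised_genes.tsv"),
               file.path(outdir, "denoised_spots.tsv"))
  }
  invisible(paths)
}
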