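test_that("srt_dataset validates its invariants", {
  m <- tiny_counts()
  ds <- tiny_dataset()
  expect_s3_class(ds, "srt_dataset")
  expect_identical(dim(ds), c(6L, 4L))
  expect_identical(ds$expression, m)
  expect_error(srt_dataset(-m, cbind(0:3, 0:3)), "non-negative")
  expect_error(srt_dataset(m, cbind(0:2, 0:2)), "one row per spot")
  dup <- m; colnames(dup) <- c("s1", "s1", "s2", "s3")
  expect_error(srt_dataset(dup, cbind(0:3, 0:3)), "unique")
  feat_bad <- matrix(0, 2, 3)
  expect_error(srt_dataset(m, cbind(0:3, 0:3), image_features = feat_bad),
               "one column per spot")
})

test_that("spots with zero total counts are dropped at load", {
  m <- tiny_counts()
  m[, 2] <- 0
  expect_message(ds <- srt_dataset(m, cbind(0:3, 0:3)), "1 spot")
  expect_identical(ncol(ds$expression), 3L)
  expect_false("s2" %in% ds$spot_ids)
})

write_visium_fixture <- function(dir, counts, positions) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(rownames(counts), rownames(counts), "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", col.names = FALSE,
              row.names = FALSE, quote = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  write.csv(positions, file.path(dir, "tissue_positions.csv"), row.names = FALSE)
}

test_that("visium directory round-trips through write-then-read", {
  dir <- withr::local_tempdir()
  m <- tiny_counts()
  pos <- data.frame(barcode = colnames(m), in_tissue = 1,
                    array_row = c(0, 0, 1, 1), array_col = c(0, 1, 0, 1),
                    pxl_row_in_fullres = c(10, 10, 20, 20),
                    pxl_col_in_fullres = c(10, 20, 10, 20))
  write_visium_fixture(dir, m, pos)
  ds <- read_visium(dir)
  expect_identical(unname(ds$expression), unname(m))
  expect_identical(ds$spot_ids, colnames(m))
  expect_equal(ds$coords, cbind(pos$array_col, pos$array_row))
  expect_equal(ds$pixel_coords,
               cbind(pos$pxl_col_in_fullres, pos$pxl_row_in_fullres))
})

test_that("spot alignment is by barcode, not file order", {
  dir <- withr::local_tempdir()
  m <- tiny_counts()
  pos <- data.frame(barcode = colnames(m)[c(3, 1, 4, 2)], in_tissue = 1,
                    array_row = c(1, 0, 1, 0), array_col = c(0, 0, 1, 1),
                    pxl_row_in_fullres = 1:4, pxl_col_in_fullres = 1:4)
  write_visium_fixture(dir, m, pos)
  ds <- read_visium(dir)
  expect_identical(ds$spot_ids, pos$barcode)
  expect_identical(unname(ds$expression), unname(m[, pos$barcode]))
})

test_that("unmatched barcodes in the positions file raise a counting error", {
  dir <- withr::local_tempdir()
  m <- tiny_counts()
  pos <- data.frame(barcode = c(colnames(m)[1:3], "missing-1"), in_tissue = 1,
                    array_row = 0:3, array_col = 0:3,
                    pxl_row_in_fullres = 1:4, pxl_col_in_fullres = 1:4)
  write_visium_fixture(dir, m, pos)
  expect_error(read_visium(dir), "1 in-tissue barcode")
})

test_that("out-of-tissue spots are excluded", {
  dir <- withr::local_tempdir()
  m <- tiny_counts()
  pos <- data.frame(barcode = colnames(m), in_tissue = c(1, 1, 0, 1),
                    array_row = 0:3, array_col = 0:3,
                    pxl_row_in_fullres = 1:4, pxl_col_in_fullres = 1:4)
  write_visium_fixture(dir, m, pos)
  ds <- read_visium(dir)
  expect_identical(ds$spot_ids, colnames(m)[c(1, 2, 4)])
})

test_that("MTX with an explicit zero matches the dense CSV reader", {
  dir <- withr::local_tempdir()
  m <- tiny_counts()
  pos <- data.frame(barcode = colnames(m), in_tissue = 1,
                    array_row = c(0, 0, 1, 1), array_col = c(0, 1, 0, 1),
                    pxl_row_in_fullres = 1:4, pxl_col_in_fullres = 1:4)
  write_visium_fixture(dir, m, pos)
  # rewrite the MTX by hand with an explicit stored zero entry
  nz <- which(m != 0, arr.ind = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               paste(nrow(m), ncol(m), nrow(nz) + 1),
               paste(nz[, 1], nz[, 2], m[nz]),
               "1 2 0"),
             file.path(dir, "matrix.mtx"))
  ds_mtx <- read_visium(dir)
  csv_dir <- withr::local_tempdir()
  ds0 <- srt_dataset(m, ds_mtx$coords)
  write_fixture(ds0, rep(0L, 4), csv_dir)
  ds_csv <- read_csv_bundle(file.path(csv_dir, "expression.csv"),
                            file.path(csv_dir, "coords.csv"))
  expect_equal(unname(ds_mtx$expression), unname(ds_csv$expression))
})

test_that("gzipped triplets and the headerless positions dialect are accepted", {
  dir <- withr::local_tempdir()
  m <- tiny_counts()
  tmp <- file.path(dir, "tmp.mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                              "generalMatrix"), tmp)
  f <- gzfile(file.path(dir, "matrix.mtx.gz"), "w")
  writeLines(readLines(tmp), f); close(f); file.remove(tmp)
  f <- gzfile(file.path(dir, "features.tsv.gz"), "w")
  write.table(cbind(rownames(m), rownames(m)), f, sep = "\t",
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  close(f)
  f <- gzfile(file.path(dir, "barcodes.tsv.gz"), "w")
  writeLines(colnames(m), f); close(f)
  pos <- data.frame(colnames(m), 1, c(0, 0, 1, 1), c(0, 1, 0, 1), 1:4, 5:8)
  write.table(pos, file.path(dir, "tissue_positions_list.csv"), sep = ",",
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  ds <- read_visium(dir)
  expect_equal(unname(ds$expression), unname(m), ignore_attr = TRUE)
  expect_equal(ds$coords[, 1], c(0, 1, 0, 1), ignore_attr = TRUE)
})

test_that("csv bundle reads and aligns by spot id", {
  dir <- withr::local_tempdir()
  expr <- file.path(dir, "e.csv")
  writeLines(c("gene,a,b", "g1,1,2", "g2,0,3", "g3,4,0"), expr)
  co <- file.path(dir, "c.csv")
  writeLines(c("spot,x,y", "b,1,0", "a,0,0"), co)   # permuted order
  ds <- read_csv_bundle(expr, co)
  expect_identical(dim(ds), c(3L, 2L))
  expect_identical(ds$spot_ids, c("a", "b"))
  expect_equal(ds$coords[1, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(ds$expression["g1", "b"], 2, ignore_attr = TRUE)

  feats <- file.path(dir, "f.csv")
  writeLines(c("f,b,a", paste0("f", 1:5, ",", 1:5, ",", 6:10)), feats)
  ds2 <- read_csv_bundle(expr, co, feats)
  expect_identical(dim(ds2$image_features), c(5L, 2L))
  expect_equal(ds2$image_features[1, "a"], 6, ignore_attr = TRUE)
})

test_that("csv bundle rejects malformed input", {
  dir <- withr::local_tempdir()
  expr <- file.path(dir, "e.csv")
  writeLines(c("gene,a,a", "g1,1,2"), expr)
  co <- file.path(dir, "c.csv")
  writeLines(c("spot,x,y", "a,0,0"), co)
  expect_error(read_csv_bundle(expr, co), "duplicate spot ids")
  writeLines(c("gene,a,b", "g1,1,oops"), expr)
  writeLines(c("spot,x,y", "a,0,0", "b,1,0"), co)
  expect_error(read_csv_bundle(expr, co), "non-numeric")
  expect_error(read_csv_bundle(file.path(dir, "nope.csv"), co), "not found")
})

test_that("write_outputs writes labels, embedding and denoised triplet", {
  dir <- withr::local_tempdir()
  res <- list(labels = c(0L, 1L, 1L, 0L),
              embedding = matrix(rnorm(40), 10, 4),
              denoised = matrix(runif(24), 6, 4),
              spot_ids = paste0("s", 1:4), gene_ids = paste0("g", 1:6))
  paths <- write_outputs(res, dir)
  expect_true(all(file.exists(paths)))
  lab <- read.csv(file.path(dir, "domains.csv"))
  expect_identical(nrow(lab), 4L)
  emb <- read.csv(file.path(dir, "embedding.csv"))
  expect_equal(unname(as.matrix(emb[, -1])), unname(t(res$embedding)),
               tolerance = 1e-6)
  den <- as.matrix(Matrix::readMM(file.path(dir, "denoised.mtx")))
  expect_equal(den, unname(res$denoised), tolerance = 1e-6)
  expect_error(write_outputs(res, ""), "empty output directory")
})
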