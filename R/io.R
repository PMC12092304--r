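#' Write and read a spot grid as tissue-positions CSV plus region TSV
#'
#' The CSV follows the Space Ranger tissue-positions layout (`barcode`,
#' `in_tissue`, `array_row`, `array_col`, `pxl_row_in_fullres`,
#' `pxl_col_in_fullres`); pixel coordinates are derived from the physical
#' coordinates at the given scale. Regions, sample ids and the
#' reliable-staining flag go to a side TSV.
#'
#' @param grid a [make_spot_grid()] grid.
#' @param positions_csv,regions_tsv output paths.
#' @param pixel_size micrometres per pixel of the pixel frame.
#' @return invisibly, the paths.
#' @export
write_spot_grid <- function(grid, positions_csv, regions_tsv, pixel_size = 1) {
  pos <- data.frame(barcode = grid$spot_id,
                    in_tissue = 1L,
                    array_row = grid$array_row,
                    array_col = grid$array_col,
                    pxl_row_in_fullres = round(grid$y / pixel_size),
                    pxl_col_in_fullres = round(grid$x / pixel_size))
  utils::write.csv(pos, positions_csv, row.names = FALSE, quote = FALSE)
  reg <- data.frame(barcode = grid$spot_id, region = grid$region,
                    sample_id = grid$sample_id,
                    reliable_ab = grid$reliable_ab)
  utils::write.table(reg, regions_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(positions_csv, regions_tsv))
}

#' @rdname write_spot_grid
#' @param pitch,spot_diameter geometry restored onto the grid attributes.
#' @export
read_spot_grid <- function(positions_csv, regions_tsv, pixel_size = 1,
                           pitch = 100, spot_diameter = 55) {
  pos <- utils::read.csv(positions_csv, stringsAsFactors = FALSE)
  reg <- utils::read.delim(regions_tsv, stringsAsFactors = FALSE)
  g <- data.frame(spot_id = pos$barcode,
                  array_row = pos$array_row,
                  array_col = pos$array_col,
                  x = pos$pxl_col_in_fullres * pixel_size,
                  y = pos$pxl_row_in_fullres * pixel_size,
                  stringsAsFactors = FALSE)
  m <- match(g$spot_id, reg$barcode)
  g$region <- reg$region[m]
  g$sample_id <- reg$sample_id[m]
  g$reliable_ab <- as.logical(reg$reliable_ab[m])
  attr(g, "pitch") <- pitch
  attr(g, "spot_diameter") <- spot_diameter
  class(g) <- c("spot_grid", "data.frame")
  g
}

#' Write and read counts as MatrixMarket with feature/barcode TSVs
#'
#' @param counts genes x units matrix.
#' @param dir output directory (created if missing); files `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`.
#' @return invisibly, the directory.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}

#' Write a raster as single-channel 8-bit PNG
#'
#' Masks are written as 0/255; density rasters keep their 0-255 values.
#' The physical scale is not stored in the PNG and must be supplied when
#' reading back.
#'
#' @param raster a [mask_raster()] or [density_raster()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_raster_png <- function(raster, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_invalid("the 'png' package is required to write PNG rasters")
  px <- raster$pixels
  if (inherits(raster, "mask_raster")) px <- px * 255L
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' @rdname write_raster_png
#' @param pixel_size micrometres per pixel of the stored raster.
#' @param as mask (values thresholded at 128) or density.
#' @export
read_raster_png <- function(path, pixel_size, as = c("mask", "density")) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_invalid("the 'png' package is required to read PNG rasters")
  as <- match.arg(as)
  px <- round(png::readPNG(path) * 255)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  if (as == "mask") mask_raster((px >= 128) * 1L, pixel_size)
  else density_raster(px, pixel_size)
}

#' Write a niche annotation or DE table as TSV
#'
#' DE tables keep the fixed column order `gene`, `lfc`, `p`, `adj_p`,
#' `significant`, `tested`, `n_group1`, `n_group2`.
#'
#' @param x a data.frame (`niche_annotation`, `de_result`, ...).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
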