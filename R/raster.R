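#' Raster containers
#'
#' Rasters are plain integer matrices with a physical scale. A `mask_raster`
#' is binary (0/1); a `density_raster` holds 8-bit intensities (0-255), used
#' for the distance-decayed amyloid expansion. Row index maps to y, column
#' index to x; pixel centers sit at `(i - 0.5) * pixel_size`.
#'
#' @param pixels integer matrix.
#' @param pixel_size physical pixel edge, micrometres per pixel.
#' @return an object of class `mask_raster` or `density_raster`.
#' @export
mask_raster <- function(pixels, pixel_size) {
  if (!is.matrix(pixels)) stop_invalid("pixels must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_invalid("pixel_size must be a single positive number")
  px <- pixels
  storage.mode(px) <- "integer"
  if (any(px != 0L & px != 1L)) stop_invalid("mask values must be 0 or 1")
  structure(list(pixels = px, pixel_size = as.numeric(pixel_size)),
            class = c("mask_raster", "raster2d"))
}

#' @rdname mask_raster
#' @export
density_raster <- function(pixels, pixel_size) {
  if (!is.matrix(pixels)) stop_invalid("pixels must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_invalid("pixel_size must be a single positive number")
  px <- pixels
  storage.mode(px) <- "integer"
  if (any(px < 0L | px > 255L)) stop_invalid("density values must lie in [0, 255]")
  structure(list(pixels = px, pixel_size = as.numeric(pixel_size)),
            class = c("density_raster", "raster2d"))
}

#' @export
print.raster2d <- function(x, ...) {
  cat(sprintf("<%s> %d x %d px @ %g um/px, %d non-zero\n",
              class(x)[1], nrow(x$pixels), ncol(x$pixels),
              x$pixel_size, sum(x$pixels != 0L)))
  invisible(x)
}

check_same_frame <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop_invalid("rasters have mismatched shapes")
  if (!isTRUE(all.equal(a$pixel_size, b$pixel_size)))
    stop_invalid("rasters have mismatched pixel sizes")
}

#' Cleaning parameters for segmented-signal rasters
#'
#' @param intensity_threshold binarization threshold on the 0-255 scale;
#'   pixels strictly above it become foreground.
#' @param min_object_area,max_object_area connected components with area
#'   outside `[min, max]` (in square micrometres) are removed;
#'   `max_object_area = Inf` disables the upper cut.
#' @param despeckle_radius median-filter radius in pixels (0 disables).
#' @param close_rounds number of dilation+erosion (morphological closing)
#'   passes with a 1-px-radius structuring element.
#' @return a `cleaning_spec` list.
#' @export
cleaning_spec <- function(intensity_threshold = 183,
                          min_object_area = 0,
                          max_object_area = Inf,
                          despeckle_radius = 0L,
                          close_rounds = 2L) {
  if (intensity_threshold < 0 || intensity_threshold > 255)
    stop_invalid("intensity_threshold must lie in [0, 255]")
  if (min_object_area < 0) stop_invalid("min_object_area must be >= 0")
  if (max_object_area < min_object_area)
    stop_invalid("max_object_area must be >= min_object_area")
  if (despeckle_radius < 0 || close_rounds < 0)
    stop_invalid("despeckle_radius and close_rounds must be >= 0")
  structure(list(intensity_threshold = intensity_threshold,
                 min_object_area = min_object_area,
                 max_object_area = max_object_area,
                 despeckle_radius = as.integer(despeckle_radius),
                 close_rounds = as.integer(close_rounds)),
            class = "cleaning_spec")
}

# 8-connected component labeling. EBImage::bwlabel links 4-neighbors only,
# so labels touching diagonally are merged with a union-find pass.
label_components8 <- function(px) {
  lab <- EBImage::bwlabel(px)
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]  # down-left diagonal pairs
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Binarize a grayscale raster and clean the resulting mask
#'
#' Thresholds an 8-bit image (strictly greater than the threshold), optionally
#' median-despeckles, applies `close_rounds` rounds of morphological closing
#' with a 1-px-radius (3x3) structuring element, and removes 8-connected
#' components whose physical area falls outside the configured range.
#'
#' @param image numeric matrix with values in `[0, 255]`.
#' @param spec a [cleaning_spec()].
#' @param pixel_size micrometres per pixel.
#' @return a [mask_raster()].
#' @export
binarize_and_clean <- function(image, spec, pixel_size) {
  if (!inherits(spec, "cleaning_spec")) stop_invalid("spec must be a cleaning_spec")
  if (!is.matrix(image)) stop_invalid("image must be a matrix")
  if (length(image) && (min(image) < 0 || max(image) > 255))
    stop_invalid("image values must lie in [0, 255]")
  px <- (image > spec$intensity_threshold) * 1L
  if (length(px) == 0L || !any(px)) return(mask_raster(px * 0L, pixel_size))
  if (spec$despeckle_radius > 0L)
    px <- round(EBImage::medianFilter(px, spec$despeckle_radius))
  if (spec$close_rounds > 0L) {
    brush <- EBImage::makeBrush(3L, shape = "box")
    for (i in seq_len(spec$close_rounds)) px <- EBImage::dilate(px, brush)
    for (i in seq_len(spec$close_rounds)) px <- EBImage::erode(px, brush)
  }
  px <- matrix(as.integer(px != 0), nrow(image), ncol(image))
  if (any(px) && (spec$min_object_area > 0 || is.finite(spec$max_object_area))) {
    lab <- label_components8(px)
    areas_px <- tabulate(lab[lab > 0])
    areas_um2 <- areas_px * pixel_size^2
    keep <- which(areas_um2 >= spec$min_object_area &
                  areas_um2 <= spec$max_object_area)
    px <- matrix(as.integer(lab %in% keep & lab > 0), nrow(px), ncol(px))
  }
  mask_raster(px, pixel_size)
}

# Exact Euclidean distance (in um) from each pixel center to the nearest
# foreground pixel of the mask; 0 inside, Inf when the mask is empty.
distance_from_mask <- function(mask) {
  px <- mask$pixels
  if (!any(px)) return(matrix(Inf, nrow(px), ncol(px)))
  d <- EBImage::distmap(1L - px, metric = "euclidean")
  matrix(as.numeric(d), nrow(px), ncol(px)) * mask$pixel_size
}

#' Expand a binary amyloid mask with distance-decayed intensity
#'
#' Extends the source signal by `halo` micrometres beyond its boundary, with
#' intensity stepping down once per `band` micrometres. The source itself is
#' 255; a pixel at Euclidean distance `d` from the mask (exact distance
#' transform on pixel centers), with `0 < d <= halo`, receives
#' `floor(255 * (1 - k/6))` where `k = ceiling(d / band)`; beyond the halo
#' the output is 0. With the 100/20 defaults the bands are
#' 212, 170, 127, 85, 42 (rounded down so every band stays below the next).
#'
#' @param mask a [mask_raster()].
#' @param halo halo width in micrometres (default 100).
#' @param band band width in micrometres (default 20); must divide `halo`.
#' @return a [density_raster()].
#' @export
expand_with_decay <- function(mask, halo = 100, band = 20) {
  if (!inherits(mask, "mask_raster")) stop_invalid("mask must be a mask_raster")
  if (halo <= 0 || band <= 0) stop_invalid("halo and band must be positive")
  n_bands <- halo / band
  if (abs(n_bands - round(n_bands)) > 1e-9)
    stop_invalid("halo must be an integer multiple of band")
  n_bands <- round(n_bands)
  px <- mask$pixels
  if (!any(px))
    return(density_raster(matrix(0L, nrow(px), ncol(px)), mask$pixel_size))
  d <- distance_from_mask(mask)
  k <- ceiling(d / band)
  out <- matrix(0L, nrow(px), ncol(px))
  inside <- d <= 0
  out[inside] <- 255L
  in_halo <- !inside & d <= halo
  out[in_halo] <- as.integer(floor(255 * (1 - k[in_halo] / (n_bands + 1))))
  density_raster(out, mask$pixel_size)
}

#' Partition amyloid signal into vascular and cortical components
#'
#' The vascular label raster is dilated `dilation_rounds` times with a
#' 1-px-radius element and intersected with the amyloid mask; the residual
#' amyloid signal is cortical. The two outputs always partition the input.
#'
#' @param ab_mask amyloid [mask_raster()].
#' @param vascular_labels vascular-amyloid label [mask_raster()] in the same
#'   frame (e.g. from a classifier or manual annotation).
#' @param dilation_rounds dilation passes applied to the labels (default 2).
#' @return list with elements `cortical` and `vascular`, both [mask_raster()].
#' @export
partition_vascular <- function(ab_mask, vascular_labels, dilation_rounds = 2L) {
  check_same_frame(ab_mask, vascular_labels)
  lab <- vascular_labels$pixels
  if (dilation_rounds > 0L && any(lab)) {
    brush <- EBImage::makeBrush(3L, shape = "box")
    for (i in seq_len(dilation_rounds)) lab <- EBImage::dilate(lab, brush)
    lab <- matrix(as.integer(lab != 0), nrow(lab), ncol(lab))
  }
  vasc <- ab_mask$pixels * lab
  cort <- ab_mask$pixels * (1L - lab)
  list(cortical = mask_raster(cort, ab_mask$pixel_size),
       vascular = mask_raster(vasc, ab_mask$pixel_size))
}

#' Fraction of a region covered by a mask
#'
#' @param mask,region [mask_raster()] objects in the same frame; `region`
#'   must be non-empty.
#' @return coverage fraction in `[0, 1]`.
#' @export
area_coverage <- function(mask, region) {
  check_same_frame(mask, region)
  denom <- sum(region$pixels)
  if (denom == 0) stop_invalid("region is empty: coverage is undefined")
  sum(mask$pixels * region$pixels) / denom
}

#' Colocalization of a partner signal on a target signal within a region
#'
#' Area of `partner & target & region` divided by the area of
#' `target & region` (e.g. IBA1 coverage of cortical amyloid in gray matter).
#'
#' @param partner,target,region [mask_raster()] objects in the same frame.
#' @return fraction in `[0, 1]`.
#' @export
colocalization_fraction <- function(partner, target, region) {
  check_same_frame(partner, target)
  check_same_frame(target, region)
  tr <- target$pixels * region$pixels
  denom <- sum(tr)
  if (denom == 0) stop_invalid("target within region is empty: fraction is undefined")
  sum(partner$pixels * tr) / denom
}
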