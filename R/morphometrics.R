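#' Segment the largest dark object in a bright-field-style image
#'
#' Thresholds the image with Otsu's between-class-variance criterion,
#' takes the darker side as foreground (bright-field convention: dark
#' organoid on light background), fills holes, and keeps the largest
#' 8-connected component.
#'
#' @param image An `organovote_image`, a numeric matrix of intensities, or
#'   a path to a grayscale PNG.
#' @param min_size Minimum object size in pixels; a smaller (or absent)
#'   largest component is an error.
#' @return An `organovote_mask`: list with `mask` (0/1 matrix congruent
#'   with the raster), `pixel_count`, `bbox` (row/col ranges) and
#'   `pixel_size` (if known from the input).
#' @export
segment_largest_object <- function(image, min_size = 50) {
  pixel_size <- NA_real_
  if (inherits(image, "organovote_image")) {
    pixel_size <- image$pixel_size
    raster <- image$raster
  } else if (is.character(image)) {
    raster <- png::readPNG(image)
    if (length(dim(raster)) == 3) raster <- raster[, , 1]
  } else if (is.matrix(image)) {
    raster <- image
  } else {
    stop("image must be an organovote_image, a matrix, or a PNG path")
  }
  if (length(raster) == 0) stop("empty raster")

  if (diff(range(raster)) < .Machine$double.eps) {
    stop("no organoid found: image has no contrast")
  }
  thr <- EBImage::otsu(EBImage::Image(raster), range = range(raster))
  fg <- raster < thr                      # dark object on light background
  fg <- EBImage::fillHull(fg * 1)
  labels <- label_components8(as.matrix(fg) > 0)
  if (max(labels) == 0) stop("no organoid found")
  sizes <- tabulate(labels[labels > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_size) {
    stop("no organoid found: largest component below min_size")
  }
  mask <- (labels == best) * 1
  idx <- which(mask == 1, arr.ind = TRUE)
  structure(
    list(mask = mask,
         pixel_count = as.integer(sizes[best]),
         bbox = c(row_min = min(idx[, 1]), row_max = max(idx[, 1]),
                  col_min = min(idx[, 2]), col_max = max(idx[, 2])),
         pixel_size = pixel_size),
    class = "organovote_mask"
  )
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch only diagonally with a union-find pass.
label_components8 <- function(binary) {
  lab <- EBImage::bwlabel(binary * 1)
  lab <- as.matrix(lab)
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left neighbours
  pairs <- rbind(
    cbind(as.vector(a1), as.vector(b1)),
    cbind(as.vector(a2), as.vector(b2))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Measure area, perimeter and circularity of a segmentation mask
#'
#' Area is the pixel count scaled by `pixel_size^2`. Perimeter is the
#' length of the sub-pixel 0.5-level contour of the lightly smoothed mask
#' (marching squares), which avoids the upward bias of boundary-pixel
#' counting that would push disc circularity above 1. Circularity is
#' 4*pi*A / P^2, clamped to at most 1 on output (digitization can
#' overshoot by a few percent for small discs).
#'
#' @param mask An `organovote_mask` (or 0/1 matrix).
#' @param pixel_size Micrometres per pixel; defaults to the mask's own
#'   scale when it carries one.
#' @return One-row tibble: `area_um2`, `perimeter_um`, `circularity`.
#' @export
measure_features <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "organovote_mask")) {
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    m <- mask$mask
  } else if (is.matrix(mask)) {
    m <- (mask > 0) * 1
  } else {
    stop("mask must be an organovote_mask or a matrix")
  }
  if (is.null(pixel_size) || is.na(pixel_size)) pixel_size <- 1
  npx <- sum(m)
  if (npx == 0) stop("empty mask")

  perim_px <- contour_perimeter_px(m)
  area <- npx * pixel_size^2
  perim <- perim_px * pixel_size
  circ <- 4 * pi * area / perim^2
  tibble(area_um2 = area, perimeter_um = perim,
         circularity = min(circ, 1))
}

# Sub-pixel perimeter in pixel units: pad, blur (sigma 1 px), trace the
# 0.5-level set with marching squares, sum polyline lengths of the longest
# closed contour.
contour_perimeter_px <- function(m, sigma = 1) {
  pad <- 4L
  z <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  z[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  z <- as.matrix(EBImage::gblur(EBImage::Image(z), sigma = sigma))
  cl <- contourLines(seq_len(nrow(z)), seq_len(ncol(z)), z, levels = 0.5)
  if (!length(cl)) stop("no contour at the 0.5 level")
  max(vapply(cl, function(cc) sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)),
             numeric(1)))
}

#' Extract morphometric features from a set of images
#'
#' Runs [segment_largest_object()] and [measure_features()] over grayscale
#' PNG files and returns a feature table (one row per image, `pdo_id`
#' taken from the file name).
#'
#' @param paths Character vector of PNG paths, or a directory containing
#'   them.
#' @param pixel_size Micrometres per pixel.
#' @param min_size Minimum object size in pixels.
#' @return Tibble: `pdo_id`, `image_path`, `area_um2`, `perimeter_um`,
#'   `circularity`.
#' @export
extract_features <- function(paths, pixel_size = 2, min_size = 50) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.png$", full.names = TRUE)
  }
  if (!length(paths)) stop("no images to measure")
  rows <- lapply(paths, function(p) {
    feats <- measure_features(segment_largest_object(p, min_size = min_size),
                              pixel_size = pixel_size)
    dplyr::bind_cols(
      tibble(pdo_id = sub("\\.png$", "", basename(p)), image_path = p),
      feats
    )
  })
  dplyr::bind_rows(rows)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean: the
#' uniformity statistic used to compare organoid size dispersion between
#' culture platforms.
#'
#' @param values Numeric vector, n >= 2, positive mean.
#' @return Dimensionless CV.
#' @examples
#' coefficient_of_variation(c(1, 3)) # sqrt(2)/2
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("CV undefined for nonpositive mean")
  sd(values) / m
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("correlation needs at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for a constant vector")
  cor(x, y, method = "pearson")
}
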