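#' Threshold an intensity image into a seed mask
#'
#' Segments dark seeds on a light background. When no threshold is given,
#' one is chosen automatically by Otsu's between-class-variance criterion
#' (via \code{EBImage::otsu}). Foreground is the darker-than-threshold
#' region by default; set `dark_foreground = FALSE` for light seeds on a
#' dark background.
#'
#' @param image numeric matrix of intensities, rows = image rows (y, top
#'   down), columns = x. Any range is accepted; it is rescaled internally.
#' @param threshold optional scalar on the same scale as `image`; pixels on
#'   the foreground side of it are kept.
#' @param dark_foreground logical; if `TRUE` (default) foreground is
#'   `image < threshold`.
#' @param pixel_size physical length of one pixel side (default 1); carried
#'   on the mask and applied to all downstream measurements.
#' @return a `binary_image`: list with `mask` (0/1 integer matrix) and
#'   `pixel_size`.
#' @export
binarize <- function(image, threshold = NULL, dark_foreground = TRUE,
                     pixel_size = 1) {
  if (is.array(image) && length(dim(image)) == 3L)
    image <- rgb_to_gray(image)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  rng <- range(image, finite = TRUE)
  if (is.null(threshold)) {
    if (rng[1] == rng[2])
      stop("segmentation failure: constant image and no threshold given",
           call. = FALSE)
    scaled <- (image - rng[1]) / (rng[2] - rng[1])
    th01 <- EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1))
    threshold <- rng[1] + th01 * (rng[2] - rng[1])
  }
  mask <- if (dark_foreground) image < threshold else image > threshold
  mask <- matrix(as.integer(mask), nrow(image), ncol(image))
  if (!any(mask == 1L))
    stop("segmentation failure: no foreground pixels", call. = FALSE)
  structure(list(mask = mask, pixel_size = pixel_size, threshold = threshold),
            class = "binary_image")
}

rgb_to_gray <- function(a) {
  0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px, %d foreground px, pixel_size %g\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$pixel_size))
  invisible(x)
}

# Separable Gaussian smoothing of a numeric matrix, replicate-padded.
# A small blur before iso-contouring removes the staircase bias that a
# hard binary boundary imposes on perimeter estimates.
gauss_smooth <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(v, n) c(rep(v[1], n), v, rep(v[length(v)], n))
  smooth1 <- function(mat) {
    apply(mat, 2, function(col) stats::filter(pad(col, r), k)[(r + 1):(r + length(col))])
  }
  t(smooth1(t(smooth1(m))))
}

# Smoothing scale for contour tracing: grows as the square root of the
# equivalent radius, so the residual grid anisotropy of the binary
# boundary (a roughly constant-percentage perimeter bias at fixed sigma)
# shrinks as resolution grows, while staying well below the wavelength of
# genuine boundary features.
contour_sigma <- function(area_px) {
  min(6, max(1, 0.25 * sqrt(sqrt(area_px / pi))))
}

# Trace the outer 0.5 iso-contour of a single-component 0/1 matrix.
# Returns a polygon in mathematical coordinates: x along columns,
# y increasing upward (y = nrow - row + 0.5, pixel centers at half-integers).
trace_contour <- function(mask, smooth_sigma = 2) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- max(4L, ceiling(3 * smooth_sigma) + 2L)
  padded <- matrix(0, nr + 2L * pad, nc + 2L * pad)
  padded[pad + seq_len(nr), pad + seq_len(nc)] <- mask
  f <- if (smooth_sigma > 0) gauss_smooth(padded, smooth_sigma) else padded
  # contourLines treats z[i, j] as the value at (x[i], y[j]); feed the
  # transpose so i = column (x) and j = row.
  xs <- seq_len(nc + 2L * pad) - pad - 0.5  # original pixel centers at c - 0.5
  ys <- seq_len(nr + 2L * pad) - pad - 0.5
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(f), levels = 0.5)
  if (length(cl) == 0L)
    stop("contour tracing failed: no 0.5 iso-line found", call. = FALSE)
  areas <- vapply(cl, function(cc) abs(poly_signed_area(cc)), 0)
  cc <- cl[[which.max(areas)]]  # outer contour; holes are filled upstream
  polygon_xy(cc$x, nr - cc$y)   # flip row coordinate to y-up
}

new_silhouette <- function(outline, pixel_size = 1) {
  m <- poly_moments(outline)
  ax <- poly_principal_axes(outline)
  hull <- convex_hull(outline)
  rect <- min_area_rect(outline)
  per <- poly_perimeter(outline)
  cper <- poly_perimeter(hull)
  structure(list(
    outline = outline,
    area = m$area,
    perimeter = per,
    convex_perimeter = min(cper, per),
    centroid = m$centroid,
    major_axis = ax$major,
    minor_axis = ax$minor,
    orientation = ax$orientation,
    bbox_length = rect$length,
    bbox_width = rect$width,
    pixel_size = pixel_size), class = "silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf(paste0("<silhouette> area %.6g, perimeter %.6g, L %.5g, ",
                     "W %.5g, centroid (%.4g, %.4g)\n"),
              x$area, x$perimeter, x$bbox_length, x$bbox_width,
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Extract measured silhouettes from a binary image
#'
#' Labels 8-connected foreground components, fills interior holes, rejects
#' components below `min_area_px`, traces each outline at the 0.5 iso-level
#' with sub-pixel interpolation, and measures the geometric primitives every
#' downstream index needs: outline polygon, area and perimeter (shoelace and
#' edge-length sums on the polygon), convex perimeter, centroid,
#' moment-based major/minor axes and orientation, and the sides of the
#' minimum-area rotated bounding rectangle (L, W).
#'
#' Outlines are reported in y-up mathematical coordinates (origin at the
#' bottom-left image corner) and scaled by `pixel_size`, so model comparison
#' never sees a flipped (mirror-image) seed.
#'
#' @param b a `binary_image` from [binarize()], or a 0/1 matrix.
#' @param min_area_px smallest component kept, in pixels (default 50).
#' @return list of `silhouette` objects, sorted left-to-right by centroid x
#'   (ties top-to-bottom).
#' @export
extract_silhouettes <- function(b, min_area_px = 50L) {
  if (is.matrix(b)) b <- structure(list(mask = b, pixel_size = 1),
                                   class = "binary_image")
  mask <- b$mask
  lab <- EBImage::bwlabel(t(mask))   # EBImage images are x-major
  lab <- EBImage::fillHull(lab)
  lab <- t(EBImage::imageData(lab))
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= min_area_px)
  if (length(keep) == 0L)
    stop(sprintf("no component with area >= %d px found", min_area_px),
         call. = FALSE)
  sils <- lapply(keep, function(id) {
    comp <- matrix(as.integer(lab == id), nrow(mask), ncol(mask))
    outline <- trace_contour(comp, smooth_sigma = contour_sigma(counts[id]))
    if (b$pixel_size != 1) {
      outline$x <- outline$x * b$pixel_size
      outline$y <- outline$y * b$pixel_size
    }
    s <- new_silhouette(outline, b$pixel_size)
    s$pixel_area <- counts[id] * b$pixel_size^2
    s
  })
  cx <- vapply(sils, function(s) s$centroid[1], 0)
  cy <- vapply(sils, function(s) s$centroid[2], 0)
  sils[order(cx, -cy)]
}

#' Moment-matched fitted ellipse
#'
#' The ellipse with the same area-normalised second-order central moments as
#' the silhouette region (the construction behind fitted ellipses in
#' particle-analysis software). Axes are full lengths (diameters), matching
#' the aspect-ratio convention `AR = Major Axis / Minor Axis`.
#'
#' @param s a `silhouette`.
#' @return a `fitted_ellipse`: list with `center`, `major_axis`,
#'   `minor_axis`, `orientation` (radians).
#' @export
fit_ellipse <- function(s) {
  if (!inherits(s, "silhouette"))
    stop("s must be a silhouette", call. = FALSE)
  if (s$area <= 0) stop("degenerate region: zero area", call. = FALSE)
  if (s$minor_axis <= 1e-12 * s$major_axis)
    stop("degenerate region: collinear points", call. = FALSE)
  structure(list(center = s$centroid,
                 major_axis = s$major_axis,
                 minor_axis = s$minor_axis,
                 orientation = s$orientation),
            class = "fitted_ellipse")
}

#' @export
print.fitted_ellipse <- function(x, ...) {
  cat(sprintf("<fitted_ellipse> major %.5g, minor %.5g, angle %.2f deg\n",
              x$major_axis, x$minor_axis, 180 / pi * x$orientation))
  invisible(x)
}

#' Build a silhouette directly from a polygon
#'
#' Convenience entry for workflows that already have an outline (model
#' curves, ground-truth fixture polygons) and need the measured quantities
#' without rasterization.
#'
#' @param p a `seed_polygon`.
#' @param pixel_size physical length per coordinate unit (default 1).
#' @return a `silhouette`.
#' @export
silhouette_from_polygon <- function(p, pixel_size = 1) {
  new_silhouette(ensure_ccw(p), pixel_size)
}

#' Read a seed image file
#'
#' Reads PNG or TIFF (8/16-bit, grayscale or RGB; RGB is converted by
#' luminance) into an intensity matrix in `[0, 1]`, rows top-down.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return numeric intensity matrix.
#' @export
read_seed_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) a <- rgb_to_gray(a) else a <- a[, , 1]
  }
  a
}
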