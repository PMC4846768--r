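#' Classical seed shape indices
#'
#' Six scalar descriptors computed from caliper measurements or silhouette
#' geometry: eccentricity index EI = L/W, fitted-ellipse aspect ratio
#' AR = major/minor, flatness index FI = (L + W) / (2 H), circularity
#' I = 4 pi area / perimeter^2, roundness R = 4 area / (pi major^2), and
#' rugosity Ps / Pc (seed perimeter over convex perimeter).
#'
#' Circularity and roundness are 1 for a circle and decrease with
#' departure from it; circularity is sensitive to boundary protuberances
#' (they inflate the perimeter) while roundness is not. Rugosity is 1 for
#' convex outlines and grows with boundary roughness. FI is 1 for spheres
#' and exceeds 2 for spindly seeds; it requires a physical height H and is
#' never inferred from a 2-D image.
#'
#' @name shape-indices
NULL

check_positive <- function(..., what) {
  v <- c(...)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("invalid measurement: ", what, " must be positive", call. = FALSE)
}

# raster discretization slack: values this far past a theoretical bound are
# clamped with a warning; beyond it they signal an upstream geometry bug
.index_eps <- 1e-3

clamp_index <- function(value, upper, name) {
  if (value > upper + .index_eps)
    stop(sprintf("invalid measurement: %s = %.6g exceeds %g beyond tolerance",
                 name, value, upper), call. = FALSE)
  if (value > upper) {
    warning(sprintf("%s = %.6g clamped to %g (discretization slack)",
                    name, value, upper), call. = FALSE)
    value <- upper
  }
  value
}

#' @rdname shape-indices
#' @param L,W,H seed length, width and height (any common length unit).
#' @return a scalar index value.
#' @examples
#' eccentricity_index(5, 2)    # 2.5
#' flatness_index(10, 2, 1)    # 6, a spindly seed
#' circularity(pi, 2 * pi)     # 1, the unit circle
#' @export
eccentricity_index <- function(L, W) {
  check_positive(L, W, what = "L and W")
  if (L < W) {
    warning("L < W: inputs swapped so that length is the longer side",
            call. = FALSE)
    tmp <- L; L <- W; W <- tmp
  }
  L / W
}

#' @rdname shape-indices
#' @param e a `fitted_ellipse` from [fit_ellipse()], or a list with
#'   `major_axis` and `minor_axis`.
#' @export
aspect_ratio <- function(e) {
  if (is.null(e$major_axis) || is.null(e$minor_axis))
    stop("e must provide major_axis and minor_axis", call. = FALSE)
  check_positive(e$minor_axis, what = "minor axis")
  e$major_axis / e$minor_axis
}

#' @rdname shape-indices
#' @export
flatness_index <- function(L, W, H) {
  check_positive(L, W, H, what = "L, W and H")
  (L + W) / (2 * H)
}

#' @rdname shape-indices
#' @param area region area (squared length units).
#' @param perimeter boundary length `Ps`.
#' @export
circularity <- function(area, perimeter) {
  check_positive(area, perimeter, what = "area and perimeter")
  clamp_index(4 * pi * area / perimeter^2, 1, "circularity")
}

#' @rdname shape-indices
#' @param major_axis full major axis (diameter) of the fitted ellipse.
#' @export
roundness <- function(area, major_axis) {
  check_positive(area, major_axis, what = "area and major axis")
  clamp_index(4 * area / (pi * major_axis^2), 1, "roundness")
}

#' @rdname shape-indices
#' @param perimeter boundary length `Ps`.
#' @param convex_perimeter convex-hull boundary length `Pc`.
#' @export
rugosity <- function(perimeter, convex_perimeter) {
  check_positive(perimeter, convex_perimeter, what = "perimeters")
  if (perimeter < convex_perimeter * (1 - .index_eps))
    stop("invalid measurement: perimeter < convex perimeter signals ",
         "inconsistent upstream geometry", call. = FALSE)
  max(1, perimeter / convex_perimeter)
}

#' All image-derived indices for one silhouette
#'
#' Computes EI, AR, circularity, roundness and rugosity from a measured
#' silhouette; the flatness index is included only when a height `H` is
#' supplied.
#'
#' @param s a `silhouette`.
#' @param H optional physical seed height (same unit as `pixel_size`
#'   lengths) for the flatness index.
#' @return named list of index values.
#' @export
index_set <- function(s, H = NULL) {
  e <- fit_ellipse(s)
  out <- list(
    EI = eccentricity_index(s$bbox_length, s$bbox_width),
    AR = aspect_ratio(e),
    circularity = circularity(s$area, s$perimeter),
    roundness = roundness(s$area, e$major_axis),
    rugosity = rugosity(s$perimeter, s$convex_perimeter))
  if (!is.null(H))
    out$FI <- flatness_index(s$bbox_length, s$bbox_width, H)
  out
}
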