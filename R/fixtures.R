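#' Specification of a synthetic seed image
#'
#' Bundles everything needed to render one ground-truthed synthetic seed:
#' the model curve it is built from, the amplitude of the smooth radial
#' perturbation applied to its outline, the rendering resolution, the pose
#' in the image, and the RNG seed. Identical specs render bit-identical
#' images.
#'
#' @param kind model kind, see [make_model()].
#' @param scale model size parameter (default 1).
#' @param radial_noise_sigma standard deviation of the radial boundary
#'   perturbation, as a fraction of `scale` (default 0).
#' @param resolution pixels across the seed's long axis (>= 64, default 500).
#' @param pose list with `dx`, `dy` (pixels) and `rotation` (radians)
#'   applied to the rendered seed.
#' @param rng_seed integer seed for the perturbation harmonics.
#' @param n_vertices boundary samples of the underlying model.
#' @param ... extra model parameters for [make_model()].
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(kind = "cardioid", scale = 1,
                         radial_noise_sigma = 0, resolution = 500L,
                         pose = list(dx = 0, dy = 0, rotation = 0),
                         rng_seed = 1L, n_vertices = 720L, ...) {
  if (resolution < 64)
    stop("resolution must be >= 64 pixels", call. = FALSE)
  if (radial_noise_sigma < 0)
    stop("radial_noise_sigma must be >= 0", call. = FALSE)
  structure(list(kind = kind, scale = scale,
                 radial_noise_sigma = radial_noise_sigma,
                 resolution = as.integer(resolution), pose = pose,
                 rng_seed = as.integer(rng_seed),
                 n_vertices = as.integer(n_vertices),
                 extra = list(...)),
            class = "fixture_spec")
}

# evaluate a function under a local RNG seed without disturbing the
# caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# smooth low-frequency radial perturbation: random Fourier series over
# harmonics 2..8, normalised to unit standard deviation over theta
radial_noise <- function(theta, harmonics = 2:8) {
  amp <- stats::rnorm(length(harmonics))
  phase <- stats::runif(length(harmonics), 0, 2 * pi)
  d <- rep(0, length(theta))
  for (i in seq_along(harmonics))
    d <- d + amp[i] * cos(harmonics[i] * theta + phase[i])
  d / sqrt(sum(amp^2) / 2)
}

perturbed_model_polygon <- function(spec) {
  m <- do.call(make_model, c(list(kind = spec$kind, scale = spec$scale,
                                  n_vertices = spec$n_vertices), spec$extra))
  p <- m$polygon
  if (spec$radial_noise_sigma == 0) return(p)
  ctr <- poly_centroid(p)
  theta <- atan2(p$y - ctr[2], p$x - ctr[1])
  for (attempt in 1:10) {
    d <- radial_noise(theta)
    r <- sqrt((p$x - ctr[1])^2 + (p$y - ctr[2])^2)
    rr <- r + spec$radial_noise_sigma * spec$scale * d
    q <- list(x = ctr[1] + rr * cos(theta), y = ctr[2] + rr * sin(theta))
    ok <- all(rr > 0) && poly_is_simple(q)
    if (ok) return(polygon_xy(q$x, q$y))
  }
  stop("radial noise self-intersects the outline after 10 attempts; ",
       "reduce radial_noise_sigma", call. = FALSE)
}

# Even-odd scanline rasterizer. Pixel (row r, col c) of an nr x nc image
# has its center at x = c - 0.5, y = nr - r + 0.5 (y-up mathematical
# coordinates, matching extract_silhouettes). Deliberately elementary: it
# is the independent oracle the polygon-clipping J is checked against.
rasterize_polygon <- function(p, nr, nc) {
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  mask <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    yc <- nr - r + 0.5
    cross <- (y > yc) != (yn > yc)
    if (!any(cross)) next
    xi <- x[cross] + (yc - y[cross]) / (yn[cross] - y[cross]) *
      (xn[cross] - x[cross])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      c0 <- ceiling(xi[k] + 0.5)
      c1 <- floor(xi[k + 1] + 0.5 - 1e-9)
      if (c1 >= c0) {
        c0 <- max(1L, c0); c1 <- min(nc, c1)
        if (c1 >= c0) mask[r, c0:c1] <- TRUE
      }
    }
  }
  mask
}

#' Render a ground-truthed synthetic seed image
#'
#' Perturbs the model outline with smooth low-frequency radial noise, poses
#' it, and rasterizes it with supersampled anti-aliasing as a dark seed on
#' a light background. Both the 8-bit image and the exact perturbed polygon
#' (in image coordinates) are returned, so segmentation and measurement can
#' be validated against ground truth.
#'
#' @param spec a [fixture_spec()].
#' @return list with `image` (integer matrix, 0-255, rows top-down),
#'   `ground_truth` (`seed_polygon` in image coordinates, y-up, units px)
#'   and `spec`.
#' @export
generate_seed_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  poly <- with_local_seed(spec$rng_seed, perturbed_model_polygon(spec))
  # scale model units -> pixels so the long axis spans `resolution` px
  rect <- min_area_rect(poly)
  px_per_unit <- spec$resolution / rect$length
  ctr <- poly_centroid(poly)
  poly <- poly_translate(poly, -ctr[1], -ctr[2])
  poly <- poly_scale(poly, px_per_unit, center = c(0, 0))
  if (spec$pose$rotation != 0)
    poly <- poly_rotate(poly, spec$pose$rotation, center = c(0, 0))
  margin <- 8
  w <- diff(range(poly$x)); h <- diff(range(poly$y))
  nc <- ceiling(w + 2 * margin + abs(spec$pose$dx))
  nr <- ceiling(h + 2 * margin + abs(spec$pose$dy))
  poly <- poly_translate(poly, nc / 2 + spec$pose$dx, nr / 2 + spec$pose$dy)
  # 3x supersampling for anti-aliased coverage
  ss <- 3L
  big <- poly_scale(poly, ss, center = c(0, 0))
  cover <- rasterize_polygon(big, nr * ss, nc * ss)
  cov <- block_mean(cover, ss)
  image <- matrix(as.integer(round(255 - 225 * cov)), nr, nc)
  list(image = image, ground_truth = poly, spec = spec)
}

block_mean <- function(m, k) {
  nr <- nrow(m) / k; nc <- ncol(m) / k
  # average k x k blocks
  m <- matrix(colMeans(matrix(as.numeric(m), nrow = k)), nrow(m) / k,
              ncol(m), byrow = FALSE)
  t(matrix(colMeans(matrix(as.numeric(t(m)), nrow = k)), nc, nr))
}

#' Brute-force raster J oracle
#'
#' Re-evaluates the J index by pixel counting: both polygons are rasterized
#' on a common grid and shared/unshared pixels are counted. This is the
#' independent cross-check for [compute_j()]'s exact polygon clipping; the
#' two routes agree to within the rasterization error of the grid.
#'
#' @param a,b `seed_polygon`s in a common frame.
#' @param resolution pixels across the larger bounding-box dimension of the
#'   pair (>= 64; default 1000).
#' @return scalar J value in `[0, 100]`.
#' @export
raster_j_oracle <- function(a, b, resolution = 1000L) {
  if (resolution < 64)
    stop("resolution must be >= 64 pixels", call. = FALSE)
  xr <- range(a$x, b$x); yr <- range(a$y, b$y)
  span <- max(diff(xr), diff(yr))
  s <- resolution / span
  shift <- function(p) polygon_xy((p$x - xr[1]) * s + 2, (p$y - yr[1]) * s + 2)
  nc <- ceiling(diff(xr) * s) + 4L
  nr <- ceiling(diff(yr) * s) + 4L
  ma <- rasterize_polygon(shift(a), nr, nc)
  mb <- rasterize_polygon(shift(b), nr, nc)
  C <- sum(ma & mb)
  D <- sum(xor(ma, mb))
  if (C + D == 0) return(0)
  100 * C / (C + D)
}
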