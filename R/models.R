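#' The golden ratio
#'
#' The constant Phi = (1 + sqrt(5)) / 2, approximately 1.618. Seeds of
#' several species (e.g. *Arabidopsis thaliana*, *Medicago truncatula*) are
#' well described by a cardioid stretched along one axis by this factor.
#'
#' @return Phi at full floating-point precision.
#' @examples
#' round(golden_ratio(), 3)  # 1.618
#' @export
golden_ratio <- function() (1 + sqrt(5)) / 2

new_model_shape <- function(kind, parameters, polygon) {
  structure(list(kind = kind, parameters = parameters, polygon = polygon),
            class = "model_shape")
}

#' @export
print.model_shape <- function(x, ...) {
  pars <- paste(names(x$parameters),
                vapply(x$parameters, function(v) format(v, digits = 4), ""),
                sep = "=", collapse = ", ")
  cat(sprintf("<model_shape> kind=%s (%s), %d vertices, area %.6g\n",
              x$kind, pars, length(x$polygon$x), poly_area(x$polygon)))
  invisible(x)
}

check_n_vertices <- function(n_vertices) {
  if (!is.numeric(n_vertices) || length(n_vertices) != 1L ||
      n_vertices < 16 || n_vertices != round(n_vertices))
    stop("n_vertices must be an integer >= 16", call. = FALSE)
  as.integer(n_vertices)
}

#' Cardioid model curve
#'
#' Samples the polar curve r(theta) = scale * (1 + cos(theta)) at
#' `n_vertices` angles uniform in theta, covering `[0, 2*pi)`. The cusp
#' (theta = pi, the point at the origin) is always included as a vertex: for
#' odd `n_vertices` the nearest sample is snapped onto it. The long axis of
#' the curve lies along x, with the cusp on the negative-x side of the
#' centroid and the lobe at (2 * scale, 0). The enclosed area converges to
#' 3 * pi * scale^2 / 2.
#'
#' @param scale positive size parameter `a` of r = a (1 + cos theta).
#' @param n_vertices number of boundary samples (integer >= 16, default 720).
#' @return a `model_shape` of kind `"cardioid"`.
#' @examples
#' card <- make_cardioid(1, 720)
#' poly_area(card$polygon)  # ~ 3 * pi / 2
#' @export
make_cardioid <- function(scale, n_vertices = 720L) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("scale must be a positive scalar", call. = FALSE)
  n <- check_n_vertices(n_vertices)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  theta[which.min(abs(theta - pi))] <- pi  # cusp is always a vertex
  r <- scale * (1 + cos(theta))
  new_model_shape("cardioid", list(scale = scale, n_vertices = n),
                  polygon_xy(r * cos(theta), r * sin(theta)))
}

#' Ellipse (and circle) model curve
#'
#' Samples (a cos theta, b sin theta) uniformly in theta. When the two
#' semi-axes are equal the kind is reported as `"circle"`.
#'
#' @param semi_major,semi_minor semi-axis lengths, `semi_major >= semi_minor > 0`.
#' @param n_vertices number of boundary samples (integer >= 16, default 720).
#' @return a `model_shape` of kind `"ellipse"` or `"circle"`.
#' @export
make_ellipse <- function(semi_major, semi_minor, n_vertices = 720L) {
  if (!is.numeric(semi_major) || !is.numeric(semi_minor) ||
      !is.finite(semi_major) || !is.finite(semi_minor) ||
      semi_minor <= 0 || semi_major < semi_minor)
    stop("require semi_major >= semi_minor > 0", call. = FALSE)
  n <- check_n_vertices(n_vertices)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  kind <- if (semi_major == semi_minor) "circle" else "ellipse"
  new_model_shape(kind,
                  list(semi_major = semi_major, semi_minor = semi_minor,
                       n_vertices = n),
                  polygon_xy(semi_major * cos(theta), semi_minor * sin(theta)))
}

#' Ovoid (egg curve) model
#'
#' A Huegelschaeffer-type egg: the ellipse ordinate is modulated by a shifted
#' denominator, \deqn{y(\theta) = \frac{a b \sin\theta}
#' {\sqrt{a^2 + 2 w a\cos\theta + w^2}}, \quad x(\theta) = a\cos\theta,}
#' with `a = scale`, `b = scale / aspect` and shift `w = asymmetry * a`.
#' The curve is symmetric about its long (x) axis; `asymmetry = 0` reduces
#' exactly to `make_ellipse(a, b)` sampled at the same angles. Positive
#' asymmetry narrows the +x end (the pointed pole of the egg).
#'
#' @param scale positive semi-major axis length.
#' @param asymmetry egg-shape parameter in `[0, 1)`; 0 gives an ellipse.
#' @param n_vertices number of boundary samples (integer >= 16, default 720).
#' @param aspect ratio of semi-major to semi-minor axis; defaults to the
#'   golden ratio, a typical elongation for ovoid seeds.
#' @return a `model_shape` of kind `"ovoid"`.
#' @export
make_ovoid <- function(scale, asymmetry, n_vertices = 720L,
                       aspect = golden_ratio()) {
  if (!is.numeric(scale) || scale <= 0)
    stop("scale must be a positive scalar", call. = FALSE)
  if (!is.numeric(asymmetry) || length(asymmetry) != 1L ||
      asymmetry < 0 || asymmetry >= 1)
    stop("asymmetry must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(aspect) || aspect < 1)
    stop("aspect must be >= 1", call. = FALSE)
  n <- check_n_vertices(n_vertices)
  a <- scale; b <- scale / aspect; w <- asymmetry * a
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  x <- a * cos(theta)
  y <- a * b * sin(theta) / sqrt(a^2 + 2 * w * x + w^2)
  new_model_shape("ovoid",
                  list(scale = scale, asymmetry = asymmetry, aspect = aspect,
                       n_vertices = n),
                  polygon_xy(x, y))
}

#' Build a model shape by name
#'
#' Dispatcher over the reference shapes used for seed comparison. The
#' stretched kinds `cardioid_x_phi` and `cardioid_y_phi` are the base
#' cardioid elongated about its centroid by the golden ratio along the named
#' axis (the x-stretched form models *Arabidopsis*, the y-stretched form
#' *Medicago*).
#'
#' @param kind one of `"circle"`, `"ellipse"`, `"cardioid"`,
#'   `"cardioid_x_phi"`, `"cardioid_y_phi"`, `"ovoid"`.
#' @param scale size parameter passed to the base constructor (for
#'   `ellipse`, the semi-major axis).
#' @param n_vertices boundary samples, default 720.
#' @param ... further parameters for the base constructor
#'   (`semi_minor`, `asymmetry`, `aspect`).
#' @return a `model_shape`.
#' @examples
#' m <- make_model("cardioid_x_phi", scale = 1)
#' @export
make_model <- function(kind = c("cardioid", "cardioid_x_phi", "cardioid_y_phi",
                                "ellipse", "circle", "ovoid"),
                       scale = 1, n_vertices = 720L, ...) {
  kind <- match.arg(kind)
  extra <- list(...)
  m <- switch(kind,
    cardioid = make_cardioid(scale, n_vertices),
    cardioid_x_phi = {
      base <- make_cardioid(scale, n_vertices)
      new_model_shape("cardioid_x_phi",
                      c(base$parameters, list(phi = golden_ratio())),
                      elongate(base$polygon, "x", golden_ratio()))
    },
    cardioid_y_phi = {
      base <- make_cardioid(scale, n_vertices)
      new_model_shape("cardioid_y_phi",
                      c(base$parameters, list(phi = golden_ratio())),
                      elongate(base$polygon, "y", golden_ratio()))
    },
    circle = make_ellipse(scale, scale, n_vertices),
    ellipse = {
      b <- if (is.null(extra$semi_minor)) scale / golden_ratio()
           else extra$semi_minor
      make_ellipse(scale, b, n_vertices)
    },
    ovoid = {
      asym <- if (is.null(extra$asymmetry)) 0.2 else extra$asymmetry
      asp <- if (is.null(extra$aspect)) golden_ratio() else extra$aspect
      make_ovoid(scale, asym, n_vertices, asp)
    })
  m
}
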