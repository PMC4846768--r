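# --- polygon boolean helpers (exact clipping via polyclip/Clipper) --------

# clip at a spatial resolution far below coordinate scale, so that area
# identities (C + D = union) and rigid invariance hold to ~1e-10 relative
clip_eps <- function(...) {
  paths <- list(...)
  m <- max(abs(unlist(paths)), 1e-9)
  m * 1e-12
}

clip_op <- function(a, b, op) {
  polyclip::polyclip(list(as_poly_list(a)), list(as_poly_list(b)), op = op,
                     eps = clip_eps(a$x, a$y, b$x, b$y))
}

paths_area <- function(paths) {
  if (length(paths) == 0L) return(0)
  # outer boundaries and holes come back with opposite orientations;
  # the signed sum is the net enclosed area
  abs(sum(vapply(paths, poly_signed_area, 0)))
}

#' J index: percentage overlap between seed and model figures
#'
#' For two figures in a common frame the J index is
#' \deqn{J = \frac{C}{C + D} \times 100,}
#' where `C` is the area of the region shared by both figures and `D` the
#' total area of the regions not shared (the symmetric difference). Since
#' `C + D` is the area of the union, `J/100` equals the Jaccard
#' intersection-over-union of the two figures. J is 100 exactly when the
#' figures coincide (D = 0) and 0 when they are disjoint; it measures shape
#' agreement, not size, once the figures are area-matched by
#' [align_model()].
#'
#' Areas are computed by exact polygon boolean operations (intersection and
#' symmetric difference) on the vertex chains; the additivity identity
#' `C + D = area(union)` is verified numerically on every call.
#'
#' @param seed,model simple `seed_polygon`s with positive area, already in a
#'   common coordinate frame.
#' @param check_simple if `TRUE` (default) both inputs are screened for
#'   self-intersections (O(n^2)); alignment loops disable this.
#' @return an `overlap_result`: list with `area_C`, `area_D`, `j`, and the
#'   clipped `pieces` (intersection and difference paths) for regional
#'   analysis.
#' @examples
#' a <- polygon_xy(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' b <- polygon_xy(c(0.5, 1.5, 1.5, 0.5), c(0, 0, 1, 1))
#' compute_j(a, b)$j  # 33.33...
#' @export
compute_j <- function(seed, model, check_simple = TRUE) {
  for (p in list(seed, model)) {
    if (check_simple && !poly_is_simple(p))
      stop("invalid geometry: self-intersecting polygon", call. = FALSE)
    if (poly_area(p) <= 0)
      stop("invalid geometry: polygon with zero area", call. = FALSE)
  }
  inter <- clip_op(seed, model, "intersection")
  xor <- clip_op(seed, model, "xor")
  uni <- clip_op(seed, model, "union")
  C <- paths_area(inter)
  D <- paths_area(xor)
  U <- paths_area(uni)
  if (abs((C + D) - U) > 1e-6 * max(U, 1e-12))
    warning("overlap areas violate C + D = union beyond tolerance",
            call. = FALSE)
  j <- if (C + D == 0) 0 else 100 * C / (C + D)
  structure(list(area_C = C, area_D = D, j = j,
                 pieces = list(shared = inter, unshared = xor)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> J = %.3f (C = %.6g, D = %.6g)\n",
              x$j, x$area_C, x$area_D))
  invisible(x)
}

# Model polygon in its canonical (reference) frame: centroid at origin and
# the reference direction along +x. For cardioid kinds the reference
# direction points from the centroid toward the cusp (so "right" in the
# aligned frame is the cusp side); this comes from the construction, not
# from moments, because the base cardioid's principal axis is transverse to
# its cusp axis and moment signs are unstable there. Plain polygons are
# canonicalised by their principal axis.
canonical_model_poly <- function(m) {
  if (inherits(m, "model_shape")) {
    p <- m$polygon
    ctr <- poly_centroid(p)
    p <- poly_translate(p, -ctr[1], -ctr[2])
    crot <- 0
    if (m$kind %in% c("cardioid", "cardioid_x_phi", "cardioid_y_phi")) {
      crot <- pi  # cusp was at -x
      p <- poly_rotate(p, crot, center = c(0, 0))
    }
    list(poly = p, rot = crot, centroid = ctr)
  } else {
    ctr <- poly_centroid(m)
    phi <- poly_principal_axes(m)$orientation
    list(poly = poly_rotate(poly_translate(m, -ctr[1], -ctr[2]), -phi,
                            center = c(0, 0)),
         rot = -phi, centroid = ctr)
  }
}

wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  if (a <= -pi) a + 2 * pi else a
}

as_outline <- function(s) {
  if (inherits(s, "silhouette")) s$outline
  else if (inherits(s, "model_shape")) s$polygon
  else s
}

place_model <- function(canon, rotation, scale, translation, flipped) {
  p <- canon
  if (flipped) p <- poly_flip_y(p, 0)
  p <- poly_scale(p, scale, center = c(0, 0))
  p <- poly_rotate(p, rotation, center = c(0, 0))
  poly_translate(p, translation[1], translation[2])
}

#' Align a model curve to a seed silhouette
#'
#' Finds the similarity transform (translation, rotation, area-matched
#' scale, optional mirror flip) that superimposes a model curve on a seed.
#' The scale is fixed so that model and seed areas are equal - J then
#' measures shape only, never size. Centroids are matched and principal
#' axes aligned; the 180-degree and mirror ambiguities of the axis (and the
#' axis swap allowed by near-isotropic shapes) are resolved by evaluating J
#' at the candidate poses (theta + k pi/2) x (flip, no flip) and keeping
#' the best. With `refine = TRUE` a
#' Nelder-Mead search over (rotation, dx, dy) then polishes the pose from
#' the best candidate.
#'
#' @param s the seed: a `silhouette` or `seed_polygon`.
#' @param m the model: a `model_shape` or `seed_polygon`.
#' @param refine logical; run the derivative-free local refinement
#'   (default `TRUE`; turn off for strictly deterministic pipelines).
#' @return a `model_fit`: list with `translation`, `rotation`, `scale`,
#'   `flipped`, and the achieved `j`.
#' @export
align_model <- function(s, m, refine = TRUE) {
  seed <- as_outline(s)
  if (poly_area(seed) <= 0) stop("degenerate region: zero seed area",
                                 call. = FALSE)
  canon <- canonical_model_poly(m)
  sc <- sqrt(poly_area(seed) / poly_area(canon$poly))
  sm <- poly_moments(seed)
  phi_s <- poly_principal_axes(seed)$orientation
  phi_c <- poly_principal_axes(canon$poly)$orientation
  best <- NULL
  # quarter-turn candidates cover the 180-degree axis ambiguity and the
  # axis-swap case where the seed's major axis matches the model's minor
  # axis (near-isotropic shapes make the principal axis uninformative)
  for (flip in c(FALSE, TRUE)) {
    for (delta in c(0, 0.5, 1, 1.5) * pi) {
      psi <- phi_s - phi_c + delta
      cand <- place_model(canon$poly, psi, sc, sm$centroid, flip)
      j <- compute_j(seed, cand, check_simple = FALSE)$j
      # ties (symmetry-equivalent poses) resolve to the earliest candidate:
      # unflipped and smallest rotation offset
      if (is.null(best) || j > best$j + 1e-9)
        best <- list(psi = psi, flipped = flip, j = j)
    }
  }
  center <- sm$centroid
  if (refine) {
    len <- sqrt(poly_area(seed))
    obj <- function(par) {
      cand <- place_model(canon$poly, par[1], sc,
                          sm$centroid + par[2:3] * len, best$flipped)
      -compute_j(seed, cand, check_simple = FALSE)$j
    }
    opt <- stats::optim(c(best$psi, 0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 120, reltol = 1e-6))
    if (-opt$value > best$j) {
      best$psi <- opt$par[1]
      best$j <- -opt$value
      center <- sm$centroid + opt$par[2:3] * len
    }
  }
  # public fields are net quantities relative to the model's original pose:
  # translation is the centroid displacement, rotation the net turn (for
  # flipped fits, applied after mirroring about the canonical x-axis)
  structure(list(translation = center - canon$centroid,
                 rotation = wrap_angle(best$psi + canon$rot),
                 scale = sc, flipped = best$flipped, j = best$j,
                 canon_rot = canon$rot, model_centroid = canon$centroid),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "<model_fit> J = %.3f, rotation %.3f rad, scale %.5g, flipped %s\n",
    x$j, x$rotation, x$scale, x$flipped))
  invisible(x)
}

#' Apply a model fit to a model shape
#'
#' Returns the model polygon placed in the seed's coordinate frame under a
#' [align_model()] fit. The placed polygon has the same area as the seed
#' the fit was computed against.
#'
#' @param m the `model_shape` (or polygon) that was aligned.
#' @param fit a `model_fit`.
#' @return a `seed_polygon` in seed coordinates.
#' @export
apply_fit <- function(m, fit) {
  p <- as_outline(m)
  canon <- poly_rotate(poly_translate(p, -fit$model_centroid[1],
                                      -fit$model_centroid[2]),
                       fit$canon_rot, center = c(0, 0))
  place_model(canon, fit$rotation - fit$canon_rot, fit$scale,
              fit$model_centroid + fit$translation, fit$flipped)
}

#' Seed and model in the aligned analysis frame
#'
#' Transforms both figures into the frame used for regional J values: the
#' seed centroid at the origin, the model's reference axis along +x with
#' its reference direction (for cardioids, the cusp) pointing right. The
#' seed keeps its own chirality; if the fit required a mirror flip the
#' model appears flipped instead.
#'
#' @param s the seed (`silhouette` or polygon).
#' @param m the aligned `model_shape`.
#' @param fit the `model_fit` from [align_model()].
#' @return list with elements `seed` and `model` (both `seed_polygon`s).
#' @export
aligned_frame <- function(s, m, fit) {
  seed <- as_outline(s)
  model <- apply_fit(m, fit)
  ctr <- poly_centroid(seed)
  # undoing the placement rotation leaves the model in its canonical pose:
  # reference direction (cusp for cardioids) along +x
  back <- -(fit$rotation - fit$canon_rot)
  tidy <- function(p) {
    poly_rotate(poly_translate(p, -ctr[1], -ctr[2]), back, center = c(0, 0))
  }
  list(seed = tidy(seed), model = tidy(model))
}

region_rects <- function(center, halfspan, scheme) {
  cx <- center[1]; cy <- center[2]; h <- halfspan
  rect <- function(x0, x1, y0, y1)
    list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  if (scheme == "halves_lr") {
    list(left = rect(cx - h, cx, cy - h, cy + h),
         right = rect(cx, cx + h, cy - h, cy + h))
  } else {
    list(Q1 = rect(cx, cx + h, cy, cy + h),
         Q2 = rect(cx - h, cx, cy, cy + h),
         Q3 = rect(cx - h, cx, cy - h, cy),
         Q4 = rect(cx, cx + h, cy - h, cy))
  }
}

#' Regional J values
#'
#' Applies the J formula to the pieces of the shared (C) and unshared (D)
#' regions clipped to each part of a partition of the plane: left/right
#' halves or the four quadrants. The partition axes pass through the seed
#' centroid, parallel and perpendicular to the aligned principal axis, so
#' the inputs must already be in the aligned frame (see [aligned_frame()]).
#' Quadrants are numbered counter-clockwise from upper-right (Q1 = x > 0,
#' y > 0 about the centroid).
#'
#' Because each region's C and D are clips of the global C and D, the
#' area-weighted recombination of regional values reproduces the global J
#' exactly (up to clipping tolerance).
#'
#' @param seed,model aligned `seed_polygon`s.
#' @param scheme `"halves_lr"` or `"quadrants"`.
#' @return a named list of class `regional_j`: per-region `j` values, with
#'   attributes `C` and `D` holding the per-region areas.
#' @export
regional_j <- function(seed, model, scheme = c("halves_lr", "quadrants")) {
  scheme <- match.arg(scheme)
  ov <- compute_j(seed, model, check_simple = FALSE)
  ctr <- poly_centroid(seed)
  span <- 2 * max(abs(c(seed$x - ctr[1], seed$y - ctr[2],
                        model$x - ctr[1], model$y - ctr[2]))) + 1
  rects <- region_rects(ctr, span, scheme)
  eps <- clip_eps(seed$x, seed$y, model$x, model$y)
  out <- list()
  Cr <- Dr <- numeric(length(rects))
  names(Cr) <- names(Dr) <- names(rects)
  for (rn in names(rects)) {
    r <- list(rects[[rn]])
    Cr[rn] <- paths_area(polyclip::polyclip(ov$pieces$shared, r,
                                            "intersection", eps = eps))
    Dr[rn] <- paths_area(polyclip::polyclip(ov$pieces$unshared, r,
                                            "intersection", eps = eps))
    seed_part <- paths_area(polyclip::polyclip(list(as_poly_list(seed)), r,
                                               "intersection", eps = eps))
    if (seed_part <= 1e-9 * poly_area(seed))
      stop("degenerate region: no seed area in region ", rn, call. = FALSE)
    out[[rn]] <- unname(if (Cr[rn] + Dr[rn] == 0) 100 else
      100 * Cr[rn] / (Cr[rn] + Dr[rn]))
  }
  structure(out, C = Cr, D = Dr, global_j = ov$j, class = "regional_j")
}

#' @export
print.regional_j <- function(x, ...) {
  cat("<regional_j>",
      paste(names(x), sprintf("%.2f", unlist(x)), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Morphotype classification from left/right cardioid similarity
#'
#' Seeds compared with a cardioid fall into four morphological types
#' according to whether the left and right regional J values reach their
#' thresholds (defaults 92 left, 80 right):
#' type A (left and right both at/above threshold), type B (only right),
#' type C (only left) and type BC (neither). Threshold values themselves
#' count as "above" so every pair of values is classifiable. (The published
#' verbal definition of type BC garbles left and right; the self-consistent
#' reading - both sides below threshold - is used here.)
#'
#' @param left_j,right_j regional J values in `[0, 100]`.
#' @param left_threshold,right_threshold classification cutoffs, defaults
#'   92 and 80; other species may need other values.
#' @return one of `"A"`, `"B"`, `"C"`, `"BC"`.
#' @examples
#' classify_morphotype(95, 85)  # "A"
#' classify_morphotype(90, 70)  # "BC"
#' @export
classify_morphotype <- function(left_j, right_j,
                                left_threshold = 92, right_threshold = 80) {
  v <- c(left_j, right_j)
  if (!all(is.finite(v)) || any(v < 0) || any(v > 100))
    stop("invalid measurement: regional J values must lie in [0, 100]",
         call. = FALSE)
  lhi <- left_j >= left_threshold
  rhi <- right_j >= right_threshold
  if (lhi && rhi) "A" else if (!lhi && rhi) "B" else if (lhi && !rhi) "C"
  else "BC"
}

#' Full J-index measurement of one seed against one model
#'
#' Convenience pipeline: align the model to the silhouette, compute the
#' global J, the left/right and quadrant regional values in the aligned
#' frame, and the morphotype label.
#'
#' @param s a `silhouette` or `seed_polygon`.
#' @param m a `model_shape`.
#' @param refine passed to [align_model()].
#' @param left_threshold,right_threshold passed to [classify_morphotype()].
#' @return list with `j`, `area_C`, `area_D`, `fit`, `left`, `right`,
#'   `Q1`..`Q4`, `morphotype`.
#' @export
j_index <- function(s, m, refine = TRUE,
                    left_threshold = 92, right_threshold = 80) {
  fit <- align_model(s, m, refine = refine)
  fr <- aligned_frame(s, m, fit)
  ov <- compute_j(fr$seed, fr$model, check_simple = FALSE)
  lr <- regional_j(fr$seed, fr$model, "halves_lr")
  qd <- regional_j(fr$seed, fr$model, "quadrants")
  list(j = ov$j, area_C = ov$area_C, area_D = ov$area_D, fit = fit,
       left = lr$left, right = lr$right,
       Q1 = qd$Q1, Q2 = qd$Q2, Q3 = qd$Q3, Q4 = qd$Q4,
       morphotype = classify_morphotype(lr$left, lr$right,
                                        left_threshold, right_threshold))
}
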