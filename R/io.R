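#' Measure every seed in a set of images
#'
#' Batch pipeline behind the `measure` subcommand: each image is
#' thresholded, silhouettes are extracted and measured, every shape index
#' is computed, and (when a model is requested) the model is aligned and
#' global, left/right and quadrant J values plus the morphotype are
#' recorded. One row per extracted silhouette, in deterministic order
#' (lexicographic file order, then silhouette order within the image).
#'
#' Unreadable or unsegmentable files are skipped with a logged warning;
#' the run fails only if no seed at all is found.
#'
#' @param inputs character vector of image paths, or a directory (all
#'   .png/.tif/.tiff inside are taken, sorted).
#' @param model model kind for J-index comparison (see [make_model()]),
#'   or `NULL` to skip model comparison.
#' @param pixel_size physical length of a pixel side (default 1).
#' @param threshold optional fixed binarization threshold (default: Otsu).
#' @param min_area_px minimum component area in pixels (default 50).
#' @param refine run local pose refinement (default `TRUE`; `FALSE` makes
#'   reruns byte-identical).
#' @param dark_foreground passed to [binarize()].
#' @param out optional CSV path; when given, records are written with
#'   [write_measurements()].
#' @param log function used for progress/warning lines (default
#'   [message()]).
#' @param ... extra model parameters passed to [make_model()].
#' @return invisibly, a data.frame of measurement records.
#' @export
run_measure <- function(inputs, model = "cardioid", pixel_size = 1,
                        threshold = NULL, min_area_px = 50L, refine = TRUE,
                        dark_foreground = TRUE, out = NULL,
                        log = message, ...) {
  if (length(inputs) == 1L && dir.exists(inputs))
    inputs <- list.files(inputs, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE)
  inputs <- sort(inputs)
  if (length(inputs) == 0L)
    stop("no input images found", call. = FALSE)
  mshape <- if (!is.null(model)) make_model(model, ...) else NULL
  rows <- list()
  for (f in inputs) {
    rec <- tryCatch({
      img <- read_seed_image(f)
      b <- binarize(img, threshold = threshold,
                    dark_foreground = dark_foreground,
                    pixel_size = pixel_size)
      log(sprintf("%s: threshold %.4g", basename(f), b$threshold))
      sils <- extract_silhouettes(b, min_area_px = min_area_px)
      do.call(rbind, lapply(seq_along(sils), function(i) {
        measurement_record(sils[[i]], mshape, file = basename(f),
                           seed_id = i, refine = refine)
      }))
    }, error = function(e) {
      log(sprintf("warning: skipping %s (%s)", basename(f),
                  conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) rows[[f]] <- rec
  }
  if (length(rows) == 0L)
    stop("no seeds found in any input image", call. = FALSE)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(out)) {
    write_measurements(df, out)
    log(sprintf("wrote %d records to %s", nrow(df), out))
  }
  invisible(df)
}

#' One measurement record for a silhouette
#'
#' @param s a `silhouette`.
#' @param mshape a `model_shape` or `NULL`.
#' @param file,seed_id provenance columns.
#' @param refine passed to [align_model()].
#' @return one-row data.frame.
#' @export
measurement_record <- function(s, mshape = NULL, file = "", seed_id = 1L,
                               refine = TRUE) {
  ix <- index_set(s)
  row <- data.frame(
    file = file, seed_id = seed_id, pixel_size = s$pixel_size,
    area = s$area, perimeter = s$perimeter,
    convex_perimeter = s$convex_perimeter,
    L = s$bbox_length, W = s$bbox_width,
    major_axis = s$major_axis, minor_axis = s$minor_axis,
    EI = ix$EI, AR = ix$AR, circularity = ix$circularity,
    roundness = ix$roundness, rugosity = ix$rugosity,
    stringsAsFactors = FALSE)
  if (!is.null(mshape)) {
    jj <- j_index(s, mshape, refine = refine)
    row$model <- mshape$kind
    row$J <- jj$j
    row$J_left <- jj$left; row$J_right <- jj$right
    row$Q1 <- jj$Q1; row$Q2 <- jj$Q2; row$Q3 <- jj$Q3; row$Q4 <- jj$Q4
    row$morphotype <- jj$morphotype
    row$fit_rotation <- jj$fit$rotation
    row$fit_scale <- jj$fit$scale
    row$fit_flipped <- jj$fit$flipped
  }
  row
}

#' Write / read measurement CSVs
#'
#' Numeric values are stored at 6 significant digits with a `.` decimal
#' separator regardless of locale, so a written file re-parses to exactly
#' the rounded in-memory records.
#'
#' @param df data.frame of measurement records.
#' @param path CSV destination.
#' @return `write_measurements` returns the rounded data.frame invisibly;
#'   `read_measurements` the parsed data.frame.
#' @export
write_measurements <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(df)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Index-only computation from a table of caliper measurements
#'
#' Accepts a data.frame (or CSV path) with columns `L`, `W` and optionally
#' `H`, and returns EI and (when H is present) FI per row.
#'
#' @param x data.frame or CSV path with columns `L`, `W`, optionally `H`.
#' @return data.frame with the input columns plus `EI` and optionally `FI`.
#' @export
indices_from_measurements <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  if (!all(c("L", "W") %in% names(x)))
    stop("input must have columns L and W", call. = FALSE)
  x$EI <- mapply(eccentricity_index, x$L, x$W)
  if ("H" %in% names(x))
    x$FI <- mapply(flatness_index, x$L, x$W, x$H)
  x
}

#' Write a model curve as a two-column CSV
#'
#' @param m a `model_shape`.
#' @param path destination CSV (columns `x`, `y`).
#' @export
write_model_csv <- function(m, path) {
  p <- if (inherits(m, "model_shape")) m$polygon else m
  utils::write.csv(data.frame(x = p$x, y = p$y), path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic seed image to PNG
#'
#' @param fx result of [generate_seed_image()].
#' @param path destination .png path.
#' @export
write_fixture_png <- function(fx, path) {
  png::writePNG(fx$image / 255, path)
  invisible(path)
}
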