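test_that("J is 100 for identical figures and 0 for disjoint ones", {
  card <- make_cardioid(1, 720)$polygon
  self <- compute_j(card, card)
  expect_equal(self$j, 100)
  expect_equal(self$area_D, 0)
  far <- compute_j(unit_square(), unit_square(x0 = 5))
  expect_equal(far$j, 0)
  expect_equal(far$area_C, 0)
})

test_that("half-overlapping unit squares give C=0.5, D=1.0, J=33.33", {
  ov <- compute_j(unit_square(), unit_square(x0 = 0.5))
  expect_equal(ov$area_C, 0.5, tolerance = 1e-9)
  expect_equal(ov$area_D, 1.0, tolerance = 1e-9)
  expect_equal(ov$j, 100 / 3, tolerance = 1e-6)
  # brute-force raster oracle agrees
  expect_lt(abs(raster_j_oracle(unit_square(), unit_square(x0 = 0.5), 2000) -
                100 / 3), 0.1)
})

test_that("J is symmetric and invariant under common rigid motions", {
  set.seed(31)
  a <- random_simple_polygon(18)
  b <- poly_translate(random_simple_polygon(14), 0.2, -0.1)
  ja <- compute_j(a, b); jb <- compute_j(b, a)
  expect_equal(ja$j, jb$j, tolerance = 1e-12)
  for (i in 1:5) {
    th <- stats::runif(1, 0, 2 * pi)
    dx <- stats::runif(1, -3, 3); dy <- stats::runif(1, -3, 3)
    mv <- function(p) poly_translate(poly_rotate(p, th, center = c(0, 0)),
                                     dx, dy)
    expect_lt(abs(compute_j(mv(a), mv(b))$j - ja$j), 1e-9)
  }
})

test_that("self-intersecting input is rejected", {
  bow <- structure(list(x = c(0, 2, 0, 1), y = c(0, 1, 1, 0)),
                   class = "seed_polygon")
  expect_false(poly_is_simple(bow))
  expect_error(compute_j(bow, unit_square()), "self-intersecting")
})

test_that("clipping a protrusion off the seed strictly lowers J", {
  model <- make_cardioid(1, 360)$polygon
  # seed: cardioid with a square protrusion glued onto the lobe
  prot <- polyclip::polyclip(list(list(x = model$x, y = model$y)),
                             list(list(x = c(1.8, 2.6, 2.6, 1.8),
                                       y = c(-0.2, -0.2, 0.2, 0.2))),
                             op = "union")[[1]]
  seed <- polygon_xy(prot$x, prot$y)
  j_with <- compute_j(seed, model)$j
  j_without <- compute_j(model, model)$j
  expect_lt(j_with, j_without)
  # trimming the protrusion back restores the model outline
  expect_equal(j_without, 100)
})

test_that("alignment recovers rigidly displaced exact copies (J >= 99.9)", {
  m <- make_cardioid(1, 360)
  set.seed(13)
  for (i in 1:6) {
    th <- stats::runif(1, 0, 2 * pi)
    dx <- stats::runif(1, -10, 10); dy <- stats::runif(1, -10, 10)
    sc <- stats::runif(1, 0.5, 3)
    seed <- poly_scale(poly_rotate(poly_translate(m$polygon, dx, dy), th),
                       sc)
    fit <- align_model(seed, m, refine = FALSE)
    expect_gte(fit$j, 99.9)
    placed <- apply_fit(m, fit)
    expect_lt(abs(poly_area(placed) - poly_area(seed)) / poly_area(seed),
              1e-6)
  }
})

test_that("an unmoved seed yields the identity fit", {
  m <- make_cardioid(1, 360)
  fit <- align_model(m$polygon, m, refine = FALSE)
  expect_lt(max(abs(fit$translation)), 1e-6)
  expect_lt(abs(fit$rotation), 1e-6)
  expect_false(fit$flipped)
  expect_equal(fit$scale, 1, tolerance = 1e-9)
})

test_that("mirror ambiguity is resolved for chiral model curves", {
  # a chiral model: ovoid with the top half sheared sideways
  base <- make_ovoid(1, 0.3, 256)$polygon
  base$y <- base$y + 0.15 * base$x * (base$y > 0)
  chiral <- polygon_xy(base$x, base$y)
  seed_same <- poly_rotate(poly_translate(chiral, 2, 1), 0.5)
  seed_mirror <- poly_rotate(poly_flip_y(chiral), -0.3)
  f1 <- align_model(seed_same, chiral, refine = FALSE)
  f2 <- align_model(seed_mirror, chiral, refine = FALSE)
  expect_gte(f1$j, 99.9)
  expect_gte(f2$j, 99.9)
  expect_false(f1$flipped)
  expect_true(f2$flipped)
})

test_that("regional J is symmetric for symmetric pairs and recombines", {
  # two ellipses: bilaterally symmetric about both partition axes, so the
  # left/right halves (and all quadrants) must agree
  me <- make_ellipse(2, 1, 720)
  se <- make_ellipse(1.6, 1, 720)$polygon
  fr <- with(list(fit = align_model(se, me, refine = FALSE)),
             aligned_frame(se, me, fit))
  lr <- regional_j(fr$seed, fr$model, "halves_lr")
  expect_equal(lr$left, lr$right, tolerance = 1e-6)

  # cardioid pair symmetric about the cusp (x) axis only: top/bottom
  # quadrant pairs match while left/right differ
  m <- make_cardioid(1, 720)
  seed <- elongate(m$polygon, "x", 1.05)
  fit <- align_model(seed, m, refine = FALSE)
  fr2 <- aligned_frame(seed, m, fit)
  qd <- regional_j(fr2$seed, fr2$model, "quadrants")
  expect_equal(qd$Q1, qd$Q4, tolerance = 1e-6)
  expect_equal(qd$Q2, qd$Q3, tolerance = 1e-6)
  # recombination of regional C and D reproduces the global J
  for (rj in list(lr, qd)) {
    C <- attr(rj, "C"); D <- attr(rj, "D")
    expect_equal(100 * sum(C) / (sum(C) + sum(D)), attr(rj, "global_j"),
                 tolerance = 1e-6)
  }
})

test_that("a notch on one side lowers that side's regional J only", {
  m <- make_cardioid(1, 720)
  fit0 <- align_model(m$polygon, m, refine = FALSE)
  fr0 <- aligned_frame(m$polygon, m, fit0)
  # in the aligned frame the cusp points +x; cut a notch from the right
  notch <- list(x = c(0.2, 1.5, 1.5, 0.2), y = c(-0.08, -0.08, 0.08, 0.08))
  cut <- polyclip::polyclip(list(list(x = fr0$seed$x, y = fr0$seed$y)),
                            list(notch), op = "minus")[[1]]
  seed <- polygon_xy(cut$x, cut$y)
  lr <- regional_j(seed, fr0$model, "halves_lr")
  expect_lt(lr$right, lr$left)
})

test_that("morphotype classification matches the published type table", {
  expect_identical(classify_morphotype(95, 85), "A")
  expect_identical(classify_morphotype(90, 85), "B")
  expect_identical(classify_morphotype(95, 70), "C")
  expect_identical(classify_morphotype(90, 70), "BC")
  # thresholds inclusive on the "above" side
  expect_identical(classify_morphotype(92, 80), "A")
  expect_error(classify_morphotype(101, 50), "0, 100")
  expect_error(classify_morphotype(-1, 50), "0, 100")
})

test_that("noisy stretched-cardioid silhouettes keep J above 95", {
  m <- make_model("cardioid_x_phi")
  for (seed in 1:5) {
    fx <- fixture_spec("cardioid_x_phi", radial_noise_sigma = 0.01,
                       resolution = 300, rng_seed = seed)
    truth <- generate_seed_image(fx)$ground_truth
    fit <- align_model(truth, m, refine = TRUE)
    expect_gte(fit$j, 95)
  }
})
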