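# ONH structural parameters against closed forms and dense oracles.

test_that("ellipse fit recovers exact circles and ellipses", {
  t <- seq(0, 2 * pi, length.out = 49)[-49]
  circ <- cbind(806 * cos(t), 806 * sin(t), 0)
  e <- fit_bmo_ellipse(circ)
  expect_equal(e$area_mm2, pi * 0.806^2, tolerance = 1e-9)
  expect_equal(round(equivalent_diameter(e$area_mm2), -2), 1600)

  ell <- cbind(1000 * cos(t), 500 * sin(t), 0)
  f <- fit_bmo_ellipse(ell)
  expect_equal(f$area_mm2, pi * 0.5, tolerance = 1e-9)
  expect_equal(f$a, 1000, tolerance = 1e-6)
  expect_equal(f$b, 500, tolerance = 1e-6)

  # rotated, tilted, off-centre: in-plane axes and area still exact
  phi <- 40 * pi / 180
  u <- cbind(900 * cos(t), 640 * sin(t))
  xy <- cbind(u[, 1] * cos(phi) - u[, 2] * sin(phi),
              u[, 1] * sin(phi) + u[, 2] * cos(phi))
  pts <- cbind(xy[, 1] + 120, xy[, 2] - 80, 0.08 * xy[, 1] - 50)
  g <- fit_bmo_ellipse(pts)
  # the en-face projection of the fitted in-plane ellipse has area pi*a*b
  expect_equal(g$area_mm2 * cos(atan(0.08)), pi * 0.9 * 0.64,
               tolerance = 1e-6)
  expect_equal(g$center[1:2], c(120, -80), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("noisy circle fit matches the orthogonal-residual oracle", {
  set.seed(11)
  t <- seq(0, 2 * pi, length.out = 49)[-49]
  pts <- cbind(800 * cos(t) + rnorm(48, 0, 5),
               800 * sin(t) + rnorm(48, 0, 5), 0)
  e <- fit_bmo_ellipse(pts)
  expect_lt(abs(e$a / 800 - 1), 0.02)
  expect_lt(abs(e$b / 800 - 1), 0.02)
  nls <- oracle_ellipse_nls(pts[, 1:2], start = c(0, 0, 810, 790, 0.1))
  expect_equal(e$a, nls$a, tolerance = 0.005)
  expect_equal(e$b, nls$b, tolerance = 0.005)
})

test_that("degenerate ellipse inputs error", {
  expect_error(fit_bmo_ellipse(cbind(1:5, 1:5, 0)), class = "onh_fit_error")
  line <- cbind(seq(0, 1000, length.out = 20), 2 * seq(0, 1000, length.out = 20), 0)
  expect_error(fit_bmo_ellipse(line), class = "onh_fit_error")
})

test_that("minimum rim width closed-form cases", {
  # flat ILM shelf at 350 above the BMO plane
  b <- flat_bscan(rim = 350)
  expect_equal(as.numeric(minimum_rim_width(b, "right")), 350)
  expect_equal(as.numeric(minimum_rim_width(b, "left")), 350)

  # nearest-vertex case: ILM kink at (700, 300) against BMO point (800, 0)
  bk <- flat_bscan(ilm_s = c(-800, 0, 600, 700, 800),
                   ilm_z = c(350, 350, 500, 300, 480))
  expect_equal(as.numeric(minimum_rim_width(bk, "right")),
               sqrt(100^2 + 300^2), tolerance = 1e-12)

  # ILM not covering the BMO interval -> coverage error
  short <- radial_bscan(0, 0,
                        ilm = layer_polyline(c(-100, 100), c(350, 350), "ILM"),
                        bm = layer_polyline(c(-2500, 2500), c(0, 0), "BM"),
                        bmo_left = c(-800, 0), bmo_right = c(800, 0))
  expect_error(minimum_rim_width(short, "left"), class = "onh_coverage_error")
})

test_that("minimum rim width matches the dense-resampling oracle", {
  set.seed(21)
  for (rep in 1:10) {
    amp <- runif(1, 50, 250)
    s <- seq(-900, 900, by = 12.5)
    z <- 400 - amp * cos(pi * s / 900) + 30 * sin(s / 150)
    b <- flat_bscan(ilm_s = s, ilm_z = z,
                    bmo_left = c(-800, runif(1, -50, 50)),
                    bmo_right = c(800, runif(1, -50, 50)))
    for (side in c("left", "right")) {
      p <- if (side == "left") b$bmo_left else b$bmo_right
      expect_equal(as.numeric(minimum_rim_width(b, side)),
                   oracle_min_dist(p, s, z, -800, 800), tolerance = 0.5)
    }
  }
})

test_that("ties in MRW resolve toward smaller |s|", {
  # two equidistant ILM vertices at s = 600 and 1000 from BMO point (800, 0):
  # only s in (-800, 800) is searchable, but craft equal distances inside
  b <- flat_bscan(ilm_s = c(-800, -100, 100, 800),
                  ilm_z = c(300, 300, 300, 300),
                  bmo_left = c(-800, 0), bmo_right = c(800, 0))
  w <- minimum_rim_width(b, "right")
  expect_equal(as.numeric(w), 300)
  expect_equal(unname(attr(w, "foot")["s"]), 800)  # directly above, in arc
})

test_that("global MRW is the mean of 48 point values", {
  ph <- make_phantom(phantom_spec(a = 800, b = 800, tilt_deg = 0,
                                  cup_depth = 0, rim_h = 355, noise_sd = 0,
                                  s_step_um = 25))
  g <- global_mrw(ph$set)
  expect_equal(as.numeric(g), 355, tolerance = 1e-9)
  expect_length(attr(g, "per_point"), 48)
  expect_equal(as.numeric(g), mean(attr(g, "per_point")))
})

test_that("BMO height: flat, displaced, and tilted reference lines", {
  expect_equal(unname(bmo_height(flat_bscan())), c(0, 0))
  disp <- flat_bscan(bmo_left = c(-800, -102), bmo_right = c(800, -102))
  expect_equal(unname(bmo_height(disp)), c(-102, -102))
  # BM z = 0.1 s, BMO point at (0, -100): distance -100 / sqrt(1.01)
  s <- seq(-2500, 2500, by = 100)
  tilted <- radial_bscan(0, 0,
                         ilm = layer_polyline(s, 0.1 * s + 400, "ILM"),
                         bm = layer_polyline(s, 0.1 * s, "BM"),
                         bmo_left = c(-1e-9, -100), bmo_right = c(1e-9, -100))
  expect_equal(unname(bmo_height(tilted)), rep(-100 / sqrt(1.01), 2),
               tolerance = 1e-9)
  # BM not spanning 4 mm
  narrow <- radial_bscan(0, 0,
                         ilm = layer_polyline(c(-1500, 1500), c(350, 350), "ILM"),
                         bm = layer_polyline(c(-1500, 1500), c(0, 0), "BM"),
                         bmo_left = c(-800, 0), bmo_right = c(800, 0))
  expect_error(bmo_height(narrow), class = "onh_coverage_error")
})

test_that("lamina depth: flat cases and dense-integration oracle", {
  s <- seq(-640, 640, by = 20)
  flat <- flat_bscan(alcs = layer_polyline(s, rep(-440, length(s)), "ALCS"))
  expect_equal(alcs_depth(flat), -440)

  two <- flat_bscan(alcs = layer_polyline(
    c(-300, -100, 100, 300), c(-400, -480, -400, -480), "ALCS"))
  expect_equal(alcs_depth(two), -440)

  expect_true(is.na(alcs_depth(flat_bscan())))                 # no trace
  sparse <- flat_bscan(alcs = layer_polyline(c(-790, -700),
                                             c(-400, -400), "ALCS"))
  expect_true(is.na(alcs_depth(sparse)))                       # outside window

  # slanted BMO chord + curved lamina vs numeric-integration oracle
  p1 <- c(-800, 0); p2 <- c(800, 160)
  fz <- function(sv) -430 + 40 * (sv / 800)^2 + 0.05 * sv
  sa <- seq(-700, 700, by = 12.5)
  slant <- radial_bscan(0, 0,
                        ilm = layer_polyline(c(-2500, 2500), c(400, 560), "ILM"),
                        bm = layer_polyline(c(-2500, 2500), c(-160, 320), "BM"),
                        bmo_left = p1, bmo_right = p2,
                        alcs = layer_polyline(sa, fz(sa), "ALCS"))
  expect_equal(alcs_depth(slant),
               oracle_alcsd(fz, c(-700, 700), p1, p2), tolerance = 0.5)
})

test_that("TRT map reproduces constant and linear fields", {
  ph <- make_phantom(phantom_spec(a = 800, b = 800, bmo_z = 0, tilt_deg = 0,
                                  rim_h = 300, cup_depth = 0, trt_slope = 0,
                                  noise_sd = 0, s_step_um = 25))
  m <- trt_map(ph$set)
  expect_true(all(abs(m$trt[!is.na(m$trt)] - 300) < 1e-9))

  lin <- make_phantom(phantom_spec(a = 800, b = 800, bmo_z = 0, tilt_deg = 0,
                                   rim_h = 400, cup_depth = 0,
                                   trt_slope = -0.05, noise_sd = 0,
                                   s_step_um = 25))
  ml <- trt_map(lin$set)
  outside <- ml$radius_um > 820
  want <- 400 - 0.05 * (ml$radius_um[outside] - 800)
  got <- ml$trt[1, outside]
  expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("TRT annuli: piecewise-constant map and constant-map invariance", {
  t <- seq(0, 2 * pi, length.out = 49)[-49]
  ell <- fit_bmo_ellipse(cbind(800 * cos(t), 800 * sin(t), 0))
  radius <- seq(0, 2400, by = 1)
  step_map <- structure(list(
    angle_deg = 0:359, radius_um = radius,
    trt = matrix(ifelse(radius < 1300, 400, 300), nrow = 360,
                 ncol = length(radius), byrow = TRUE)), class = "trt_map")
  ann <- trt_annuli(step_map, ell)
  expect_equal(unname(ann), c(400, 400, 300, 300), tolerance = 1e-9)

  # constant map: annuli equal the constant for any ellipse shape
  const_map <- structure(list(
    angle_deg = 0:359, radius_um = radius,
    trt = matrix(321, 360, length(radius))), class = "trt_map")
  sq <- fit_bmo_ellipse(cbind(1000 * cos(t), 600 * sin(t), 0))
  expect_equal(unname(trt_annuli(const_map, sq)), rep(321, 4))
})

test_that("TRT annuli match the quadrature oracle on elliptical phantoms", {
  ph <- make_phantom(random_phantom_spec(31))
  res <- session_morphometry(ph$set, ph$circles)
  gt <- ph$ground_truth
  expect_equal(res$trt250, gt$trt250, tolerance = 1)
  expect_equal(res$trt500, gt$trt500, tolerance = 1)
  expect_equal(res$trt1000, gt$trt1000, tolerance = 1)
  expect_equal(res$trt1500, gt$trt1500, tolerance = 1)
})

test_that("circular means: constants, sinusoids, masked arcs", {
  n <- 720
  th <- seq(0, 360 - 360 / n, length.out = n)
  mk <- function(rnfl, valid = rep(TRUE, n)) {
    circular_scan(3.5, th, ilm_z = rep(0, n), rnfl_post_z = -rnfl,
                  bm_z = rep(-300, n), choroid_sclera_z = rep(-500, n),
                  valid = valid)
  }
  expect_equal(unname(circular_means(mk(rep(119, n)))["rnflt"]), 119)

  sine <- 100 + 20 * sin(th * pi / 180)
  expect_equal(unname(circular_means(mk(sine))["rnflt"]), 100,
               tolerance = 0.01)

  mask <- rep(TRUE, n)
  mask[100:171] <- FALSE  # 10% contiguous sector
  got <- circular_means(mk(sine, mask))
  expect_equal(unname(got["rnflt"]),
               oracle_circular_mean(th, sine, mask), tolerance = 0.1)
  expect_equal(unname(got["choroidt"]), 200)
})

test_that("session morphometry populates all fields, reports gaps", {
  ph <- make_phantom(random_phantom_spec(7))
  res <- session_morphometry(ph$set, ph$circles)
  expect_s3_class(res, "morphometry_result")
  nums <- c(res$mrw_global, res$bmo_height_global, res$alcsd_global,
            res$bmo_area_mm2, res$trt250, res$trt500, res$trt1000,
            res$trt1500, res$rnflt, res$trt_circ, res$choroidt)
  expect_true(all(is.finite(nums)))
  expect_length(res$completeness, 0)
  expect_length(res$mrw_per_point, 48)
  expect_equal(res$mrw_global, mean(res$mrw_per_point))

  no_alcs <- segmented_radial_set(lapply(ph$set$bscans, function(b) {
    b$alcs <- NULL
    b
  }))
  res2 <- session_morphometry(no_alcs, ph$circles)
  expect_true(is.na(res2$alcsd_global))
  expect_true("alcsd" %in% names(res2$completeness))
  expect_false(is.na(res2$mrw_global))
})

test_that("scale equivariance: distances scale exactly with coordinates", {
  ph <- make_phantom(random_phantom_spec(13))
  b <- ph$set$bscans[[3]]
  k <- 1.7
  scaled <- radial_bscan(b$index, b$angle_deg,
                         ilm = layer_polyline(k * b$ilm$s, k * b$ilm$z, "ILM"),
                         bm = layer_polyline(k * b$bm$s, k * b$bm$z, "BM"),
                         bmo_left = k * b$bmo_left,
                         bmo_right = k * b$bmo_right,
                         alcs = layer_polyline(k * b$alcs$s, k * b$alcs$z,
                                               "ALCS"))
  expect_equal(as.numeric(minimum_rim_width(scaled, "left")),
               k * as.numeric(minimum_rim_width(b, "left")),
               tolerance = 1e-12)
  expect_equal(alcs_depth(scaled), k * alcs_depth(b), tolerance = 1e-12)
  expect_equal(unname(bmo_height(scaled, half_span_um = 2000 * k)),
               k * unname(bmo_height(b)), tolerance = 1e-12)
})

test_that("rotating the phantom by one scan step leaves globals unchanged", {
  base <- random_phantom_spec(17)
  rot <- base
  rot$orientation_deg <- base$orientation_deg + 7.5
  a <- session_morphometry(make_phantom(base)$set)
  b <- session_morphometry(make_phantom(rot)$set)
  expect_equal(a$mrw_global, b$mrw_global, tolerance = 1e-6 * a$mrw_global)
  expect_equal(a$bmo_area_mm2, b$bmo_area_mm2,
               tolerance = 1e-6 * a$bmo_area_mm2)
  expect_equal(a$trt250, b$trt250, tolerance = 0.05)
})

test_that("MRW never exceeds the axial rim thickness (minimality)", {
  ph <- make_phantom(random_phantom_spec(23))
  for (b in ph$set$bscans) {
    for (side in c("left", "right")) {
      p <- if (side == "left") b$bmo_left else b$bmo_right
      axial <- approx(b$ilm$s, b$ilm$z, p[1], ties = "ordered")$y - p[2]
      expect_lte(as.numeric(minimum_rim_width(b, side)), abs(axial) + 1e-9)
    }
  }
})

test_that("worked-example helpers do the stated arithmetic", {
  expect_equal(round(equivalent_diameter(2.04), -2), 1600)
  expect_equal(circle_eccentricity(c(2.7, 3.5, 4.2, 4.9), 1600),
               c(550, 950, 1300, 1650))
})
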