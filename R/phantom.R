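#' Analytic ONH phantoms
#'
#' A phantom is a fully analytic optic nerve head: an elliptical BMO on a
#' (possibly tilted) plane sunk below a far Bruch's membrane plane, a
#' parametric inner-limiting-membrane rim/cup, linear-in-eccentricity
#' retinal, nerve-fibre and choroid thickness profiles, and a flat or
#' quadratically bowed anterior lamina surface.  [make_phantom()] samples
#' these surfaces exactly the way the scanner samples a real eye (24 radial
#' diameters, four circles) while the ground-truth morphometry is computed
#' directly from the analytic surfaces by dense evaluation -- never through
#' the measurement pipeline -- so phantoms serve as independent oracles.
#'
#' @name phantom
NULL

#' Specify an analytic ONH phantom
#'
#' Defaults describe a healthy eye: BMO area close to 2.04 mm^2, BMO plane
#' about 102 um below the peripheral Bruch's membrane, lamina 440 um below
#' the BMO plane, rim thickness giving TRT250 near 395 um.
#'
#' @param a,b BMO ellipse semi-axes of the en-face projection (um).
#' @param orientation_deg En-face orientation of the major axis.
#' @param tilt_deg Tilt of the BMO plane about the y axis (degrees).
#' @param bmo_z Depth of the BMO plane centre below the far BM plane (um,
#'   negative = posterior).
#' @param rim_h Retinal thickness at the BMO margin, `T(0)` (um); with a
#'   flat shelf (`cup_depth = 0`, `tilt_deg = 0`) the minimum rim width
#'   equals `rim_h` exactly.
#' @param cup_depth,cup_power Depth (um) and sharpness of the inner cup
#'   below the rim shelf; 0 gives the closed-form flat-shelf case.
#' @param trt_slope Radial slope of total retinal thickness per um of
#'   eccentricity from the BMO margin.
#' @param bm_taper_um Radial distance over which BM rises from the BMO rim
#'   back to the far plane (cosine taper).
#' @param bm_slope_x Slope of the far BM plane along x (um per um).
#' @param lamina_depth Depth of the anterior lamina surface below the BMO
#'   plane (um, positive number; stored depth is negative).
#' @param lamina_curv Quadratic anterior bowing of the lamina toward the
#'   BMO centre (um at the centre).
#' @param alcs_span_frac Fraction of the BMO radius over which the lamina is
#'   traced (partial visibility).
#' @param rnfl_base,rnfl_slope Nerve-fibre-layer thickness profile
#'   `rnfl_base + rnfl_slope * eccentricity` (um).
#' @param choroid_base,choroid_slope Choroid thickness profile (um).
#' @param noise_sd Axial Gaussian segmentation noise added to every sampled
#'   coordinate (um); ground truth always uses the noise-free surfaces.
#' @param s_step_um,s_max_um Radial sampling step and half-span.
#' @param circ_n Samples per circular scan.
#' @param seed Seed for the noise stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(a = 900, b = 720, orientation_deg = 20,
                         tilt_deg = 0, bmo_z = -102, rim_h = 403,
                         cup_depth = 500, cup_power = 2,
                         trt_slope = -0.065, bm_taper_um = 1100,
                         bm_slope_x = 0, lamina_depth = 440,
                         lamina_curv = 0, alcs_span_frac = 0.8,
                         rnfl_base = 169, rnfl_slope = -0.048,
                         choroid_base = 149, choroid_slope = 0.056,
                         noise_sd = 2, s_step_um = 12.5, s_max_um = 2600,
                         circ_n = 512, seed = 1L) {
  if (!(a >= b && b > 0)) onh_stop("need a >= b > 0", "onh_schema_error")
  if (rim_h <= 0) onh_stop("rim_h must be positive", "onh_schema_error")
  if (rim_h + trt_slope * 1600 <= 0) {
    onh_stop("retinal thickness profile must stay positive over the map",
             "onh_geometry_error")
  }
  if (noise_sd < 0 || s_step_um <= 0) {
    onh_stop("invalid sampling settings", "onh_schema_error")
  }
  spec <- as.list(environment())
  structure(spec, class = "phantom_spec")
}

# --- analytic surface evaluators (vectorised over psi_deg / r) -------------

phantom_R <- function(spec, psi_deg) {
  th <- (psi_deg - spec$orientation_deg) * pi / 180
  spec$a * spec$b / sqrt((spec$b * cos(th))^2 + (spec$a * sin(th))^2)
}

# z of the BMO plane at en-face point (x, y)
phantom_bmo_plane <- function(spec, x) {
  spec$bmo_z + tan(spec$tilt_deg * pi / 180) * x
}

# BM surface outside the opening, at direction psi and radius r >= R(psi)
phantom_bm <- function(spec, psi_deg, r) {
  R <- phantom_R(spec, psi_deg)
  x <- r * cos(psi_deg * pi / 180)
  xr <- R * cos(psi_deg * pi / 180)
  zb <- phantom_bmo_plane(spec, xr)
  zfar <- spec$bm_slope_x * x
  u <- pmin(1, pmax(0, (r - R) / spec$bm_taper_um))
  w <- (1 - cos(pi * u)) / 2
  zb + (zfar - zb) * w
}

# total retinal thickness as a function of eccentricity from the BMO margin
phantom_T <- function(spec, e) spec$rim_h + spec$trt_slope * e

# ILM z along a B-scan at angle theta_deg, signed lateral s (full diameter)
phantom_ilm_bscan <- function(spec, theta_deg, s) {
  psi <- ifelse(s >= 0, theta_deg, theta_deg + 180)
  r <- abs(s)
  R <- phantom_R(spec, psi)
  z <- numeric(length(s))
  outside <- r >= R
  z[outside] <- phantom_bm(spec, psi[outside], r[outside]) +
    phantom_T(spec, r[outside] - R[outside])
  if (any(!outside)) {
    sR <- phantom_R(spec, theta_deg)
    sL <- -phantom_R(spec, theta_deg + 180)
    zR <- phantom_bmo_plane(spec, sR * cos(theta_deg * pi / 180))
    zL <- phantom_bmo_plane(spec, sL * cos(theta_deg * pi / 180))
    si <- s[!outside]
    zline <- zL + (zR - zL) * (si - sL) / (sR - sL)
    xi <- pmax(0, (si - sL) * (sR - si)) / ((sR - sL) / 2)^2
    z[!outside] <- zline + spec$rim_h -
      spec$cup_depth * xi^spec$cup_power
  }
  z
}

# BM along a B-scan: analytic outside the opening, chord bridge inside
phantom_bm_bscan <- function(spec, theta_deg, s) {
  psi <- ifelse(s >= 0, theta_deg, theta_deg + 180)
  r <- abs(s)
  R <- phantom_R(spec, psi)
  z <- numeric(length(s))
  outside <- r >= R
  z[outside] <- phantom_bm(spec, psi[outside], r[outside])
  if (any(!outside)) {
    sR <- phantom_R(spec, theta_deg)
    sL <- -phantom_R(spec, theta_deg + 180)
    zR <- phantom_bmo_plane(spec, sR * cos(theta_deg * pi / 180))
    zL <- phantom_bmo_plane(spec, sL * cos(theta_deg * pi / 180))
    si <- s[!outside]
    z[!outside] <- zL + (zR - zL) * (si - sL) / (sR - sL)
  }
  z
}

phantom_alcs_bscan <- function(spec, theta_deg, s) {
  psi <- ifelse(s >= 0, theta_deg, theta_deg + 180)
  r <- abs(s)
  R <- phantom_R(spec, psi)
  x <- s * cos(theta_deg * pi / 180)
  phantom_bmo_plane(spec, x) - spec$lamina_depth +
    spec$lamina_curv * (1 - (r / R)^2)
}

# --- ground truth by dense evaluation --------------------------------------

phantom_ground_truth <- function(spec, ds = 0.1, dpsi = 0.25) {
  angles <- RADIAL_STEP_DEG * (0:23)
  tiltrad <- spec$tilt_deg * pi / 180

  mrw <- matrix(NA_real_, 2, 24)
  bh <- matrix(NA_real_, 2, 24)
  alcsd <- numeric(24)
  for (i in seq_along(angles)) {
    th <- angles[i]
    sR <- phantom_R(spec, th)
    sL <- -phantom_R(spec, th + 180)
    zR <- phantom_bmo_plane(spec, sR * cos(th * pi / 180))
    zL <- phantom_bmo_plane(spec, sL * cos(th * pi / 180))
    sg <- seq(sL, sR, by = ds)
    zg <- phantom_ilm_bscan(spec, th, sg)
    mrw[1, i] <- sqrt(min((sg - sL)^2 + (zg - zL)^2))
    mrw[2, i] <- sqrt(min((sg - sR)^2 + (zg - zR)^2))
    # 4-mm BM chord, analytic endpoints
    z2 <- phantom_bm_bscan(spec, th, c(-2000, 2000))
    mslope <- (z2[2] - z2[1]) / 4000
    c0 <- z2[1] + mslope * 2000
    bh[1, i] <- (zL - (mslope * sL + c0)) / sqrt(1 + mslope^2)
    bh[2, i] <- (zR - (mslope * sR + c0)) / sqrt(1 + mslope^2)
    # lamina: dense perpendicular distances to the BMO chord, central 50%
    span <- c(sL * spec$alcs_span_frac, sR * spec$alcs_span_frac)
    sa <- seq(span[1], span[2], by = ds * 5)
    za <- phantom_alcs_bscan(spec, th, sa)
    L <- sqrt((sR - sL)^2 + (zR - zL)^2)
    u <- c(sR - sL, zR - zL) / L
    nrm <- c(-u[2], u[1]); if (nrm[2] < 0) nrm <- -nrm
    frac <- ((sa - sL) * u[1] + (za - zL) * u[2]) / L
    keep <- frac >= 0.25 & frac <= 0.75
    alcsd[i] <- mean((sa[keep] - sL) * nrm[1] + (za[keep] - zL) * nrm[2])
  }

  # annuli: 2-D quadrature on the analytic thickness field
  psi <- seq(0, 360 - dpsi, by = dpsi)
  Rpsi <- phantom_R(spec, psi)
  edges <- c(0, 250, 500, 1000, 1500)
  ann <- numeric(4)
  de <- 1
  for (k in 1:4) {
    e <- seq(edges[k] + de / 2, edges[k + 1] - de / 2, by = de)
    w <- outer(Rpsi, e, `+`)
    tval <- matrix(phantom_T(spec, e), nrow = length(psi),
                   ncol = length(e), byrow = TRUE)
    ann[k] <- sum(w * tval) / sum(w)
  }

  # circular means by angular quadrature
  circ <- sapply(CIRCLE_DIAMETERS_MM, function(d) {
    rc <- d * 500
    e <- rc - Rpsi
    c(rnflt = mean(spec$rnfl_base + spec$rnfl_slope * e),
      trt = mean(phantom_T(spec, e)),
      choroidt = mean(spec$choroid_base + spec$choroid_slope * e))
  })
  colnames(circ) <- sprintf("%.1f", CIRCLE_DIAMETERS_MM)

  list(mrw_global = mean(mrw), mrw_per_point = as.vector(mrw[c(1, 2), ]),
       bmo_height_global = mean(bh),
       alcsd_global = mean(alcsd),
       bmo_area_mm2 = pi * spec$a * spec$b / (1e6 * cos(tiltrad)),
       trt250 = ann[1], trt500 = ann[2], trt1000 = ann[3], trt1500 = ann[4],
       rnflt = circ["rnflt", ], trt_circ = circ["trt", ],
       choroidt = circ["choroidt", ])
}

#' Build a sampled phantom with ground truth
#'
#' Samples the analytic surfaces of `spec` along 24 radial diameters (7.5
#' degree spacing) and the four standard circles, optionally adding axial
#' Gaussian segmentation noise, and returns the sampled scan set together
#' with ground-truth morphometry computed by dense evaluation of the
#' noise-free surfaces (0.1 um lateral resampling; quadrature for annuli and
#' circular means).
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `set` ([segmented_radial_set()]), `circles`
#'   (list of four [circular_scan()]s), `ground_truth` (named list mirroring
#'   the `morphometry_result` fields), and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  noise <- function(n) if (spec$noise_sd > 0) {
    stats::rnorm(n, 0, spec$noise_sd)
  } else {
    numeric(n)
  }
  s <- seq(-spec$s_max_um, spec$s_max_um, by = spec$s_step_um)
  bscans <- vector("list", 24)
  for (i in 0:23) {
    th <- RADIAL_STEP_DEG * i
    sR <- phantom_R(spec, th)
    sL <- -phantom_R(spec, th + 180)
    zR <- phantom_bmo_plane(spec, sR * cos(th * pi / 180))
    zL <- phantom_bmo_plane(spec, sL * cos(th * pi / 180))
    z_ilm <- phantom_ilm_bscan(spec, th, s) + noise(length(s))
    z_bm <- phantom_bm_bscan(spec, th, s) + noise(length(s))
    if (any(z_ilm <= z_bm & abs(s) > max(abs(sL), sR))) {
      onh_stop("non-physical phantom: ILM at or below BM on the rim",
               "onh_geometry_error")
    }
    span <- c(sL, sR) * spec$alcs_span_frac
    sa <- s[s >= span[1] & s <= span[2]]
    alcs <- if (length(sa) >= 3) {
      layer_polyline(sa, phantom_alcs_bscan(spec, th, sa) + noise(length(sa)),
                     "ALCS")
    }
    bscans[[i + 1L]] <- radial_bscan(
      index = i, angle_deg = th,
      ilm = layer_polyline(s, z_ilm, "ILM"),
      bm = layer_polyline(s, z_bm, "BM"),
      alcs = alcs,
      bmo_left = c(sL, zL + noise(1)),
      bmo_right = c(sR, zR + noise(1)))
  }
  set <- segmented_radial_set(bscans)

  theta <- seq(0, 360 - 360 / spec$circ_n, length.out = spec$circ_n)
  circles <- lapply(CIRCLE_DIAMETERS_MM, function(d) {
    rc <- d * 500
    R <- phantom_R(spec, theta)
    e <- rc - R
    zb <- phantom_bm(spec, theta, rep(rc, length(theta)))
    zi <- zb + phantom_T(spec, e)
    circular_scan(d, theta,
                  ilm_z = zi + noise(length(theta)),
                  rnfl_post_z = zi - (spec$rnfl_base + spec$rnfl_slope * e) +
                    noise(length(theta)),
                  bm_z = zb + noise(length(theta)),
                  choroid_sclera_z = zb -
                    (spec$choroid_base + spec$choroid_slope * e) +
                    noise(length(theta)))
  })
  list(set = set, circles = circles,
       ground_truth = phantom_ground_truth(spec), spec = spec)
}
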