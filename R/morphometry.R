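#' Optic nerve head morphometry
#'
#' Structural parameters of the optic nerve head (ONH) computed from
#' segmented radial and circular OCT scans: best-fit Bruch's membrane
#' opening (BMO) ellipse and area, minimum rim width (BMO-MRW), BMO height
#' relative to a 4-mm Bruch's membrane reference chord, anterior lamina
#' cribrosa surface depth (BMO-ALCSD), a polar total-retinal-thickness (TRT)
#' map with annular means, and circumpapillary layer thickness means.
#' All distances are Euclidean in the B-scan plane and in micrometres;
#' anterior displacement is positive.
#'
#' @name morphometry
NULL

# ---------------------------------------------------------------------------
# BMO ellipse

#' Fit the best-fit ellipse to BMO points
#'
#' Fits a least-squares plane through the 3-D BMO points, projects the points
#' into that plane, and runs a direct least-squares conic fit constrained to
#' an ellipse (Fitzgibbon's method in the numerically stable Halir-Flusser
#' form).  BMO area is `pi * a * b` of the in-plane semi-axes.
#'
#' @param points An `n x 3` matrix of BMO points (um), `n >= 6`,
#'   non-collinear; a radial set contributes 48 (2 per B-scan).
#' @return An object of class `bmo_ellipse` with fields `center` (3-D um),
#'   `normal`, `a`, `b` (semi-major/minor, um), `orientation_deg` (in-plane),
#'   `area_mm2`, and the in-plane basis `e1`, `e2`.
#' @export
fit_bmo_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6L || ncol(points) != 3L) {
    onh_stop("need >= 6 three-dimensional points", "onh_fit_error")
  }
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    onh_stop("BMO points are collinear: degenerate ellipse fit",
             "onh_fit_error")
  }
  normal <- sv$v[, 3]
  if (normal[3] < 0) normal <- -normal
  # deterministic in-plane basis: projection of the global x-axis
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * normal) * normal
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  uv <- X %*% cbind(e1, e2)

  scale <- mean(sqrt(rowSums(uv^2)))
  if (scale <= 0) onh_stop("degenerate point cloud", "onh_fit_error")
  u <- uv[, 1] / scale; v <- uv[, 2] / scale

  # Halir & Flusser partitioned direct ellipse fit
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) -
    Re(ev$vectors[2, ])^2
  k <- which(cond > 0)
  if (!length(k)) onh_stop("conic fit is not an ellipse", "onh_fit_error")
  a1 <- Re(ev$vectors[, k[1]])
  coef <- c(a1, Tm %*% a1)  # A B C D E F in scaled frame

  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) onh_stop("conic fit is not an ellipse", "onh_fit_error")
  u0 <- (2 * C * D - B * E) / den
  v0 <- (B * D - 2 * A * E) / den
  mu <- A * u0^2 + B * u0 * v0 + C * v0^2 + D * u0 + E * v0 + Fc
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  eq <- eigen(Q, symmetric = TRUE)
  ax2 <- -mu / eq$values
  if (any(ax2 <= 0)) onh_stop("conic fit is not an ellipse", "onh_fit_error")
  semi <- sqrt(ax2)                      # paired with eq$vectors columns
  major <- which.max(semi)
  a_ <- semi[major] * scale
  b_ <- semi[-major][1] * scale
  vmaj <- eq$vectors[, major]
  orient <- atan2(vmaj[2], vmaj[1])
  if (orient < 0) orient <- orient + pi   # canonical [0, pi)

  center <- ctr + (u0 * scale) * e1 + (v0 * scale) * e2
  structure(list(center = center, normal = normal,
                 a = a_, b = b_, orientation_deg = orient * 180 / pi,
                 area_mm2 = pi * a_ * b_ / 1e6, e1 = e1, e2 = e2),
            class = "bmo_ellipse")
}

#' @export
print.bmo_ellipse <- function(x, ...) {
  cat(sprintf("<bmo_ellipse> a = %.1f um, b = %.1f um, area = %.3f mm2\n",
              x$a, x$b, x$area_mm2))
  invisible(x)
}

#' Radius of the BMO boundary projected to the en-face plane
#'
#' Distance from the projected ellipse centre to the projected boundary along
#' the en-face direction `psi_deg` (degrees).  Used to anchor eccentricity
#' ("distance from the BMO margin") for the TRT annuli.
#'
#' @param ellipse A `bmo_ellipse`.
#' @param psi_deg Direction(s) in degrees in the x-y plane.
#' @return Radii in um.
#' @export
bmo_boundary_radius <- function(ellipse, psi_deg) {
  phi <- ellipse$orientation_deg * pi / 180
  amaj <- ellipse$a * (cos(phi) * ellipse$e1 + sin(phi) * ellipse$e2)
  bmin <- ellipse$b * (-sin(phi) * ellipse$e1 + cos(phi) * ellipse$e2)
  A2 <- cbind(amaj[1:2], bmin[1:2])     # en-face image of the unit circle
  Ainv <- solve(A2)
  psi <- psi_deg * pi / 180
  d <- rbind(cos(psi), sin(psi))
  w <- Ainv %*% d
  1 / sqrt(colSums(w^2))
}

#' Equivalent circular diameter of an area
#'
#' @param area_mm2 Area in mm squared.
#' @return Diameter in um of the circle with that area.
#' @export
equivalent_diameter <- function(area_mm2) 2 * sqrt(area_mm2 * 1e6 / pi)

#' Eccentricity of a circular scan from the BMO margin
#'
#' @param diameter_mm Circular scan diameter (mm).
#' @param bmo_diameter_um Equivalent BMO diameter (um).
#' @return Distance in um from the BMO margin to the scan circle.
#' @export
circle_eccentricity <- function(diameter_mm, bmo_diameter_um) {
  (diameter_mm * 1000 - bmo_diameter_um) / 2
}

# ---------------------------------------------------------------------------
# Minimum rim width

clip_polyline <- function(poly, s_lo, s_hi, what) {
  s <- poly$s; z <- poly$z
  if (s_lo < s[1] - 1e-9 || s_hi > s[length(s)] + 1e-9) {
    onh_stop(sprintf("%s does not cover the BMO interval [%g, %g]",
                     what, s_lo, s_hi), "onh_coverage_error")
  }
  keep <- s > s_lo & s < s_hi
  zs <- interp_strict(s, z, c(s_lo, s_hi), what)
  list(s = c(s_lo, s[keep], s_hi), z = c(zs[1], z[keep], zs[2]))
}

#' Minimum rim width at one BMO point
#'
#' Euclidean distance in the B-scan plane from the marked BMO point to the
#' nearest point of the (linearly interpolated) internal limiting membrane,
#' searching only the ILM arc whose lateral coordinate lies between the two
#' BMO points of that B-scan.  Equidistant minima resolve toward the foot
#' point with smaller `|s|`.
#'
#' @param bscan A [radial_bscan()].
#' @param side `"left"` or `"right"` BMO point.
#' @return Minimum rim width in um, with attribute `foot` giving the
#'   nearest ILM point `(s, z)`.
#' @export
minimum_rim_width <- function(bscan, side = c("left", "right")) {
  side <- match.arg(side)
  p <- if (side == "left") bscan$bmo_left else bscan$bmo_right
  arc <- clip_polyline(bscan$ilm, bscan$bmo_left[1], bscan$bmo_right[1],
                       "ILM")
  hit <- point_segment_dist(p, arc$s, arc$z)
  dmin <- min(hit$dist)
  cand <- which(hit$dist <= dmin + 1e-9)
  best <- cand[which.min(abs(hit$foot_s[cand]))]
  structure(hit$dist[best], foot = c(s = hit$foot_s[best],
                                     z = hit$foot_z[best]))
}

#' Global minimum rim width
#'
#' Arithmetic mean of the 48 point-wise minimum rim widths (2 per B-scan).
#'
#' @param set A [segmented_radial_set()].
#' @return Global BMO-MRW in um, with attribute `per_point` (48 values,
#'   ordered left then right within each B-scan index).
#' @export
global_mrw <- function(set) {
  per <- unlist(lapply(set$bscans, function(b) {
    tryCatch(c(as.numeric(minimum_rim_width(b, "left")),
               as.numeric(minimum_rim_width(b, "right"))),
             onh_error = function(e) {
               onh_stop(sprintf("B-scan %d: %s", b$index,
                                conditionMessage(e)),
                        class(e)[1])
             })
  }))
  structure(mean(per), per_point = per)
}

# ---------------------------------------------------------------------------
# BMO height and lamina depth

#' BMO height of one B-scan
#'
#' Signed perpendicular distance of each BMO point from the 4-mm Bruch's
#' membrane reference chord of that B-scan (BM interpolated at s = -2000 and
#' +2000 um); anterior displacement is positive.
#'
#' @param bscan A [radial_bscan()].
#' @param half_span_um Half-length of the reference chord (default 2000 um).
#' @return Named numeric `c(left, right)` in um.
#' @export
bmo_height <- function(bscan, half_span_um = 2000) {
  ref_z <- interp_strict(bscan$bm$s, bscan$bm$z,
                         c(-half_span_um, half_span_um), "BM")
  m <- (ref_z[2] - ref_z[1]) / (2 * half_span_um)
  c0 <- ref_z[1] + m * half_span_um
  h <- function(p) (p[2] - (m * p[1] + c0)) / sqrt(1 + m^2)
  c(left = h(bscan$bmo_left), right = h(bscan$bmo_right))
}

#' Global BMO height
#'
#' Mean of the 48 point-wise BMO heights.
#'
#' @inheritParams global_mrw
#' @return Global BMO height in um, attribute `per_point` (48 values).
#' @export
global_bmo_height <- function(set) {
  per <- unlist(lapply(set$bscans, bmo_height))
  structure(mean(per), per_point = per)
}

#' Anterior lamina cribrosa surface depth of one B-scan
#'
#' Mean signed perpendicular distance from the traced anterior lamina
#' cribrosa surface to the line joining the two BMO points, using only
#' samples whose perpendicular foot falls within the central 50% of the BMO
#' segment (25%-75% of its length).  Posterior displacement is negative.
#'
#' @param bscan A [radial_bscan()].
#' @return Depth in um, or `NA` when the ALCS is absent or fewer than 3
#'   samples fall inside the central window (missing value, not an error).
#' @export
alcs_depth <- function(bscan) {
  if (is.null(bscan$alcs)) return(NA_real_)
  p1 <- bscan$bmo_left; p2 <- bscan$bmo_right
  L <- sqrt(sum((p2 - p1)^2))
  u <- (p2 - p1) / L
  nrm <- c(-u[2], u[1])
  if (nrm[2] < 0) nrm <- -nrm            # anterior-positive sign
  qs <- bscan$alcs$s - p1[1]
  qz <- bscan$alcs$z - p1[2]
  frac <- (qs * u[1] + qz * u[2]) / L
  keep <- frac >= 0.25 & frac <= 0.75
  if (sum(keep) < 3L) return(NA_real_)
  mean(qs[keep] * nrm[1] + qz[keep] * nrm[2])
}

#' Global anterior lamina cribrosa surface depth
#'
#' Mean over B-scans with a valid per-scan value.
#'
#' @inheritParams global_mrw
#' @return BMO-ALCSD in um (`NA` if no B-scan yields a value), attribute
#'   `n_bscans` giving the number contributing.
#' @export
global_alcsd <- function(set) {
  per <- vapply(set$bscans, alcs_depth, numeric(1))
  ok <- !is.na(per)
  structure(if (any(ok)) mean(per[ok]) else NA_real_, n_bscans = sum(ok))
}

# ---------------------------------------------------------------------------
# Total retinal thickness map and annuli

#' Polar total retinal thickness map
#'
#' Builds a polar-grid map of total retinal thickness (axial ILM - BM
#' distance) around the scan centre.  Thickness is sampled along the 48
#' radial half-lines of the set, linearly interpolated in radius on each
#' half-line and circumferentially (period 360 degrees) between adjacent
#' half-line angles.
#'
#' @param set A [segmented_radial_set()].
#' @param angle_step_deg Angular grid step (default 1 degree).
#' @param radius_step_um Radial grid step (default 10 um).
#' @param r_max_um Outer radius of the map; defaults to the largest radius
#'   covered by any half-line.
#' @return Object of class `trt_map`: `angle_deg`, `radius_um`, and matrix
#'   `trt` (angles x radii, um; `NA` where coverage is missing).
#' @export
trt_map <- function(set, angle_step_deg = 1, radius_step_um = 10,
                    r_max_um = NULL) {
  half <- list()
  for (b in set$bscans) {
    for (sgn in c(1, -1)) {
      ang <- (b$angle_deg + if (sgn > 0) 0 else 180) %% 360
      sel_i <- if (sgn > 0) b$ilm$s >= 0 else b$ilm$s <= 0
      sel_b <- if (sgn > 0) b$bm$s >= 0 else b$bm$s <= 0
      half[[length(half) + 1L]] <- list(
        angle = ang,
        r_ilm = abs(b$ilm$s[sel_i]), z_ilm = b$ilm$z[sel_i],
        r_bm = abs(b$bm$s[sel_b]), z_bm = b$bm$z[sel_b])
    }
  }
  ord <- order(vapply(half, `[[`, numeric(1), "angle"))
  half <- half[ord]
  hangles <- vapply(half, `[[`, numeric(1), "angle")
  if (is.null(r_max_um)) {
    r_max_um <- max(vapply(half, function(h)
      min(max(h$r_ilm), max(h$r_bm)), numeric(1)))
  }
  radius <- seq(0, r_max_um, by = radius_step_um)
  prof <- vapply(half, function(h) {
    o_i <- order(h$r_ilm); o_b <- order(h$r_bm)
    zi <- stats::approx(h$r_ilm[o_i], h$z_ilm[o_i], radius, rule = 1,
                        ties = "ordered")$y
    zb <- stats::approx(h$r_bm[o_b], h$z_bm[o_b], radius, rule = 1,
                        ties = "ordered")$y
    zi - zb
  }, numeric(length(radius)))                    # radii x 48
  angle <- seq(0, 360 - angle_step_deg, by = angle_step_deg)
  nh <- length(hangles)
  trt <- matrix(NA_real_, length(angle), length(radius))
  for (gi in seq_along(angle)) {
    g <- angle[gi]
    hi <- findInterval(g, hangles)
    if (hi == 0L) hi <- nh
    lo <- hi; up <- if (hi == nh) 1L else hi + 1L
    a_lo <- hangles[lo]
    a_up <- hangles[up] + if (up == 1L) 360 else 0
    gg <- g + if (g < a_lo) 360 else 0
    w <- if (a_up > a_lo) (gg - a_lo) / (a_up - a_lo) else 0
    trt[gi, ] <- (1 - w) * prof[, lo] + w * prof[, up]
  }
  structure(list(angle_deg = angle, radius_um = radius, trt = trt),
            class = "trt_map")
}

# bilinear lookup on the polar map; NA outside radial coverage
map_lookup <- function(map, theta_deg, r_um) {
  ang <- map$angle_deg; rad <- map$radius_um
  astep <- ang[2] - ang[1]; rstep <- rad[2] - rad[1]
  th <- theta_deg %% 360
  ai <- floor(th / astep)
  aw <- th / astep - ai
  a0 <- (ai %% length(ang)) + 1L
  a1 <- ((ai + 1L) %% length(ang)) + 1L
  ri <- floor(r_um / rstep)
  rw <- r_um / rstep - ri
  out <- rep(NA_real_, length(th))
  ok <- ri >= 0 & ri + 2L <= length(rad) & is.finite(r_um)
  i0 <- ri[ok] + 1L
  v00 <- map$trt[cbind(a0[ok], i0)]
  v01 <- map$trt[cbind(a0[ok], i0 + 1L)]
  v10 <- map$trt[cbind(a1[ok], i0)]
  v11 <- map$trt[cbind(a1[ok], i0 + 1L)]
  out[ok] <- (1 - aw[ok]) * ((1 - rw[ok]) * v00 + rw[ok] * v01) +
    aw[ok] * ((1 - rw[ok]) * v10 + rw[ok] * v11)
  out
}

#' Annular means of the TRT map
#'
#' Area-weighted mean total retinal thickness in four annuli of
#' eccentricity -- radial distance beyond the BMO ellipse boundary along
#' rays from the ellipse centre -- covering 0-250, 250-500, 500-1000 and
#' 1000-1500 um from the BMO margin.
#'
#' @param map A [trt_map()].
#' @param ellipse A `bmo_ellipse` from [fit_bmo_ellipse()].
#' @param ecc_step_um Eccentricity sampling step (default 5 um).
#' @return Named numeric `c(trt250, trt500, trt1000, trt1500)` in um.  An
#'   annulus with more than 25% of its area unmapped is `NA` with a warning.
#' @export
trt_annuli <- function(map, ellipse, ecc_step_um = 5) {
  edges <- c(0, 250, 500, 1000, 1500)
  psi <- map$angle_deg
  Re_ <- bmo_boundary_radius(ellipse, psi)
  cx <- ellipse$center[1]; cy <- ellipse$center[2]
  out <- numeric(4)
  names(out) <- c("trt250", "trt500", "trt1000", "trt1500")
  for (k in 1:4) {
    e_mid <- seq(edges[k] + ecc_step_um / 2, edges[k + 1] - ecc_step_um / 2,
                 by = ecc_step_um)
    rr <- outer(Re_, e_mid, `+`)               # |psi| x |e|
    px <- cx + cos(psi * pi / 180) * rr
    py <- cy + sin(psi * pi / 180) * rr
    rad <- sqrt(px^2 + py^2)
    th <- atan2(py, px) * 180 / pi
    val <- map_lookup(map, as.vector(th), as.vector(rad))
    w <- as.vector(rr)                          # polar area element ~ r
    ok <- !is.na(val)
    if (sum(w[!ok]) / sum(w) > 0.25) {
      warning(sprintf("annulus %s: >25%% of area unmapped", names(out)[k]))
      out[k] <- NA_real_
    } else {
      out[k] <- sum(w[ok] * val[ok]) / sum(w[ok])
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Circular scans

#' Mean circumpapillary thicknesses of a circular scan
#'
#' Per-sample axial thicknesses (RNFLT = ILM - RNFL posterior boundary,
#' TRT = ILM - BM, choroid = BM - choroid/sclera interface) averaged over
#' valid samples with trapezoidal angular-gap weighting; masked samples
#' contribute neither value nor weight.
#'
#' @param scan A [circular_scan()].
#' @return Named numeric `c(rnflt, trt, choroidt)` in um.
#' @export
circular_means <- function(scan) {
  w <- angular_weights(scan$theta, scan$valid)
  wsum <- sum(w)
  if (wsum <= 0) onh_stop("no contiguous valid samples", "onh_quality_error")
  avg <- function(x) sum(w * ifelse(scan$valid, x, 0)) / wsum
  c(rnflt = avg(scan$ilm_z - scan$rnfl_post_z),
    trt = avg(scan$ilm_z - scan$bm_z),
    choroidt = avg(scan$bm_z - scan$choroid_sclera_z))
}

# ---------------------------------------------------------------------------
# Session aggregate

#' Full morphometry of one imaging session
#'
#' Runs every structural parameter on a radial set plus its four circular
#' scans, recording per-field failures rather than aborting.
#'
#' @param set A [segmented_radial_set()].
#' @param circles List of [circular_scan()]s (one per diameter 2.7, 3.5,
#'   4.2, 4.9 mm; missing diameters yield `NA` fields).
#' @param map_angle_step_deg,map_radius_step_um TRT map grid settings.
#' @return An object of class `morphometry_result`: `mrw_global`,
#'   `mrw_per_point`, `bmo_height_global`, `alcsd_global`, `bmo_area_mm2`,
#'   `ellipse`, `trt250`..`trt1500`, `rnflt`, `trt_circ`, `choroidt` (each a
#'   4-vector named by diameter) and a `completeness` report.
#' @export
session_morphometry <- function(set, circles = list(),
                                map_angle_step_deg = 1,
                                map_radius_step_um = 10) {
  comp <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      comp[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  mrw <- grab("mrw", global_mrw(set))
  bh <- grab("bmo_height", global_bmo_height(set))
  al <- global_alcsd(set)
  if (is.na(al)) comp[["alcsd"]] <- "no B-scan with usable ALCS trace"
  ell <- grab("bmo_ellipse", fit_bmo_ellipse(to_3d(set)$bmo))
  annuli <- rep(NA_real_, 4)
  names(annuli) <- c("trt250", "trt500", "trt1000", "trt1500")
  if (!is.null(ell)) {
    ann <- grab("trt_annuli", {
      m <- trt_map(set, map_angle_step_deg, map_radius_step_um)
      trt_annuli(m, ell)
    })
    if (!is.null(ann)) annuli <- ann
  }
  dia <- CIRCLE_DIAMETERS_MM
  circ <- matrix(NA_real_, 3, 4,
                 dimnames = list(c("rnflt", "trt", "choroidt"),
                                 sprintf("%.1f", dia)))
  for (sc in circles) {
    j <- which(abs(dia - sc$diameter_mm) < 1e-9)
    cm <- grab(sprintf("circle_%.1f", sc$diameter_mm), circular_means(sc))
    if (!is.null(cm)) circ[, j] <- cm
  }
  structure(list(
    mrw_global = if (is.null(mrw)) NA_real_ else as.numeric(mrw),
    mrw_per_point = if (is.null(mrw)) NULL else attr(mrw, "per_point"),
    bmo_height_global = if (is.null(bh)) NA_real_ else as.numeric(bh),
    bmo_height_per_point = if (is.null(bh)) NULL else attr(bh, "per_point"),
    alcsd_global = as.numeric(al),
    alcsd_n_bscans = attr(al, "n_bscans"),
    bmo_area_mm2 = if (is.null(ell)) NA_real_ else ell$area_mm2,
    ellipse = ell,
    trt250 = annuli[["trt250"]], trt500 = annuli[["trt500"]],
    trt1000 = annuli[["trt1000"]], trt1500 = annuli[["trt1500"]],
    rnflt = circ["rnflt", ], trt_circ = circ["trt", ],
    choroidt = circ["choroidt", ],
    completeness = comp), class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  cat(sprintf("  BMO-MRW  %8.2f um   BMO height %8.2f um\n",
              x$mrw_global, x$bmo_height_global))
  cat(sprintf("  ALCSD    %8.2f um   BMO area   %8.3f mm2\n",
              x$alcsd_global, x$bmo_area_mm2))
  cat(sprintf("  TRT annuli (250/500/1000/1500): %.1f / %.1f / %.1f / %.1f um\n",
              x$trt250, x$trt500, x$trt1000, x$trt1500))
  if (length(x$completeness)) {
    cat("  incomplete fields:", paste(names(x$completeness), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Serialise a morphometry result to JSON
#'
#' @param result A `morphometry_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morphometry_result <- function(result, path) {
  out <- result[setdiff(names(result), "ellipse")]
  if (!is.null(result$ellipse)) {
    out$ellipse <- result$ellipse[c("center", "a", "b", "orientation_deg",
                                    "area_mm2")]
  }
  out$completeness <- as.list(result$completeness)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
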