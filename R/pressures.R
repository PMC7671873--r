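#' Pressures and optic nerve sheath diameter
#'
#' Intraocular pressure (IOP) as the mean of rebound-tonometry triplets,
#' mean arterial pressure MAP = (2 DBP + SBP) / 3, mean ocular perfusion
#' pressure with a hydrostatic correction of 0.77 mmHg per cm of vertical
#' cuff-to-eye distance, and optic nerve sheath diameter (ONSD) measured
#' 3 mm behind the globe on an ultrasound trace.
#'
#' Sign convention: `cuff_eye_cm` is positive when the eye is above the
#' brachial cuff (seated) and negative when below it (head-down tilt), so
#' tilt raises MOPP even when MAP falls.
#'
#' @name pressures
NULL

HYDROSTATIC_MMHG_PER_CM <- 0.77

#' Mean intraocular pressure
#'
#' @param readings Tonometry readings in mmHg; the standard protocol takes
#'   exactly three.
#' @param allow_fewer Accept 1-2 readings with a warning instead of erroring.
#' @return Mean IOP in mmHg.
#' @export
mean_iop <- function(readings, allow_fewer = FALSE) {
  readings <- as.double(readings)
  if (!length(readings) || any(!is.finite(readings))) {
    onh_stop("need at least one finite IOP reading", "onh_schema_error")
  }
  if (length(readings) != 3L) {
    if (!allow_fewer || length(readings) > 3L) {
      onh_stop("expected exactly 3 IOP readings", "onh_schema_error")
    }
    warning(sprintf("averaging %d IOP reading(s) instead of 3",
                    length(readings)))
  }
  mean(readings)
}

#' Mean arterial pressure
#'
#' `MAP = (2 * DBP + SBP) / 3`.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg; requires
#'   `0 < dbp < sbp`.
#' @return MAP in mmHg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (!all(is.finite(c(sbp, dbp))) || any(dbp <= 0) || any(dbp >= sbp)) {
    onh_stop("require 0 < dbp < sbp", "onh_schema_error")
  }
  (2 * dbp + sbp) / 3
}

#' Mean ocular perfusion pressure
#'
#' `MOPP = (MAP - 0.77 mmHg/cm * cuff_eye_cm) - IOP`.
#'
#' @param map MAP in mmHg.
#' @param cuff_eye_cm Signed vertical cuff-to-eye distance in cm (positive =
#'   eye above cuff).
#' @param iop IOP in mmHg.
#' @return MOPP in mmHg.
#' @export
mopp <- function(map, cuff_eye_cm, iop) {
  if (!all(is.finite(c(map, cuff_eye_cm, iop)))) {
    onh_stop("mopp inputs must be finite", "onh_schema_error")
  }
  map - HYDROSTATIC_MMHG_PER_CM * cuff_eye_cm - iop
}

#' Assemble a validated pressure record
#'
#' @param iop_readings Tonometry readings (mmHg).
#' @param sbp,dbp Brachial pressures (mmHg).
#' @param cuff_eye_cm Signed vertical cuff-to-eye distance (cm).
#' @param posture `"SEATED"`, `"HDT"` or `"LLD"`.
#' @return An object of class `pressure_record` with derived `iop_mean`,
#'   `map`, `mopp`.
#' @export
pressure_record <- function(iop_readings, sbp, dbp, cuff_eye_cm,
                            posture = "SEATED") {
  if (!posture %in% c("SEATED", "HDT", "LLD")) {
    onh_stop("posture must be SEATED, HDT or LLD", "onh_schema_error")
  }
  iop <- mean_iop(iop_readings)
  map_ <- mean_arterial_pressure(sbp, dbp)
  structure(list(iop_readings = as.double(iop_readings), iop_mean = iop,
                 sbp = sbp, dbp = dbp, map = map_,
                 cuff_eye_cm = cuff_eye_cm,
                 mopp = mopp(map_, cuff_eye_cm, iop),
                 posture = posture),
            class = "pressure_record")
}

# ---------------------------------------------------------------------------
# ONSD

polyline_arclength <- function(xy) {
  c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
}

# intersections of the infinite line p + t*d with a polyline; returns points
line_polyline_intersections <- function(p, d, xy) {
  n <- nrow(xy)
  a <- xy[-n, , drop = FALSE]
  b <- xy[-1, , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ez <- b[, 2] - a[, 2]
  # solve p + t d = a + u e  for each segment
  det <- d[1] * (-ez) - d[2] * (-ex)
  rx <- a[, 1] - p[1]; rz <- a[, 2] - p[2]
  t <- (rx * (-ez) - rz * (-ex)) / det
  u <- (d[1] * rz - d[2] * rx) / det
  hit <- is.finite(u) & u >= -1e-12 & u <= 1 + 1e-12 & abs(det) > 1e-15
  if (!any(hit)) return(NULL)
  cbind(a[hit, 1] + u[hit] * ex[hit], a[hit, 2] + u[hit] * ez[hit])
}

#' Construct an ONSD ultrasound trace
#'
#' @param globe_posterior `(x, z)` point in mm where the nerve leaves the
#'   globe.
#' @param axis `n x 2` polyline of the nerve axis (mm), starting at
#'   `globe_posterior`.
#' @param sheath_upper,sheath_lower `n x 2` polylines of the two sheath
#'   boundaries (mm), flanking the axis.
#' @return An object of class `onsd_trace`.
#' @export
onsd_trace <- function(globe_posterior, axis, sheath_upper, sheath_lower) {
  axis <- as.matrix(axis)
  sheath_upper <- as.matrix(sheath_upper)
  sheath_lower <- as.matrix(sheath_lower)
  if (ncol(axis) != 2 || nrow(axis) < 2) {
    onh_stop("axis must be an n x 2 polyline", "onh_schema_error")
  }
  if (sqrt(sum((axis[1, ] - globe_posterior)^2)) > 1e-6) {
    onh_stop("axis must start at globe_posterior", "onh_geometry_error")
  }
  structure(list(globe_posterior = as.double(globe_posterior), axis = axis,
                 sheath_upper = sheath_upper, sheath_lower = sheath_lower),
            class = "onsd_trace")
}

#' Measure optic nerve sheath diameter
#'
#' Locates the point 3 mm along the nerve axis (arc length) from the
#' posterior globe, erects the perpendicular to the local axis tangent, and
#' returns the distance between its intersections with the two sheath
#' boundaries.
#'
#' @param trace An [onsd_trace()].
#' @param station_mm Arc-length station behind the globe (default 3 mm).
#' @return ONSD in mm.
#' @export
measure_onsd <- function(trace, station_mm = 3) {
  s <- polyline_arclength(trace$axis)
  if (s[length(s)] < station_mm) {
    onh_stop(sprintf("axis arc length %.2f mm < %.1f mm station",
                     s[length(s)], station_mm), "onh_coverage_error")
  }
  i <- max(which(s <= station_mm))
  i <- min(i, nrow(trace$axis) - 1L)
  seg <- trace$axis[i + 1L, ] - trace$axis[i, ]
  tangent <- seg / sqrt(sum(seg^2))
  P <- trace$axis[i, ] + (station_mm - s[i]) * tangent
  perp <- c(-tangent[2], tangent[1])
  pick <- function(sheath, side) {
    hits <- line_polyline_intersections(P, perp, sheath)
    if (is.null(hits)) {
      onh_stop(sprintf("perpendicular does not intersect %s sheath", side),
               "onh_measure_error")
    }
    d2 <- (hits[, 1] - P[1])^2 + (hits[, 2] - P[2])^2
    hits[which.min(d2), ]
  }
  up <- pick(trace$sheath_upper, "upper")
  lo <- pick(trace$sheath_lower, "lower")
  sqrt(sum((up - lo)^2))
}
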