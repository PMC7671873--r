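#' Segmented OCT scan containers
#'
#' The scan model holds segmented OCT geometry in physical micrometres; no
#' pixel data are involved.  A radial acquisition consists of 24 B-scan
#' diameters uniformly spaced by 7.5 degrees and sharing a rotation centre at
#' lateral position s = 0.  The axial coordinate z increases toward the
#' vitreous (anterior positive), so posteriorly displaced structures have
#' negative z -- the convention under which Bruch's membrane opening (BMO)
#' height and lamina depth come out negative in healthy eyes.
#'
#' @name scan_model
NULL

LAYER_IDS <- c("ILM", "BM", "RNFL_POST", "CHOROID_SCLERA", "ALCS")
CIRCLE_DIAMETERS_MM <- c(2.7, 3.5, 4.2, 4.9)
N_RADIAL_BSCANS <- 24L
RADIAL_STEP_DEG <- 7.5

#' Create a layer polyline
#'
#' @param s Numeric vector of lateral positions along the B-scan line (um),
#'   strictly increasing.  Negative s is the half-line opposite the scan
#'   direction.
#' @param z Numeric vector of axial positions (um), anterior positive.
#' @param layer_id One of `"ILM"`, `"BM"`, `"RNFL_POST"`, `"CHOROID_SCLERA"`,
#'   `"ALCS"`.
#' @return An object of class `layer_polyline`.
#' @export
layer_polyline <- function(s, z, layer_id) {
  if (!layer_id %in% LAYER_IDS) {
    onh_stop(sprintf("unknown layer_id '%s'", layer_id), "onh_schema_error")
  }
  s <- as.double(s); z <- as.double(z)
  if (length(s) != length(z) || length(s) < 2L) {
    onh_stop(sprintf("layer %s: s and z must have equal length >= 2", layer_id),
             "onh_schema_error")
  }
  if (!all(is.finite(s)) || !all(is.finite(z))) {
    onh_stop(sprintf("layer %s: non-finite coordinates", layer_id),
             "onh_geometry_error")
  }
  if (any(diff(s) <= 0)) {
    onh_stop(sprintf("layer %s: s must be strictly increasing", layer_id),
             "onh_geometry_error")
  }
  structure(list(s = s, z = z, layer_id = layer_id),
            class = "layer_polyline")
}

#' Create a radial B-scan
#'
#' @param index Integer 0-23, position in the radial set.
#' @param angle_deg Orientation of the scan line; by convention
#'   `index * 7.5` degrees.
#' @param ilm,bm [layer_polyline()] objects (required).
#' @param bmo_left,bmo_right Numeric `(s, z)` pairs marking Bruch's membrane
#'   opening on this B-scan, with `bmo_left[1] < bmo_right[1]`.
#' @param alcs Optional anterior lamina cribrosa surface polyline; may cover
#'   only part of the lateral span.
#' @return An object of class `radial_bscan`.
#' @export
radial_bscan <- function(index, angle_deg, ilm, bm, bmo_left, bmo_right,
                         alcs = NULL) {
  index <- as.integer(index)
  if (is.na(index) || index < 0L || index >= N_RADIAL_BSCANS) {
    onh_stop("index must be an integer in 0..23", "onh_schema_error")
  }
  stopifnot(inherits(ilm, "layer_polyline"), inherits(bm, "layer_polyline"))
  if (ilm$layer_id != "ILM" || bm$layer_id != "BM") {
    onh_stop("ilm/bm arguments must carry layer_id ILM and BM",
             "onh_schema_error")
  }
  if (!is.null(alcs)) {
    stopifnot(inherits(alcs, "layer_polyline"))
    if (alcs$layer_id != "ALCS") {
      onh_stop("alcs argument must carry layer_id ALCS", "onh_schema_error")
    }
  }
  bmo_left <- as.double(bmo_left); bmo_right <- as.double(bmo_right)
  if (length(bmo_left) != 2L || length(bmo_right) != 2L ||
      !all(is.finite(c(bmo_left, bmo_right)))) {
    onh_stop("bmo_left/bmo_right must be finite (s, z) pairs",
             "onh_schema_error")
  }
  if (bmo_left[1] >= bmo_right[1]) {
    onh_stop("bmo_left.s must be < bmo_right.s", "onh_geometry_error")
  }
  span <- range(bm$s)
  if (bmo_left[1] < span[1] - 1e-9 || bmo_right[1] > span[2] + 1e-9) {
    onh_stop("BMO points lie outside the lateral span of BM",
             "onh_geometry_error")
  }
  structure(list(index = index, angle_deg = as.double(angle_deg),
                 ilm = ilm, bm = bm, alcs = alcs,
                 bmo_left = bmo_left, bmo_right = bmo_right),
            class = "radial_bscan")
}

#' Create a segmented radial set
#'
#' @param bscans List of 24 [radial_bscan()] objects with unique indices 0-23.
#' @param eye `"OD"` or `"OS"`.  Stored, not used to mirror coordinates.
#' @param axial_sign Axial convention flag; only `"anterior_up"` is defined.
#' @return An object of class `segmented_radial_set`.
#' @export
segmented_radial_set <- function(bscans, eye = "OD",
                                 axial_sign = "anterior_up") {
  if (!eye %in% c("OD", "OS")) {
    onh_stop("eye must be 'OD' or 'OS'", "onh_schema_error")
  }
  if (!identical(axial_sign, "anterior_up")) {
    onh_stop("axial_sign must be 'anterior_up'", "onh_schema_error")
  }
  if (length(bscans) != N_RADIAL_BSCANS) {
    onh_stop(sprintf("expected %d B-scans, got %d", N_RADIAL_BSCANS,
                     length(bscans)), "onh_completeness_error")
  }
  idx <- vapply(bscans, function(b) b$index, integer(1))
  if (!setequal(idx, 0:23) || anyDuplicated(idx)) {
    onh_stop("B-scan indices must be exactly 0..23, each once",
             "onh_completeness_error")
  }
  bscans <- bscans[order(idx)]
  structure(list(bscans = bscans, eye = eye, axial_sign = axial_sign),
            class = "segmented_radial_set")
}

#' Create a circular scan
#'
#' @param diameter_mm One of 2.7, 3.5, 4.2, 4.9.
#' @param theta Strictly increasing angular samples in degrees, spanning at
#'   least 359 degrees.
#' @param ilm_z,rnfl_post_z,bm_z,choroid_sclera_z Per-sample axial positions
#'   (um).
#' @param valid Logical validity mask; at most 25% of samples may be masked,
#'   otherwise the scan is rejected outright (quality rule).
#' @return An object of class `circular_scan`.
#' @export
circular_scan <- function(diameter_mm, theta, ilm_z, rnfl_post_z, bm_z,
                          choroid_sclera_z, valid = NULL) {
  if (!any(abs(diameter_mm - CIRCLE_DIAMETERS_MM) < 1e-9)) {
    onh_stop("diameter_mm must be one of 2.7, 3.5, 4.2, 4.9",
             "onh_schema_error")
  }
  theta <- as.double(theta)
  n <- length(theta)
  if (n < 8L || any(diff(theta) <= 0)) {
    onh_stop("theta must be strictly increasing", "onh_geometry_error")
  }
  if (theta[n] - theta[1] < 359) {
    onh_stop("theta must span at least 359 degrees", "onh_geometry_error")
  }
  valid <- if (is.null(valid)) rep(TRUE, n) else as.logical(valid)
  layers <- list(ilm_z = ilm_z, rnfl_post_z = rnfl_post_z, bm_z = bm_z,
                 choroid_sclera_z = choroid_sclera_z)
  for (nm in names(layers)) {
    v <- as.double(layers[[nm]])
    if (length(v) != n) {
      onh_stop(sprintf("%s must match theta length", nm), "onh_schema_error")
    }
    if (any(!is.finite(v[valid]))) {
      onh_stop(sprintf("%s has non-finite values at valid samples", nm),
               "onh_geometry_error")
    }
    layers[[nm]] <- v
  }
  if (length(valid) != n) {
    onh_stop("valid mask must match theta length", "onh_schema_error")
  }
  if (mean(!valid) > 0.25) {
    onh_stop("more than 25% of samples masked: scan rejected",
             "onh_quality_error")
  }
  structure(c(list(diameter_mm = as.double(diameter_mm), theta = theta,
                   valid = valid), layers),
            class = "circular_scan")
}

#' Create session metadata
#'
#' @param subject_id Character scalar.
#' @param time_label One of the diurnal grid labels (`"7a"`, `"9a"`, `"11a"`,
#'   `"1p"`, `"3p"`, `"5p"`, `"7p"`) or the post-tilt endpoint label
#'   `"endpoint"`.
#' @param posture `"SEATED"`, `"HDT"` (6 degree head-down tilt) or `"LLD"`
#'   (left lateral decubitus, used for tonometry during tilt sessions).
#' @param scan_quality_db Scan quality in dB; sessions below 30 dB are
#'   rejected.
#' @return An object of class `session_meta`.
#' @export
session_meta <- function(subject_id, time_label, posture, scan_quality_db) {
  if (!time_label %in% c(TIME_LABELS, "endpoint")) {
    onh_stop(sprintf("unknown time_label '%s'", time_label),
             "onh_schema_error")
  }
  if (!posture %in% c("SEATED", "HDT", "LLD")) {
    onh_stop("posture must be SEATED, HDT or LLD", "onh_schema_error")
  }
  if (!is_number(scan_quality_db) || scan_quality_db < 30) {
    onh_stop("scan_quality_db must be >= 30 dB for accepted sessions",
             "onh_quality_error")
  }
  structure(list(subject_id = as.character(subject_id),
                 time_label = time_label, posture = posture,
                 scan_quality_db = as.double(scan_quality_db)),
            class = "session_meta")
}

TIME_LABELS <- c("7a", "9a", "11a", "1p", "3p", "5p", "7p")

#' Unfold a radial set into 3-D point clouds
#'
#' Each B-scan plane is vertical and passes through the rotation centre at
#' its orientation angle; a sample at lateral position s and axial position z
#' maps to `(x, y, z) = (s cos(theta), s sin(theta), z)`.  The mapping is an
#' isometry of each plane.
#'
#' @param set A [segmented_radial_set()].
#' @return A list with one `n x 3` matrix per layer (`ilm`, `bm`, and `alcs`
#'   where present) and a 48 x 3 matrix `bmo` of the marked BMO points
#'   (columns x, y, z in um).
#' @export
to_3d <- function(set) {
  stopifnot(inherits(set, "segmented_radial_set"))
  unfold <- function(poly, theta) {
    th <- theta * pi / 180
    cbind(x = poly$s * cos(th), y = poly$s * sin(th), z = poly$z)
  }
  ilm <- list(); bm <- list(); alcs <- list(); bmo <- list()
  for (b in set$bscans) {
    th <- b$angle_deg
    ilm[[length(ilm) + 1L]] <- unfold(b$ilm, th)
    bm[[length(bm) + 1L]] <- unfold(b$bm, th)
    if (!is.null(b$alcs)) alcs[[length(alcs) + 1L]] <- unfold(b$alcs, th)
    rad <- th * pi / 180
    pts <- rbind(b$bmo_left, b$bmo_right)
    bmo[[length(bmo) + 1L]] <-
      cbind(x = pts[, 1] * cos(rad), y = pts[, 1] * sin(rad), z = pts[, 2])
  }
  out <- list(ilm = do.call(rbind, ilm), bm = do.call(rbind, bm),
              bmo = do.call(rbind, bmo))
  if (length(alcs)) out$alcs <- do.call(rbind, alcs)
  out
}

#' @export
print.segmented_radial_set <- function(x, ...) {
  cat(sprintf("<segmented_radial_set> eye %s, %d B-scans (%.1f deg step)\n",
              x$eye, length(x$bscans), RADIAL_STEP_DEG))
  n_alcs <- sum(vapply(x$bscans, function(b) !is.null(b$alcs), logical(1)))
  cat(sprintf("  ALCS traced on %d/%d B-scans\n", n_alcs, length(x$bscans)))
  invisible(x)
}

#' @export
print.circular_scan <- function(x, ...) {
  cat(sprintf("<circular_scan> %.1f mm, %d samples (%.1f%% masked)\n",
              x$diameter_mm, length(x$theta), 100 * mean(!x$valid)))
  invisible(x)
}
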