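# JSON / CSV interchange for segmented scan geometry and session tables.
# Numeric fields are serialised at 17 significant digits so a write/read
# cycle is bit-for-bit on doubles (jsonlite digits = NA keeps only 15).

poly_to_mat <- function(p) unname(cbind(p$s, p$z))

mat_to_poly <- function(m, layer_id, field) {
  m <- matrix(as.double(unlist(m)), ncol = 2, byrow = !is.matrix(m))
  if (is.null(m) || ncol(m) != 2) {
    onh_stop(sprintf("field '%s' must be a list of [s, z] pairs", field),
             "onh_schema_error")
  }
  layer_polyline(m[, 1], m[, 2], layer_id)
}

#' Write a segmented radial set to JSON
#'
#' @param set A [segmented_radial_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_radial_set()]; the schema ships in
#'   `system.file("schema", "radial_set.schema.json", package = "onhmorph")`.
#' @export
write_radial_set <- function(set, path) {
  stopifnot(inherits(set, "segmented_radial_set"))
  bs <- lapply(set$bscans, function(b) {
    rec <- list(index = b$index, angle_deg = b$angle_deg,
                ilm = poly_to_mat(b$ilm), bm = poly_to_mat(b$bm),
                bmo_left = b$bmo_left, bmo_right = b$bmo_right)
    if (!is.null(b$alcs)) rec$alcs <- poly_to_mat(b$alcs)
    rec
  })
  obj <- list(eye = set$eye, axial_sign = set$axial_sign, bscans = bs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a segmented radial set from JSON
#'
#' Validates the documented interchange schema: all 24 B-scan indices
#' present, strictly increasing lateral coordinates, two BMO points per
#' B-scan with `bmo_left.s < bmo_right.s` inside the BM span.
#'
#' @param path Path to a radial-set JSON file.
#' @return A validated [segmented_radial_set()].
#' @export
read_radial_set <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("eye", "axial_sign", "bscans")) {
    if (is.null(obj[[f]])) {
      onh_stop(sprintf("radial-set JSON missing field '%s'", f),
               "onh_schema_error")
    }
  }
  pair <- function(x, field) {
    v <- as.double(unlist(x))
    if (length(v) != 2L) {
      onh_stop(sprintf("field '%s' must be an [s, z] pair", field),
               "onh_schema_error")
    }
    v
  }
  bscans <- lapply(obj$bscans, function(b) {
    for (f in c("index", "angle_deg", "ilm", "bm", "bmo_left", "bmo_right")) {
      if (is.null(b[[f]])) {
        onh_stop(sprintf("B-scan record missing field '%s'", f),
                 "onh_schema_error")
      }
    }
    radial_bscan(
      index = b$index, angle_deg = b$angle_deg,
      ilm = mat_to_poly(b$ilm, "ILM", "ilm"),
      bm = mat_to_poly(b$bm, "BM", "bm"),
      alcs = if (!is.null(b$alcs)) mat_to_poly(b$alcs, "ALCS", "alcs"),
      bmo_left = pair(b$bmo_left, "bmo_left"),
      bmo_right = pair(b$bmo_right, "bmo_right"))
  })
  segmented_radial_set(bscans, eye = obj$eye, axial_sign = obj$axial_sign)
}

#' Write a circular scan to JSON
#'
#' @param scan A [circular_scan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_circular_scan <- function(scan, path) {
  stopifnot(inherits(scan, "circular_scan"))
  obj <- list(diameter_mm = scan$diameter_mm, theta = scan$theta,
              ilm_z = scan$ilm_z, rnfl_post_z = scan$rnfl_post_z,
              bm_z = scan$bm_z, choroid_sclera_z = scan$choroid_sclera_z,
              valid = scan$valid)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a circular scan from JSON
#'
#' @param path Path to a circular-scan JSON file.
#' @return A validated [circular_scan()].
#' @export
read_circular_scan <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("diameter_mm", "theta", "ilm_z", "rnfl_post_z", "bm_z",
            "choroid_sclera_z")
  for (f in need) {
    if (is.null(obj[[f]])) {
      onh_stop(sprintf("circular-scan JSON missing field '%s'", f),
               "onh_schema_error")
    }
  }
  circular_scan(obj$diameter_mm, obj$theta, obj$ilm_z, obj$rnfl_post_z,
                obj$bm_z, obj$choroid_sclera_z, obj$valid)
}

#' Read a per-session physiology table
#'
#' Expected columns: `subject_id`, `time_label`, `posture`, `iop1`, `iop2`,
#' `iop3`, `sbp`, `dbp`, `cuff_eye_cm`; further columns (for example scan
#' paths) are carried through untouched.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with an added validated [pressure_record()] per row
#'   in list-column `pressure`.
#' @export
read_session_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_label", "posture", "iop1", "iop2", "iop3",
            "sbp", "dbp", "cuff_eye_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    onh_stop(sprintf("session table missing columns: %s",
                     paste(miss, collapse = ", ")), "onh_schema_error")
  }
  df$pressure <- lapply(seq_len(nrow(df)), function(i) {
    pressure_record(iop_readings = c(df$iop1[i], df$iop2[i], df$iop3[i]),
                    sbp = df$sbp[i], dbp = df$dbp[i],
                    cuff_eye_cm = df$cuff_eye_cm[i],
                    posture = df$posture[i])
  })
  df
}
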