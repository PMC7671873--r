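#' Diurnal cohort simulation
#'
#' Simulates seated and 6-degree head-down-tilt (HDT) diurnal cohorts with
#' the effect structure reported for healthy adults: a seated neuroretinal
#' rim that thins through the day (linearly from 7 a.m. to 3 p.m., then
#' plateaus, more in females), modest TRT/RNFL thinning near the rim, a
#' mid-day choroidal trough, late-day blood-pressure rise, and -- in HDT --
#' step increases in IOP and optic nerve sheath diameter, anterior BMO
#' drift, and no rim thinning.  All variability is controlled by a single
#' seed.
#'
#' @name cohort_sim
NULL

#' Default parameter catalogue
#'
#' One row per cohort parameter: baseline mean and between-subject SD,
#' within-subject SD `sw` (measurement noise; `2.77 * sw` is the
#' repeatability), seated 12-hour effects (total change by 7 p.m., or trough
#' depth for `dip`-shaped parameters), sex split where reported, trajectory
#' shape, and HDT step.
#'
#' @return A `data.frame`, one row per parameter.
#' @export
cohort_parameter_defaults <- function() {
  p <- function(param, mean, sd, sw, eff = 0, eff_sd = 0, eff_f = NA,
                eff_m = NA, shape = "flat", hdt_step = 0, hdt_step_sd = 0) {
    data.frame(param = param, baseline_mean = mean, baseline_sd = sd,
               sw = sw, effect = eff, effect_sd = eff_sd,
               effect_female = eff_f, effect_male = eff_m, shape = shape,
               hdt_step = hdt_step, hdt_step_sd = hdt_step_sd,
               stringsAsFactors = FALSE)
  }
  rbind(
    p("iop", 13.50, 3.14, 1.00, hdt_step = 4.37, hdt_step_sd = 1.92),
    p("onsd", 5.07, 0.49, 0.15, hdt_step = 0.43, hdt_step_sd = 0.48),
    p("mrw", 355.31, 61.76, 4.40 / 2.77, eff = -9.55, eff_sd = 8.03,
      eff_f = -13.56, eff_m = -5.55, shape = "ramp"),
    p("bmo_height", -102.01, 45.59, 8.03 / 2.77, eff = -3.7, eff_sd = 3,
      shape = "dip", hdt_step = 11, hdt_step_sd = 5),
    p("alcsd", -440.14, 90.69, 25.01 / 2.77),
    p("bmo_area", 2.04, 0.44, 0.06 / 2.77),
    p("trt250", 394.77, 36.66, 4.85 / 2.77, eff = -7.07, eff_sd = 6.21,
      eff_f = -9.6, eff_m = -4.6, shape = "ramp"),
    p("trt500", 375.02, 20.64, 3.07 / 2.77, eff = -3.50, eff_sd = 3.55,
      eff_f = -4.9, eff_m = -2.1, shape = "ramp"),
    p("trt1000", 343.08, 13.27, 2.13 / 2.77),
    p("trt1500", 317.12, 11.22, 2.80 / 2.77),
    p("rnflt_2.7", 142.85, 14.51, 3.82 / 2.77, eff = -1.24, eff_sd = 2.35,
      shape = "ramp"),
    p("rnflt_3.5", 118.96, 10.79, 2.60 / 2.77, eff = -0.91, eff_sd = 1.91,
      shape = "ramp"),
    p("rnflt_4.2", 102.93, 9.10, 2.41 / 2.77, eff = -1.0, eff_sd = 2.0,
      shape = "ramp"),
    p("rnflt_4.9", 90.10, 7.91, 2.24 / 2.77),
    p("choroidt_2.7", 179.84, 41.48, 20.28 / 2.77, eff = -6, eff_sd = 5,
      shape = "dip"),
    p("choroidt_3.5", 211.25, 50.72, 13.85 / 2.77, eff = -6, eff_sd = 5,
      shape = "dip"),
    p("choroidt_4.2", 228.83, 53.85, 13.71 / 2.77, eff = -7, eff_sd = 5,
      shape = "dip"),
    p("choroidt_4.9", 241.26, 55.44, 14.76 / 2.77, eff = -7, eff_sd = 5,
      shape = "dip"))
}

# fraction of the 12-h effect realised at each of the 7 seated sessions
trajectory_shape <- function(shape) {
  switch(shape,
         flat = rep(0, 7),
         ramp = c(0, 0.25, 0.5, 0.75, 1, 1, 1),
         dip = c(0, 0.5, 1, 1, 0.8, 0.5, 0.2),
         late = c(0, 0, 0, 0, 1 / 3, 2 / 3, 1),
         onh_stop(sprintf("unknown trajectory shape '%s'", shape),
                  "onh_schema_error"))
}

#' Specify a cohort simulation
#'
#' @param n_subjects Number of subjects (default 30).
#' @param sex_ratio Fraction of females (default 0.5).
#' @param arm `"seated"` or `"hdt"`.
#' @param params Parameter catalogue as in [cohort_parameter_defaults()];
#'   every effect and noise level is a config field.
#' @param noise_scale Multiplier on all within-subject SDs (0 = noise-free).
#' @param effect_sd_scale Multiplier on the between-subject SDs of the
#'   12-hour effects and HDT steps (0 = every subject gets the mean effect).
#' @param map_rise_mmHg Late-day rise in mean arterial pressure by 7 p.m.
#' @param hdt_map_drop_mmHg Initial MAP drop on assuming HDT.
#' @param cuff_eye_seated_cm,cuff_eye_hdt_cm Vertical cuff-to-eye distances.
#' @param seed Integer seed; the simulation is fully determined by it.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_subjects = 30, sex_ratio = 0.5,
                            arm = c("seated", "hdt"),
                            params = cohort_parameter_defaults(),
                            noise_scale = 1, effect_sd_scale = 1,
                            map_rise_mmHg = 4, hdt_map_drop_mmHg = 6.80,
                            cuff_eye_seated_cm = 38.4,
                            cuff_eye_hdt_cm = -3.6, seed = 1L) {
  arm <- match.arg(arm)
  if (n_subjects < 2) onh_stop("need >= 2 subjects", "onh_schema_error")
  if (any(params$baseline_sd < 0) || any(params$sw < 0)) {
    onh_stop("SDs must be >= 0", "onh_schema_error")
  }
  spec <- as.list(environment())
  structure(spec, class = "cohort_sim_spec")
}

#' Simulate a diurnal cohort
#'
#' Produces a long-format cohort table: one row per subject and session with
#' physiology (IOP triplet mean, SBP/DBP, MAP, MOPP via the hydrostatic
#' correction), ONSD, and all structural parameters.  The seated arm has the
#' seven two-hourly sessions; the HDT arm has the 7 a.m. seated baseline,
#' seven sessions in tilt, and a seated endpoint.
#'
#' @param spec A [cohort_sim_spec()].
#' @return A `data.frame` of class `cohort_table` with columns
#'   `subject_id`, `sex`, `arm`, `session_order`, `time_label`, `posture`,
#'   `sbp`, `dbp`, `cuff_eye_cm`, and one column per parameter (including
#'   derived `map` and `mopp`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  nf <- round(n * spec$sex_ratio)
  sex <- rep(c("F", "M"), c(nf, n - nf))
  ids <- sprintf("S%03d", seq_len(n))
  P <- spec$params

  if (spec$arm == "seated") {
    sessions <- data.frame(session_order = 1:7, time_label = TIME_LABELS,
                           posture = "SEATED", stringsAsFactors = FALSE)
  } else {
    sessions <- data.frame(
      session_order = 1:9,
      time_label = c("7a", TIME_LABELS, "endpoint"),
      posture = c("SEATED", rep("HDT", 7), "SEATED"),
      stringsAsFactors = FALSE)
  }
  ns <- nrow(sessions)
  # fraction of the seated diurnal effect at each session (time-of-day only)
  tod_index <- match(sessions$time_label, TIME_LABELS)
  tod_index[is.na(tod_index)] <- 7L            # endpoint: 7 p.m. clock time

  # subject-level baselines and effects
  draw <- function(mean, sd) stats::rnorm(n, mean, sd)
  base <- sapply(seq_len(nrow(P)), function(j)
    draw(P$baseline_mean[j], P$baseline_sd[j]))
  colnames(base) <- P$param
  eff_mean <- sapply(seq_len(nrow(P)), function(j) {
    if (!is.na(P$effect_female[j])) {
      ifelse(sex == "F", P$effect_female[j], P$effect_male[j])
    } else {
      rep(P$effect[j], n)
    }
  })
  eff <- eff_mean + sapply(seq_len(nrow(P)), function(j)
    stats::rnorm(n, 0, P$effect_sd[j] * spec$effect_sd_scale))
  hdt_step <- sapply(seq_len(nrow(P)), function(j)
    stats::rnorm(n, P$hdt_step[j], P$hdt_step_sd[j] * spec$effect_sd_scale))
  colnames(eff) <- colnames(hdt_step) <- P$param

  # blood pressure generators: MAP = dbp + pulse/3
  dbp0 <- draw(73, 8)
  pulse0 <- pmax(20, draw(44, 8))
  map_shape <- trajectory_shape("late")
  in_tilt <- sessions$posture == "HDT"

  # long layout: subject-major, session-minor (vectorised over both)
  sub_i <- rep(seq_len(n), each = ns)
  ses_t <- rep(seq_len(ns), times = n)
  tf <- tod_index[ses_t]
  tilt <- in_tilt[ses_t]
  nr <- n * ns
  out <- data.frame(
    subject_id = ids[sub_i], sex = sex[sub_i], arm = spec$arm,
    session_order = sessions$session_order[ses_t],
    time_label = sessions$time_label[ses_t],
    posture = ifelse(tilt, "HDT", "SEATED"),
    stringsAsFactors = FALSE)

  vals <- matrix(NA_real_, nr, nrow(P) + 2L,
                 dimnames = list(NULL, c(P$param, "map", "mopp")))
  for (j in seq_len(nrow(P))) {
    pm <- P$param[j]
    frac <- trajectory_shape(P$shape[j])[tf]
    v <- base[sub_i, pm] +
      ifelse(tilt,
             # tilt suppresses the seated diurnal drift of structural
             # parameters and superimposes the posture step
             hdt_step[sub_i, pm] +
               if (pm == "iop") {
                 (2.5 - hdt_step[sub_i, "iop"]) * (tf - 1) / 6 *
                   (hdt_step[sub_i, "iop"] != 0)
               } else 0,
             frac * eff[sub_i, pm])
    vals[, j] <- v + stats::rnorm(nr, 0, P$sw[j] * spec$noise_scale)
  }
  # IOP is the mean of a tonometry triplet around the latent value
  vals[, "iop"] <- vals[, "iop"] +
    rowMeans(matrix(stats::rnorm(3 * nr, 0, 0.5 * spec$noise_scale), nr))
  # BP with a late-day rise, initial dip in tilt recovering by 3 p.m.
  dbp <- dbp0[sub_i] + map_shape[tf] * spec$map_rise_mmHg -
    ifelse(tilt, spec$hdt_map_drop_mmHg * pmax(0, 1 - (tf - 1) / 4), 0) +
    stats::rnorm(nr, 0, 2 * spec$noise_scale)
  pulse <- pmax(10, pulse0[sub_i] + stats::rnorm(nr, 0, 3 * spec$noise_scale))
  sbp <- dbp + pulse
  cuff <- ifelse(tilt, spec$cuff_eye_hdt_cm, spec$cuff_eye_seated_cm)
  out$sbp <- sbp
  out$dbp <- dbp
  out$cuff_eye_cm <- cuff
  vals[, "map"] <- mean_arterial_pressure(sbp, dbp)
  vals[, "mopp"] <- mopp(vals[, "map"], cuff, vals[, "iop"])
  out <- cbind(out, as.data.frame(vals))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate a duplicate-measurement repeatability design
#'
#' Per-subject latent value plus two replicates with within-subject noise
#' `sigma_w`; exercises the `2.77 * Sw` repeatability machinery.
#'
#' @param n Number of subjects (`>= 2`).
#' @param sigma_w Within-subject SD (same units as the parameter).
#' @param seed Integer seed.
#' @param mean,between_sd Population mean and between-subject SD of the
#'   latent values (defaults mimic BMO-MRW in um).
#' @return `data.frame` with columns `subject_id`, `rep1`, `rep2`.
#' @export
simulate_repeatability <- function(n, sigma_w, seed = 1L, mean = 355.31,
                                   between_sd = 61.76) {
  if (n < 2 || sigma_w < 0) {
    onh_stop("need n >= 2 and sigma_w >= 0", "onh_schema_error")
  }
  set.seed(seed)
  truth <- stats::rnorm(n, mean, between_sd)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             rep1 = truth + stats::rnorm(n, 0, sigma_w),
             rep2 = truth + stats::rnorm(n, 0, sigma_w))
}
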