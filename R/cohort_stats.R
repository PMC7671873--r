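#' Cohort statistics for diurnal ONH studies
#'
#' Within-subject repeatability (Sw, CV, 2.77*Sw), change-from-baseline
#' tables against the 7 a.m. seated session, repeated-measures ANOVA with
#' Dunnett many-to-one contrasts, and the simple/multiple regressions used
#' to relate structural change to pressure change.
#'
#' @name cohort_stats
NULL

#' Within-subject repeatability from duplicate measurements
#'
#' For paired same-session replicates, the within-subject standard deviation
#' is `Sw = sqrt(sum(d_i^2) / (2 n))` with `d_i` the within-subject
#' difference; repeatability is `2.77 * Sw` (the expected bound on the
#' difference between two repeated measures) and `CV = 100 * Sw / |grand
#' mean|`.  The absolute grand mean keeps CV meaningful for signed
#' parameters near zero (where CV is large and flagged as such).
#'
#' @param rep1,rep2 First and second measurement per subject (equal length,
#'   `n >= 2`).
#' @param parameter Parameter name carried into the result.
#' @return Object of class `repeatability_result`: `parameter`, `sw`,
#'   `repeatability`, `cv_percent`, `n_subjects`, `signed_mean` flag.
#' @export
repeatability <- function(rep1, rep2, parameter = "parameter") {
  rep1 <- as.double(rep1); rep2 <- as.double(rep2)
  if (length(rep1) != length(rep2)) {
    onh_stop("duplicate design requires exactly 2 replicates per subject",
             "onh_schema_error")
  }
  ok <- is.finite(rep1) & is.finite(rep2)
  rep1 <- rep1[ok]; rep2 <- rep2[ok]
  n <- length(rep1)
  if (n < 2L) onh_stop("need >= 2 subjects", "onh_schema_error")
  d <- rep1 - rep2
  sw <- sqrt(sum(d^2) / (2 * n))
  gm <- mean(c(rep1, rep2))
  structure(list(parameter = parameter, sw = sw,
                 repeatability = 2.77 * sw,
                 cv_percent = 100 * sw / abs(gm),
                 grand_mean = gm, signed_mean = gm < 0, n_subjects = n),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("<repeatability> %s: Sw = %.3f, 2.77*Sw = %.3f, CV = %.2f%% (n = %d)\n",
              x$parameter, x$sw, x$repeatability, x$cv_percent, x$n_subjects))
  invisible(x)
}

cohort_param_cols <- function(cohort) {
  drop <- c("subject_id", "sex", "arm", "time_label", "posture",
            "session_order", "sbp", "dbp", "cuff_eye_cm")
  setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))], drop)
}

#' Change from the 7 a.m. seated baseline
#'
#' Subtracts each subject's 7 a.m. seated value from every session, for
#' every numeric parameter column of a long-format cohort table.  Subjects
#' without a baseline row are excluded and logged.
#'
#' @param cohort Long-format `data.frame` with columns `subject_id`,
#'   `time_label`, `posture`, `session_order`, and one numeric column per
#'   parameter.
#' @param parameters Parameter columns to process (default: all numeric
#'   parameter columns).
#' @param baseline_label,baseline_posture Identify the baseline session.
#' @return Object of class `change_table`: `$changes` (long rows with
#'   `value`, `baseline`, `change`), `$summary` (per parameter x session:
#'   `n`, `mean_change`, `sd_change`, `se_change`), `$excluded` subject ids.
#' @export
change_from_baseline <- function(cohort, parameters = NULL,
                                 baseline_label = "7a",
                                 baseline_posture = "SEATED") {
  if (is.null(parameters)) parameters <- cohort_param_cols(cohort)
  base <- cohort[cohort$time_label == baseline_label &
                   cohort$posture == baseline_posture, ]
  if (anyDuplicated(base$subject_id)) {
    onh_stop("multiple baseline rows for a subject", "onh_schema_error")
  }
  excluded <- setdiff(unique(cohort$subject_id), base$subject_id)
  keep <- cohort$subject_id %in% base$subject_id
  co <- cohort[keep, ]
  rows <- list()
  for (p in parameters) {
    b <- base[[p]][match(co$subject_id, base$subject_id)]
    rows[[p]] <- data.frame(
      subject_id = co$subject_id, parameter = p,
      time_label = co$time_label, posture = co$posture,
      session_order = co$session_order,
      value = co[[p]], baseline = b, change = co[[p]] - b,
      stringsAsFactors = FALSE)
  }
  changes <- do.call(rbind, rows)
  rownames(changes) <- NULL
  agg <- stats::aggregate(change ~ parameter + session_order + time_label +
                            posture, data = changes,
                          FUN = function(v) c(n = sum(is.finite(v)),
                                              mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(agg[c("parameter", "session_order", "time_label",
                              "posture")],
                        n = agg$change[, "n"],
                        mean_change = agg$change[, "mean"],
                        sd_change = agg$change[, "sd"])
  summary$se_change <- summary$sd_change / sqrt(summary$n)
  summary <- summary[order(summary$parameter, summary$session_order), ]
  rownames(summary) <- NULL
  structure(list(changes = changes, summary = summary, excluded = excluded,
                 baseline_label = baseline_label,
                 baseline_posture = baseline_posture),
            class = "change_table")
}

#' @export
print.change_table <- function(x, ...) {
  cat(sprintf("<change_table> %d parameters, %d sessions, %d subjects excluded\n",
              length(unique(x$changes$parameter)),
              length(unique(x$changes$session_order)), length(x$excluded)))
  invisible(x)
}

#' Dunnett contrasts of every session against baseline
#'
#' One-way repeated-measures ANOVA across sessions followed by two-sided
#' Dunnett many-to-one comparisons of each later session with the baseline
#' session, using the within-subject error mean square.  Subjects with any
#' missing session are dropped listwise (logged in the result).
#'
#' @param changes A [change_from_baseline()] result.
#' @param parameter Parameter name to analyse.
#' @return `data.frame` with one row per non-baseline session: `time_label`,
#'   `posture`, `n`, `mean_change`, `tstat`, `p_adj`.  Attributes `anova_F`,
#'   `anova_p`, `df_error`, `n_subjects`, `dropped`.
#' @export
baseline_contrasts <- function(changes, parameter) {
  stopifnot(inherits(changes, "change_table"))
  d <- changes$changes[changes$changes$parameter == parameter, ]
  if (!nrow(d)) onh_stop("unknown parameter", "onh_schema_error")
  sess <- unique(d[order(d$session_order),
                   c("session_order", "time_label", "posture")])
  wide <- stats::reshape(d[c("subject_id", "session_order", "value")],
                         idvar = "subject_id", timevar = "session_order",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  m <- m[, order(as.integer(sub("value\\.", "", colnames(m)))), drop = FALSE]
  complete <- stats::complete.cases(m)
  dropped <- wide$subject_id[!complete]
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) onh_stop("need >= 3 complete subjects", "onh_schema_error")
  grand <- mean(m)
  ss_time <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  df_time <- k - 1; df_err <- (n - 1) * (k - 1)
  mse <- ss_err / df_err
  if (mse <= .Machine$double.eps * max(1, abs(grand))) {
    onh_stop("zero within-subject variance: contrasts undefined",
             "onh_degenerate_error")
  }
  Fstat <- (ss_time / df_time) / mse
  se <- sqrt(2 * mse / n)
  diffs <- colMeans(m)[-1] - colMeans(m)[1]
  tstat <- diffs / se
  p <- dunnett_pvalue(tstat, k = k - 1, df = df_err)
  out <- data.frame(sess[-1, c("time_label", "posture")],
                    n = n, mean_change = diffs, tstat = tstat, p_adj = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, anova_F = Fstat,
            anova_p = stats::pf(Fstat, df_time, df_err, lower.tail = FALSE),
            df_error = df_err, n_subjects = n, dropped = dropped)
}

#' Ordinary least squares on one predictor
#'
#' @param x,y Numeric vectors (`n >= 3`), `x` non-constant.
#' @return List `slope`, `intercept`, `r2`, `p` (two-sided slope test).
#' @export
ols <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) onh_stop("need >= 3 points", "onh_schema_error")
  if (stats::sd(x) == 0) onh_stop("constant predictor", "onh_degenerate_error")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(x))
}

#' Ordinary least squares on two predictors
#'
#' @param y Response.
#' @param x1,x2 Predictors; the design matrix must be full rank.
#' @return List `coefficients` (intercept, x1, x2), `r2`, `p_values`
#'   (per-coefficient, two-sided), `p_model`, `n`.
#' @export
multiple_ols <- function(y, x1, x2) {
  ok <- is.finite(y) & is.finite(x1) & is.finite(x2)
  y <- y[ok]; x1 <- x1[ok]; x2 <- x2[ok]
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L) {
    onh_stop("rank-deficient design matrix", "onh_degenerate_error")
  }
  fit <- stats::lm(y ~ x1 + x2)
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(coefficients = stats::coef(fit), r2 = sm$r.squared,
       p_values = sm$coefficients[, 4],
       p_model = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       n = length(y))
}

#' Two-group comparison
#'
#' Two-sided t test, unpaired (for example, sex contrasts) or paired on
#' `subject_id` (seated versus head-down tilt in the same subjects).
#'
#' @param values Numeric measurements.
#' @param groups Two-level grouping vector.
#' @param paired Pair observations on `subject_id`.
#' @param subject_id Required when `paired = TRUE`.
#' @return List `p`, `tstat`, `df`, `estimate` (difference of means,
#'   group1 - group2), `n`.
#' @export
group_compare <- function(values, groups, paired = FALSE,
                          subject_id = NULL) {
  g <- factor(groups)
  if (nlevels(g) != 2L) onh_stop("need exactly two groups", "onh_schema_error")
  a <- values[g == levels(g)[1]]
  b <- values[g == levels(g)[2]]
  if (paired) {
    if (is.null(subject_id)) {
      onh_stop("paired comparison requires subject_id", "onh_schema_error")
    }
    ia <- subject_id[g == levels(g)[1]]
    ib <- subject_id[g == levels(g)[2]]
    common <- intersect(ia, ib)
    if (length(common) < 2L) onh_stop("need >= 2 pairs", "onh_schema_error")
    a <- a[match(common, ia)]
    b <- b[match(common, ib)]
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2L || length(b) < 2L) {
      onh_stop("each group needs n >= 2", "onh_schema_error")
    }
    tt <- stats::t.test(a, b)
  }
  list(p = tt$p.value, tstat = unname(tt$statistic),
       df = unname(tt$parameter), estimate = mean(a) - mean(b),
       n = c(length(a), length(b)))
}
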