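#' Reproducible simulate -> morphometry -> stats pipeline
#'
#' [run_pipeline()] chains the cohort simulator, repeatability machinery,
#' change-from-baseline tables with Dunnett contrasts, and the regression
#' analyses into a deterministic report bundle of TSV tables plus a
#' machine-readable JSON summary.  Re-running with the same config and seed
#' is byte-identical; every output carries the config hash and seed.
#'
#' @name cli_pipeline
NULL

#' Build a run configuration
#'
#' @param arm `"seated"`, `"hdt"` or `"both"`.
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory (created if absent).
#' @param n_subjects,n_subjects_hdt Cohort sizes per arm.
#' @param n_repeatability Subjects in the duplicate-scan repeatability
#'   simulation.
#' @param params Parameter catalogue (see [cohort_parameter_defaults()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(arm = c("seated", "hdt", "both"), seed = 1L,
                       out_dir = "onh-run", n_subjects = 30,
                       n_subjects_hdt = 10, n_repeatability = 24,
                       params = cohort_parameter_defaults()) {
  arm <- match.arg(arm)
  structure(list(arm = arm, seed = as.integer(seed), out_dir = out_dir,
                 n_subjects = n_subjects, n_subjects_hdt = n_subjects_hdt,
                 n_repeatability = n_repeatability, params = params),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with any subset of the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- obj[intersect(names(obj), c("arm", "seed", "out_dir", "n_subjects",
                                      "n_subjects_hdt", "n_repeatability"))]
  do.call(run_config, args)
}

write_tsv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# onhmorph seed=%d config=%s", meta$seed, meta$hash),
             con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # where the bundle lands does not change what it contains
  x <- unclass(config)
  x$out_dir <- NULL
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

analyse_arm <- function(cohort, params, log) {
  ch <- change_from_baseline(cohort)
  contrasts <- list()
  for (p in unique(ch$changes$parameter)) {
    contrasts[[p]] <- tryCatch({
      con <- baseline_contrasts(ch, p)
      cbind(parameter = p, con,
            anova_F = attr(con, "anova_F"), anova_p = attr(con, "anova_p"))
    }, onh_error = function(e) {
      log(sprintf("contrasts for %s skipped: %s", p, conditionMessage(e)))
      NULL
    })
  }
  list(changes = ch, contrasts = do.call(rbind, contrasts))
}

last_change <- function(ch, param, label = "7p") {
  d <- ch$changes[ch$changes$parameter == param &
                    ch$changes$time_label == label, ]
  d[order(d$subject_id), c("subject_id", "change", "baseline")]
}

#' Run the full pipeline
#'
#' Stages: (1) simulate the cohort(s); (2) repeatability table from a
#' duplicate-scan simulation at each parameter's within-subject SD;
#' (3) change-from-baseline tables and per-session Dunnett contrasts;
#' (4) regressions (12-hour rim change versus baseline rim width; multiple
#' regression of rim change on IOP and ONSD change; sex contrast) and, for
#' the HDT arm, the paired seated-versus-tilt comparison.  All tables are
#' written under `out_dir` and summarised in `summary.json`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the tables and the summary; side effect:
#'   files under `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta <- list(seed = config$seed, hash = hash)
  logline <- function(msg) {
    if (!quiet) message(sprintf("[onhmorph] %s", msg))
  }

  arms <- if (config$arm == "both") c("seated", "hdt") else config$arm
  cohorts <- list()
  for (a in arms) {
    n <- if (a == "seated") config$n_subjects else config$n_subjects_hdt
    spec <- cohort_sim_spec(n_subjects = n, arm = a, params = config$params,
                            seed = derive_seed(config$seed,
                                               match(a, c("seated", "hdt"))))
    cohorts[[a]] <- simulate_cohort(spec)
    logline(sprintf("simulated %s arm: %d rows", a, nrow(cohorts[[a]])))
  }

  # repeatability table (duplicate-scan design per parameter)
  P <- config$params
  rep_rows <- lapply(seq_len(nrow(P)), function(j) {
    d <- simulate_repeatability(config$n_repeatability, P$sw[j],
                                seed = derive_seed(config$seed, 100 + j),
                                mean = P$baseline_mean[j],
                                between_sd = P$baseline_sd[j])
    r <- repeatability(d$rep1, d$rep2, P$param[j])
    data.frame(parameter = r$parameter, sw = r$sw,
               repeatability = r$repeatability, cv_percent = r$cv_percent,
               n = r$n_subjects)
  })
  rep_table <- do.call(rbind, rep_rows)
  logline(sprintf("repeatability table: %d parameters", nrow(rep_table)))

  results <- list(repeatability = rep_table)
  files <- list(repeatability = "repeatability.tsv")
  summary <- list(seed = config$seed, config_hash = hash, arm = config$arm)

  for (a in arms) {
    an <- analyse_arm(cohorts[[a]], P, logline)
    base <- cohorts[[a]][cohorts[[a]]$time_label == "7a" &
                           cohorts[[a]]$posture == "SEATED", ]
    pbase <- data.frame(parameter = cohort_param_cols(cohorts[[a]]))
    pbase$mean <- vapply(pbase$parameter, function(p) mean(base[[p]]),
                         numeric(1))
    pbase$sd <- vapply(pbase$parameter, function(p) stats::sd(base[[p]]),
                       numeric(1))
    results[[paste0("baseline_", a)]] <- pbase
    results[[paste0("changes_", a)]] <- an$changes$summary
    results[[paste0("contrasts_", a)]] <- an$contrasts
    files[[paste0("baseline_", a)]] <- sprintf("baseline_%s.tsv", a)
    files[[paste0("changes_", a)]] <- sprintf("changes_%s.tsv", a)
    files[[paste0("contrasts_", a)]] <- sprintf("contrasts_%s.tsv", a)

    # regressions on the 12-hour changes
    ch <- an$changes
    label_end <- "7p"
    mrw_end <- last_change(ch, "mrw", label_end)
    iop_end <- last_change(ch, "iop", label_end)
    onsd_end <- last_change(ch, "onsd", label_end)
    reg1 <- ols(mrw_end$baseline, mrw_end$change)
    reg2 <- multiple_ols(mrw_end$change, iop_end$change, onsd_end$change)
    co <- cohorts[[a]]
    sex_end <- merge(mrw_end,
                     unique(co[c("subject_id", "sex")]), by = "subject_id")
    sexcmp <- group_compare(sex_end$change, sex_end$sex)
    reg_table <- data.frame(
      analysis = c("mrw_change_vs_baseline", "mrw_vs_iop_onsd",
                   "sex_contrast"),
      statistic = c(reg1$r2, reg2$r2, sexcmp$estimate),
      p = c(reg1$p, reg2$p_model, sexcmp$p), n = c(reg1$n, reg2$n,
                                                   sum(sexcmp$n)))
    results[[paste0("regressions_", a)]] <- reg_table
    files[[paste0("regressions_", a)]] <- sprintf("regressions_%s.tsv", a)
    summary[[paste0(a, "_mrw_change_7p")]] <-
      mean(mrw_end$change)
    logline(sprintf("%s arm analysed: %d contrasts", a,
                    nrow(an$contrasts)))
  }

  # paired seated-vs-HDT comparison when both arms are present
  if (all(c("seated", "hdt") %in% arms)) {
    chs <- change_from_baseline(cohorts$seated)
    chh <- change_from_baseline(cohorts$hdt)
    rows <- list()
    for (p in c("mrw", "iop", "onsd", "trt250")) {
      s7 <- last_change(chs, p); h7 <- last_change(chh, p)
      ns <- min(nrow(s7), nrow(h7))    # paired on shared simulated subjects
      gc <- group_compare(c(s7$change[seq_len(ns)], h7$change[seq_len(ns)]),
                          rep(c("seated", "hdt"), each = ns), paired = TRUE,
                          subject_id = rep(s7$subject_id[seq_len(ns)], 2))
      rows[[p]] <- data.frame(parameter = p, mean_diff = gc$estimate,
                              tstat = gc$tstat, p = gc$p, n_pairs = ns)
    }
    results$paired_seated_vs_hdt <- do.call(rbind, rows)
    files$paired_seated_vs_hdt <- "paired_seated_vs_hdt.tsv"
  }

  for (nm in names(files)) {
    write_tsv(results[[nm]], file.path(config$out_dir, files[[nm]]), meta)
  }
  summary$tables <- unname(unlist(files))
  summary$n_rows <- vapply(results, nrow, integer(1))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline(sprintf("bundle written to %s (%.1f s)", config$out_dir,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(c(results, list(summary = summary)))
}
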