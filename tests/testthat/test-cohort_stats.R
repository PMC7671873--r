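# Repeatability, change tables, Dunnett contrasts, regressions.

test_that("repeatability implements sqrt(sum(d^2) / 2n) with 2.77 factor", {
  r0 <- repeatability(c(10, 20, 30), c(10, 20, 30))
  expect_equal(r0$sw, 0)
  expect_equal(r0$repeatability, 0)

  # d = (2, -2, 2, -2): sw = sqrt(16 / 8) = sqrt(2)
  r <- repeatability(c(12, 8, 12, 8), c(10, 10, 10, 10))
  expect_equal(r$sw, sqrt(2), tolerance = 1e-12)
  expect_equal(r$repeatability, 2.77 * sqrt(2), tolerance = 1e-12)
  expect_equal(r$repeatability / r$sw, 2.77)

  # sw = 1 with grand mean 100 -> CV = 1%
  r2 <- repeatability(c(100 + sqrt(2), 100 - sqrt(2)), c(100, 100))
  expect_equal(r2$sw, 1, tolerance = 1e-12)
  expect_equal(r2$cv_percent, 1, tolerance = 1e-6)

  expect_error(repeatability(1:3, 1:2), class = "onh_schema_error")
  expect_error(repeatability(1, 2), class = "onh_schema_error")
})

test_that("repeatability ignores pure between-subject shifts", {
  set.seed(5)
  a <- rnorm(20, 350, 5); b <- a + rnorm(20, 0, 2)
  shift <- rnorm(20, 0, 60)
  r1 <- repeatability(a, b)
  r2 <- repeatability(a + shift, b + shift)
  expect_equal(r1$sw, r2$sw, tolerance = 1e-12)
})

test_that("change_from_baseline subtracts each subject's 7 a.m. value", {
  co <- data.frame(subject_id = rep(c("A", "B"), each = 3),
                   time_label = rep(c("7a", "9a", "11a"), 2),
                   posture = "SEATED", session_order = rep(1:3, 2),
                   mrw = c(355, 350, 345, 400, 398, 390))
  ch <- change_from_baseline(co, "mrw")
  a <- ch$changes[ch$changes$subject_id == "A", ]
  expect_equal(a$change, c(0, -5, -10))
  expect_true(all(ch$changes$change[ch$changes$time_label == "7a"] == 0))
  s <- ch$summary[ch$summary$time_label == "11a", ]
  expect_equal(s$mean_change, mean(c(-10, -10)))

  # injected constant decline: mean = injected, SD = 0
  co2 <- data.frame(subject_id = rep(sprintf("S%d", 1:5), each = 2),
                    time_label = rep(c("7a", "7p"), 5), posture = "SEATED",
                    session_order = rep(c(1, 7), 5),
                    mrw = as.vector(rbind(300 + 1:5, 300 + 1:5 - 9.55)))
  ch2 <- change_from_baseline(co2, "mrw")
  s2 <- ch2$summary[ch2$summary$time_label == "7p", ]
  expect_equal(s2$mean_change, -9.55)
  expect_equal(s2$sd_change, 0)

  # subject with no baseline row is excluded and logged
  co3 <- rbind(co, data.frame(subject_id = "C", time_label = "9a",
                              posture = "SEATED", session_order = 2,
                              mrw = 123))
  ch3 <- change_from_baseline(co3, "mrw")
  expect_equal(ch3$excluded, "C")
  expect_false("C" %in% ch3$changes$subject_id)
})

test_that("Dunnett quadrature agrees with the Monte-Carlo null", {
  for (cfg in list(c(k = 6, df = 174), c(k = 4, df = 27))) {
    for (q in c(2.0, 2.6, 3.2)) {
      expect_equal(dunnett_prob(q, cfg["k"], cfg["df"]),
                   oracle_dunnett_mc(q, cfg["k"], cfg["df"]),
                   tolerance = 0.005)
    }
  }
  # k = 1 reduces to an ordinary two-sided t probability
  expect_equal(dunnett_prob(2.1, 1, 30), 1 - 2 * pt(-2.1, 30),
               tolerance = 1e-4)
  # critical value inverts the tail probability
  q <- dunnett_crit(0.05, 6, 174)
  expect_equal(dunnett_prob(q, 6, 174), 0.95, tolerance = 1e-6)
  expect_true(all(diff(dunnett_pvalue(c(1, 2, 3), 6, 174)) < 0))
})

test_that("baseline_contrasts detects an injected step and flags zero variance", {
  set.seed(8)
  n <- 30; k <- 7
  base <- rnorm(n, 355, 60)
  m <- base + matrix(rnorm(n * k, 0, 4.4 / 2.77), n, k)
  m[, 2:k] <- m[, 2:k] - 10   # -10 um at every post-baseline session
  co <- data.frame(subject_id = rep(sprintf("S%02d", 1:n), each = k),
                   time_label = rep(onhmorph:::TIME_LABELS, n),
                   posture = "SEATED",
                   session_order = rep(1:k, n), mrw = as.vector(t(m)))
  ch <- change_from_baseline(co, "mrw")
  bc <- baseline_contrasts(ch, "mrw")
  expect_equal(nrow(bc), 6)
  expect_true(all(bc$p_adj < 0.05))
  expect_lt(abs(mean(bc$mean_change) + 10), 1.5)
  expect_gt(attr(bc, "anova_F"), 10)

  co0 <- co; co0$mrw <- rep(base, each = k)
  expect_error(baseline_contrasts(change_from_baseline(co0, "mrw"), "mrw"),
               class = "onh_degenerate_error")
})

test_that("subjects with missing sessions are dropped listwise", {
  set.seed(9)
  n <- 10; k <- 7
  m <- matrix(rnorm(n * k, 350, 5), n, k)
  co <- data.frame(subject_id = rep(sprintf("S%02d", 1:n), each = k),
                   time_label = rep(onhmorph:::TIME_LABELS, n),
                   posture = "SEATED",
                   session_order = rep(1:k, n), mrw = as.vector(t(m)))
  co$mrw[co$subject_id == "S03" & co$session_order == 4] <- NA
  bc <- baseline_contrasts(change_from_baseline(co, "mrw"), "mrw")
  expect_equal(attr(bc, "n_subjects"), 9)
  expect_equal(attr(bc, "dropped"), "S03")
})

test_that("ols matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5); y <- 2 * x + 1
  f <- suppressWarnings(ols(x, y))  # exact fit: summary.lm warns
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1)

  set.seed(10)
  x5 <- rnorm(5); y5 <- rnorm(5)
  f5 <- ols(x5, y5)
  sxx <- sum((x5 - mean(x5))^2)
  slope <- sum((x5 - mean(x5)) * (y5 - mean(y5))) / sxx
  expect_equal(f5$slope, slope, tolerance = 1e-10)
  expect_equal(f5$intercept, mean(y5) - slope * mean(x5), tolerance = 1e-10)

  yind <- rnorm(2000)
  expect_lt(ols(rnorm(2000), yind)$r2, 0.01)
  expect_error(ols(rep(1, 5), 1:5), class = "onh_degenerate_error")
  expect_error(ols(1:2, 1:2), class = "onh_schema_error")
})

test_that("r2 is invariant to affine rescaling of x and y", {
  set.seed(12)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30)
  r2 <- ols(x, y)$r2
  expect_equal(ols(3 * x - 7, -2 * y + 11)$r2, r2, tolerance = 1e-12)
})

test_that("multiple_ols recovers exact coefficients and flags collinearity", {
  set.seed(13)
  x1 <- rnorm(40); x2 <- rnorm(40)
  y <- 3 - 2 * x1 + 0 * x2
  f <- suppressWarnings(multiple_ols(y, x1, x2))  # exact fit warns
  expect_equal(unname(f$coefficients), c(3, -2, 0), tolerance = 1e-10)
  expect_equal(f$r2, 1)
  expect_error(multiple_ols(y, x1, x1), class = "onh_degenerate_error")
})

test_that("multiple_ols per-coefficient type-I error is near nominal", {
  set.seed(14)
  hits <- 0L
  reps <- 400
  for (i in seq_len(reps)) {
    x1 <- rnorm(30); x2 <- rnorm(30); y <- rnorm(30)
    hits <- hits + (multiple_ols(y, x1, x2)$p_values[["x1"]] < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.03)
})

test_that("group_compare: identical, shifted, paired, and degenerate", {
  expect_equal(group_compare(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$p, 1)
  expect_error(group_compare(c(1, 1, 2), c("a", "a", "b")),
               class = "onh_schema_error")
  expect_error(group_compare(1:4, rep("a", 4)), class = "onh_schema_error")

  # sex-contrast scenario: delta 8 um, sd 7, n 15/15 detects majority of reps
  set.seed(15)
  sig <- 0L
  for (i in 1:60) {
    v <- c(rnorm(15, -13.56, 7.2), rnorm(15, -5.55, 6.9))
    sig <- sig + (group_compare(v, rep(c("F", "M"), each = 15))$p < 0.05)
  }
  expect_gt(sig / 60, 0.5)

  # paired variant aligns on subject_id regardless of row order
  set.seed(16)
  subj <- sprintf("S%02d", 1:12)
  a <- rnorm(12); b <- a + 5 + rnorm(12, 0, 0.1)
  perm <- sample(12)
  g <- group_compare(c(a, b[perm]), rep(c("x", "y"), each = 12),
                     paired = TRUE, subject_id = c(subj, subj[perm]))
  expect_equal(g$estimate, mean(a - b), tolerance = 1e-9)
  expect_lt(g$p, 1e-10)
})
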