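# Independent oracles: brute-force / dense-sampling / closed-form routes
# that never share code with the implementation paths they check.

# minimum distance from point p = c(s, z) to a polyline, by resampling the
# polyline at `step` um and taking the nearest sample
oracle_min_dist <- function(p, s, z, s_lo, s_hi, step = 0.1) {
  grid <- seq(s_lo, s_hi, by = step)
  zg <- approx(s, z, grid, ties = "ordered")$y
  sqrt(min((grid - p[1])^2 + (zg - p[2])^2))
}

# trapezoidal mean over the valid arcs of a periodic angular signal
oracle_circular_mean <- function(theta, x, valid) {
  n <- length(theta)
  th <- c(theta, theta[1] + 360)
  xx <- c(x, x[1])
  vv <- c(valid, valid[1])
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (vv[i] && vv[i + 1]) {
      h <- th[i + 1] - th[i]
      num <- num + h * (xx[i] + xx[i + 1]) / 2
      den <- den + h
    }
  }
  num / den
}

# mean signed perpendicular distance from a curve z(s) to the chord
# p1 -> p2, clipped to feet in the central 50% of the chord, by dense
# numeric integration
oracle_alcsd <- function(fz, s_range, p1, p2, step = 0.5) {
  sg <- seq(s_range[1], s_range[2], by = step)
  zg <- fz(sg)
  L <- sqrt(sum((p2 - p1)^2))
  u <- (p2 - p1) / L
  nv <- c(-u[2], u[1]); if (nv[2] < 0) nv <- -nv
  fr <- ((sg - p1[1]) * u[1] + (zg - p1[2]) * u[2]) / L
  keep <- fr >= 0.25 & fr <= 0.75
  mean((sg[keep] - p1[1]) * nv[1] + (zg[keep] - p1[2]) * nv[2])
}

# nonlinear least-squares ellipse oracle: minimises summed squared distance
# of the data to a densely sampled boundary polygon over (cx, cy, a, b, phi)
oracle_ellipse_nls <- function(xy, start) {
  boundary <- function(par, m = 2000) {
    t <- seq(0, 2 * pi, length.out = m)
    cbind(par[1] + par[3] * cos(t) * cos(par[5]) -
            par[4] * sin(t) * sin(par[5]),
          par[2] + par[3] * cos(t) * sin(par[5]) +
            par[4] * sin(t) * cos(par[5]))
  }
  obj <- function(par) {
    bd <- boundary(par)
    sum(apply(xy, 1, function(p)
      min((bd[, 1] - p[1])^2 + (bd[, 2] - p[2])^2)))
  }
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(a = max(fit$par[3:4]), b = min(fit$par[3:4]), par = fit$par)
}

# Monte-Carlo null of the balanced many-to-one max-|t| statistic
oracle_dunnett_mc <- function(q, k, df, B = 2e5, seed = 99) {
  set.seed(seed)
  z0 <- rnorm(B)
  mx <- rep(0, B)
  for (i in seq_len(k)) {
    mx <- pmax(mx, abs(rnorm(B) - z0))
  }
  s <- sqrt(rchisq(B, df) / df)
  mean(mx / (s * sqrt(2)) <= q)
}

# randomized-but-physical phantom specs (noise-free for oracle equivalence)
random_phantom_spec <- function(seed, noise_sd = 0) {
  set.seed(seed)
  phantom_spec(
    a = runif(1, 750, 1050), b = runif(1, 600, 740),
    orientation_deg = runif(1, 0, 180), tilt_deg = runif(1, -6, 6),
    bmo_z = runif(1, -160, -50), rim_h = runif(1, 340, 450),
    cup_depth = runif(1, 0, 600), cup_power = sample(2:3, 1),
    trt_slope = runif(1, -0.08, -0.04), bm_slope_x = runif(1, -0.05, 0.05),
    lamina_depth = runif(1, 350, 520), lamina_curv = runif(1, 0, 30),
    noise_sd = noise_sd, seed = seed)
}

# single synthetic B-scan built by hand (flat shelf geometry unless
# overridden); convenient for closed-form unit cases
flat_bscan <- function(index = 0, angle = 0, R = 800, rim = 350,
                       ilm_s = NULL, ilm_z = NULL,
                       bm_s = seq(-2500, 2500, by = 100),
                       bm_z = rep(0, 51),
                       bmo_left = c(-800, 0), bmo_right = c(800, 0),
                       alcs = NULL) {
  if (is.null(ilm_s)) {
    ilm_s <- seq(-2500, 2500, by = 100)
    ilm_z <- rep(rim, length(ilm_s))
  }
  radial_bscan(index, angle,
               ilm = layer_polyline(ilm_s, ilm_z, "ILM"),
               bm = layer_polyline(bm_s, bm_z, "BM"),
               bmo_left = bmo_left, bmo_right = bmo_right, alcs = alcs)
}
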