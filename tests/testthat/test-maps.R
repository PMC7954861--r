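# Zone assignment, spatiotemporal maps, rotation fits, lateral scatter.

test_that("zone assignment follows the half-open boundary rule", {
  zc <- zone_config()
  expect_equal(as.character(assign_zones(c(100, 250, 699.9, 700, 1000), zc)),
               c("MZ", "EZ", "EZ", "DZ", "DZ"))
  expect_warning(z <- assign_zones(c(-5, 10), zc), "clamped")
  expect_equal(as.character(z), c("MZ", "MZ"))
})

test_that("assigned zones reproduce simulator truth labels exactly", {
  cfg <- quiet_config(n_nuclei = 200, n_frames = 6, seed = 1)
  tr <- simulate_root(cfg)
  nu <- tr$nuclei
  z <- assign_zones(nu, zone_config(tip_mode = "config"), tip = 0)
  expect_equal(as.character(z), as.character(nu$zone))
})

test_that("tip estimation tracks a low quantile of axial positions", {
  cfg <- quiet_config(n_nuclei = 500, n_frames = 4, seed = 2)
  nu <- simulate_root(cfg)$nuclei
  tip <- estimate_tip(nu, zone_config())
  expect_true(all(tip >= 0 & tip < 60))
})

test_that("spatiotemporal maps aggregate conservatively", {
  cfg <- quiet_config(n_nuclei = 150, n_frames = 8, seed = 3)
  kin <- compute_kinematics(truth_track_set(simulate_root(cfg)))
  kin <- kin[is.finite(kin$vy), ]
  m <- spatiotemporal_map(kin, "vy", axial_bin = 50,
                          config = zone_config(tip_mode = "config"), tip = 0)
  expect_equal(sum(m$counts), nrow(kin))           # conservation
  expect_equal(dim(m$values), dim(m$counts))
  expect_true(all(is.na(m$values[m$counts == 0])))
  # uniform statistic -> every non-empty bin equals it
  kin$const <- 7.5
  mc <- spatiotemporal_map(kin, "const", axial_bin = 50)
  expect_true(all(abs(mc$values[mc$counts > 0] - 7.5) < 1e-12))
  # elongation-zone rows sit at the plateau, meristem rows below
  ez_rows <- which(m$axial_mid > 300 & m$axial_mid < 700)
  mz_rows <- which(m$axial_mid < 150)
  expect_gt(min(m$values[ez_rows, ], na.rm = TRUE), 45)
  expect_lt(mean(m$values[mz_rows, ], na.rm = TRUE), 40)
})

test_that("rotation fit recovers exact rigid rotations and rejects degenerate input", {
  set.seed(4)
  om <- c(0.05, 0.4, -0.1)
  ctr <- c(5, 120, -3)
  P <- cbind(runif(30, -40, 40), runif(30, 0, 250), runif(30, -40, 40))
  V <- t(apply(P, 1, function(p) rootkin:::cross3(om, p - ctr)))
  fit <- skewing_rotation_fit(P, V)
  expect_equal(fit$omega, om, tolerance = 1e-9)
  expect_equal(fit$omega_mag, sqrt(sum(om^2)), tolerance = 1e-9)
  expect_lt(fit$residual_rms, 1e-9)

  # pure translation: no rotation
  Vt <- matrix(rep(c(3, 1, -2), each = 30), ncol = 3)
  expect_lt(skewing_rotation_fit(P, Vt)$omega_mag, 1e-9)

  # collinear points are degenerate
  Pc <- cbind(0, seq_len(6), 0)
  expect_error(skewing_rotation_fit(Pc, Pc * 0), "degenerate")
})

test_that("rotation fit tolerates measurement jitter (Monte-Carlo)", {
  set.seed(5)
  om <- c(0, 0.4, 0)
  P <- cbind(runif(120, -50, 50), runif(120, 0, 250), runif(120, -50, 50))
  V <- t(apply(P, 1, function(p) rootkin:::cross3(om, p)))
  V <- V + matrix(rnorm(length(V), sd = 0.5 / 0.1458), ncol = 3) * 0.1458
  fit <- skewing_rotation_fit(P, V)
  expect_lt(abs(fit$omega_mag - 0.4) / 0.4, 0.1)
})

test_that("lateral scatter summaries match the Rayleigh oracle", {
  k0 <- data.frame(vx = 0, vz = 0, t_h = rep(0:3, each = 5))
  s0 <- xz_velocity_scatter(k0)
  expect_true(all(s0$mean_lateral_speed == 0))
  set.seed(6)
  sig <- 3
  k <- data.frame(vx = rnorm(20000, sd = sig), vz = rnorm(20000, sd = sig),
                  t_h = 0)
  s <- xz_velocity_scatter(k)
  expect_equal(s$mean_lateral_speed, sig * sqrt(pi / 2), tolerance = 0.02)
  expect_equal(s$cov_xx, sig^2, tolerance = 0.05 * sig^2)
  expect_equal(s$n, 20000L)
})

test_that("skew suppression reduces late-movie lateral speed", {
  cfg <- simulation_config(n_nuclei = 250, seed = 7,
                           noise = list(false_positive_rate = 0))
  sup <- apply_scenario(simulate_root(cfg),
                        list(label = "auxin_induction",
                             skew_suppression = TRUE, skew_decay = 1))
  kin <- compute_kinematics(truth_track_set(sup))
  kin$zone <- assign_zones(kin, zone_config(tip_mode = "config"), tip = 0)
  mz <- kin[kin$zone == "MZ" & is.finite(kin$vx), ]
  s <- xz_velocity_scatter(mz, time_bin = 1.5)
  expect_lt(tail(s$mean_lateral_speed, 1), head(s$mean_lateral_speed, 1))
})

test_that("map export writes a readable CSV", {
  cfg <- quiet_config(n_nuclei = 60, n_frames = 5, seed = 8)
  kin <- compute_kinematics(truth_track_set(simulate_root(cfg)))
  m <- spatiotemporal_map(kin[is.finite(kin$vy), ], "vy")
  path <- tempfile(fileext = ".csv")
  write_st_map(m, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(m$values))
  expect_equal(ncol(back), length(m$frames) + 1)
})
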