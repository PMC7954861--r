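# Kinematics: finite differences, angles, coordinated motility, features.

straight_track <- function(step, n, dt_h, start = c(0, 0, 0)) {
  P <- t(sapply(0:(n - 1), function(i) start + i * step))
  data.frame(track_id = 1L, frame = seq_len(n), t_h = (0:(n - 1)) * dt_h,
             x_um = P[, 1], y_um = P[, 2], z_um = P[, 3], gap = FALSE)
}

test_that("velocity, speed and velocity-total follow hand arithmetic", {
  # 50 um in Y over 1 h
  tk <- straight_track(c(0, 50, 0), n = 3, dt_h = 1)
  k <- compute_kinematics(tk, kinetics_config("central"))
  expect_equal(k$vy[2], 50)
  expect_equal(k$speed[2], 50)
  expect_true(is.na(k$vy[1]) && is.na(k$vy[3]))  # boundary markers

  # 3-4-0 steps per 0.1 h: speed 50, velocity_total 70, disp^2 100 at step 2
  tk2 <- straight_track(c(3, 4, 0), n = 6, dt_h = 0.1)
  k2 <- compute_kinematics(tk2, kinetics_config("forward"))
  expect_equal(k2$speed[1], 50)
  expect_equal(k2$velocity_total[1], 70)
  expect_equal(k2$disp2[3], 100)   # after 2 steps: (6, 8, 0)
  # constant velocity: zero acceleration at interior samples
  expect_equal(max(k2$a_mag[is.finite(k2$a_mag)]), 0)
})

test_that("single-sample tracks are rejected", {
  tk <- straight_track(c(0, 1, 0), n = 1, dt_h = 1)
  expect_error(compute_kinematics(tk), "single sample")
})

test_that("instantaneous angle matches its defining geometry", {
  expect_equal(instantaneous_angle(c(0, 1, 0)), 0)
  expect_equal(instantaneous_angle(c(1, 0, 0)), 90)
  expect_equal(instantaneous_angle(c(1, 1, 0)), 45)
  expect_equal(instantaneous_angle(c(0, -2, 0)), 180)
  expect_true(is.na(instantaneous_angle(c(0, 0, 0))))
})

test_that("coordinated motility matches analytic cases", {
  cfgk <- kinetics_config(cm_radius = 200, cm_min_neighbors = 1)
  P <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  # all parallel
  V <- rbind(c(0, 1, 0), c(0, 2, 0), c(0, 5, 0))
  expect_equal(coordinated_motility(P, V, 1, cfgk)$cm, 1)
  # single anti-parallel neighbour
  P2 <- rbind(c(0, 0, 0), c(10, 0, 0))
  V2 <- rbind(c(0, 1, 0), c(0, -1, 0))
  expect_equal(coordinated_motility(P2, V2, 1, cfgk)$cm, -1)
  # one parallel + one orthogonal -> mean cosine 0.5
  V3 <- rbind(c(0, 1, 0), c(0, 3, 0), c(1, 0, 0))
  expect_equal(coordinated_motility(P, V3, 1, cfgk)$cm, 0.5)
  # neighbours outside the radius are excluded
  P4 <- rbind(c(0, 0, 0), c(500, 0, 0))
  expect_true(is.na(coordinated_motility(P4, V2, 1, cfgk)$cm))
  # zero-norm neighbour velocities are excluded but counted
  V5 <- rbind(c(0, 1, 0), c(0, 0, 0), c(0, 1, 0))
  r5 <- coordinated_motility(P, V5, 1, cfgk)
  expect_equal(r5$cm, 1)
})

test_that("CM is exactly 1 for uniform translation, ~0 for isotropic noise", {
  set.seed(11)
  n <- 1001
  P <- matrix(runif(3 * n, 0, 100), ncol = 3)   # everyone within 200 um
  V <- matrix(rep(c(3, 4, 0), each = n), ncol = 3)
  cfgk <- kinetics_config(cm_radius = 200)
  for (ctr in sample(n, 5)) {
    expect_equal(coordinated_motility(P, V, ctr, cfgk)$cm, 1)
  }
  # isotropic random unit velocities, 1000 neighbours
  U <- matrix(rnorm(3 * n), ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  r <- coordinated_motility(P, U, 1, cfgk)
  expect_equal(r$n_neighbors, 1000)
  expect_lt(abs(r$cm), 3 / sqrt(r$n_neighbors))
})

test_that("kinematics are invariant under a common rotation", {
  cfg <- quiet_config(n_nuclei = 40, n_frames = 8, seed = 12)
  cfg$skew$omega <- 0.3
  kin <- add_coordination(compute_kinematics(
    truth_track_set(simulate_root(cfg))))
  th <- 0.7
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  rot <- kin[, c("track_id", "frame", "t_h", "x_um", "y_um", "z_um", "gap")]
  Pr <- cbind(kin$x_um, kin$y_um, kin$z_um) %*% t(R)
  rot$x_um <- Pr[, 1]; rot$y_um <- Pr[, 2]; rot$z_um <- Pr[, 3]
  kin_r <- add_coordination(compute_kinematics(rot))
  i <- is.finite(kin$speed)
  expect_equal(kin_r$speed[i], kin$speed[i], tolerance = 1e-9)
  expect_equal(kin_r$disp2, kin$disp2, tolerance = 1e-9)
  expect_equal(kin_r$cm[i], kin$cm[i], tolerance = 1e-9)
  # theta is invariant only under rotations about the Y axis (this one is)
  expect_equal(kin_r$theta_deg[i], kin$theta_deg[i], tolerance = 1e-9)
})

test_that("feature summary covers the manifest and known motion classes", {
  man <- feature_manifest()
  expect_gte(nrow(man), 36)
  dt_h <- 0.1
  # ballistic track: directionality 1, MSD slope 2
  tk <- straight_track(c(1, 2, 2), n = 60, dt_h = dt_h)
  fx <- cell_feature_summary(compute_kinematics(tk), delta_t_min = dt_h * 60)
  expect_true(all(man$feature %in% names(fx)))
  expect_equal(fx$directionality_ratio, 1, tolerance = 1e-9)
  expect_equal(fx$msd_slope, 2, tolerance = 0.05)
  expect_equal(fx$speed_mean, 30, tolerance = 1e-9)  # |(1,2,2)| / 0.1 h

  # pure random walk: MSD slope 1 (diffusion oracle at large n)
  set.seed(13)
  n <- 1500
  P <- apply(matrix(rnorm(3 * n), ncol = 3), 2, cumsum)
  rw <- data.frame(track_id = 1L, frame = seq_len(n),
                   t_h = (seq_len(n) - 1) * dt_h,
                   x_um = P[, 1], y_um = P[, 2], z_um = P[, 3], gap = FALSE)
  frw <- cell_feature_summary(compute_kinematics(rw), delta_t_min = dt_h * 60)
  expect_equal(frw$msd_slope, 1, tolerance = 0.1)

  # stationary track: zero velocity features, undefined directionality
  st <- straight_track(c(0, 0, 0), n = 10, dt_h = dt_h)
  fst <- cell_feature_summary(compute_kinematics(st), delta_t_min = 6)
  expect_equal(fst$speed_mean, 0)
  expect_equal(fst$vy_max, 0)
  expect_true(is.na(fst$directionality_ratio))
})

test_that("gap-adjacent velocities are flagged from_gap", {
  pos <- lapply(1:8, function(f) if (f == 4) NULL else rbind(c(0, 6 * f, 0)))
  ts <- link_tracks(manual_frames(pos))
  k <- compute_kinematics(ts)
  expect_true(k$from_gap[k$frame == 4])
  expect_true(all(k$from_gap[k$frame %in% 3:5]))   # central stencil touches gap
  expect_false(any(k$from_gap[k$frame %in% c(2, 7)]))
})
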