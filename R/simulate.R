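# Root-growth simulator: ground-truth trajectories with zone-dependent axial
# velocity, meristem rigid-rotation skewing, whole-root lateral drift,
# meristem cell division and phenomenological reporter dynamics.

# --- scenario machinery -----------------------------------------------------

known_scenarios <- c("control", "auxin_induction", "exogenous_IAA")

# Normalise a scenario list, filling defaults. Axial speeds are multiplied by
# a time profile that rises to a peak at t_peak and then declines
# exponentially; skew suppression decays omega to zero; dose scales the
# reporter amplitude and the auxin level driving ratiometric reporters.
normalize_scenario <- function(scenario) {
  label <- scenario$label %||% "control"
  if (!label %in% known_scenarios) {
    stop("unknown scenario label: ", label, call. = FALSE)
  }
  if (label == "control") return(list(label = "control"))
  sc <- list(label = label,
             t_peak = scenario$t_peak %||% 0.5,
             rise_amp = scenario$rise_amp %||% 0.2,
             decay_rate = scenario$decay_rate %||% 0.5,
             skew_suppression = scenario$skew_suppression %||% TRUE,
             skew_decay = scenario$skew_decay %||% 1,
             dose = scenario$dose %||% 1,
             auxin_tau = scenario$auxin_tau %||% 1)
  if (label == "exogenous_IAA") {
    # dose scaling: stronger dose => faster/deeper velocity decline
    sc$decay_rate <- (scenario$decay_rate %||% 0.3) * sc$dose
  }
  sc
}

# Multiplier on the axial velocity field at time t (hours).
scenario_axial_profile <- function(sc, t) {
  if (sc$label == "control") return(rep(1, length(t)))
  rise <- 1 + sc$rise_amp * pmin(t / sc$t_peak, 1)
  rise * exp(-sc$decay_rate * pmax(0, t - sc$t_peak))
}

# Multiplier on the skew angular rate at time t.
scenario_skew_profile <- function(sc, t) {
  if (sc$label == "control" || !isTRUE(sc$skew_suppression)) {
    return(rep(1, length(t)))
  }
  exp(-sc$skew_decay * t)
}

# Auxin level (a.u.) at time t; zero for control, saturating rise otherwise.
scenario_auxin_level <- function(sc, t) {
  if (sc$label == "control") return(rep(0, length(t)))
  sc$dose * (1 - exp(-t / sc$auxin_tau))
}

scenario_reporter_scale <- function(sc) {
  if (sc$label == "control") 1 else sc$dose
}

# --- velocity field ---------------------------------------------------------

# Instantaneous true velocity field evaluated at positions P (n x 3, tip
# frame, um) and time t (h). Returns an n x 3 matrix in um/h.
sim_velocity_field <- function(P, t, cfg, sc) {
  y <- P[, 2]
  ax <- scenario_axial_profile(sc, t) * cfg$axial$v_plateau *
    logistic((y - cfg$axial$y_mid) / cfg$axial$width)
  V <- cbind(0, ax, 0)
  om <- cfg$skew$omega * scenario_skew_profile(sc, t)
  if (om != 0) {
    w <- logistic((cfg$skew$meristem_extent - y) / cfg$skew$taper)
    Cm <- cross_mat(tilted_axis(cfg$skew$axis_tilt))
    V <- V + (om * w) * (P %*% t(Cm))
  }
  if (cfg$lateral_drift$speed > 0) {
    ang <- 2 * pi * t / cfg$lateral_drift$period
    V[, 1] <- V[, 1] + cfg$lateral_drift$speed * cos(ang)
    V[, 3] <- V[, 3] + cfg$lateral_drift$speed * sin(ang)
  }
  V
}

# RK4 step of the full field over dt hours.
sim_rk4_step <- function(P, t, dt, cfg, sc) {
  k1 <- sim_velocity_field(P, t, cfg, sc)
  k2 <- sim_velocity_field(P + dt / 2 * k1, t + dt / 2, cfg, sc)
  k3 <- sim_velocity_field(P + dt / 2 * k2, t + dt / 2, cfg, sc)
  k4 <- sim_velocity_field(P + dt * k3, t + dt, cfg, sc)
  P + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# --- reporter ---------------------------------------------------------------

reporter_intensity <- function(y, t, cfg, sc) {
  rp <- cfg$reporter
  tt <- pmax(0, t - rp$onset_delay)
  temporal <- ifelse(t < rp$onset_delay, 0, 1 - exp(-tt / rp$rise_time))
  spatial <- exp(-(y - rp$spatial_origin)^2 / (2 * rp$spatial_width^2))
  rp$baseline + scenario_reporter_scale(sc) * rp$amplitude * temporal * spatial
}

# --- zones ------------------------------------------------------------------

zone_of <- function(dist_from_tip, zones) {
  z <- ifelse(dist_from_tip < zones$meristem_end, "MZ",
              ifelse(dist_from_tip < zones$elongation_end, "EZ", "DZ"))
  factor(z, levels = c("MZ", "EZ", "DZ"))
}

# --- main entry -------------------------------------------------------------

#' Simulate a growing root with ground-truth nucleus trajectories
#'
#' Seeds nuclei in a cylinder spanning meristem, elongation and
#' differentiation zones and advects them through a zone-dependent axial
#' velocity field (sigmoidal ramp from ~0 at the tip to the elongation
#' plateau), plus, for meristem nuclei, a rigid rotation about an axis tilted
#' from the root axis (producing anti-parallel lateral velocities on opposite
#' flanks of the root diameter), plus a gentle whole-root lateral drift.
#' Meristem nuclei divide as a Poisson process; the two children of a
#' division first appear at the parent's last position +/- a small offset and
#' carry the parent id. Reproducible for a fixed seed.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `root_truth`: a list with `nuclei` (data frame
#'   of per-nucleus, per-frame true positions, velocities, zone labels,
#'   reporter and auxin levels), `tip` (tip position per frame) and the
#'   originating `config`.
#' @examples
#' cfg <- simulation_config(n_nuclei = 50, n_frames = 5, seed = 7)
#' tr <- simulate_root(cfg)
#' head(tr$nuclei)
#' @export
simulate_root <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  sc <- normalize_scenario(cfg$scenario)
  dt_h <- cfg$frame_interval / 60
  nf <- cfg$n_frames

  with_seed(cfg$seed, {
    n <- cfg$n_nuclei
    # seed uniformly along the axis and uniformly over the disk cross-section
    y0 <- runif(n, min = 5, max = cfg$root_length)
    rho <- cfg$root_radius * sqrt(runif(n))
    phi <- runif(n, 0, 2 * pi)
    P <- cbind(rho * cos(phi), y0, rho * sin(phi))
    ids <- seq_len(n)
    parent <- rep(NA_integer_, n)
    next_id <- n + 1L
    division_offset <- 1.5  # um, half the 3-um sibling separation

    frames <- vector("list", nf)
    for (f in seq_len(nf)) {
      t <- (f - 1) * dt_h
      V <- sim_velocity_field(P, t, cfg, sc)
      y <- P[, 2]
      frames[[f]] <- data.frame(
        nucleus_id = ids, parent_id = parent, frame = f, t_h = t,
        x_um = P[, 1], y_um = y, z_um = P[, 3],
        vx = V[, 1], vy = V[, 2], vz = V[, 3],
        zone = zone_of(y, cfg$zones),
        reporter = reporter_intensity(y, t, cfg, sc),
        auxin = scenario_auxin_level(sc, t))
      if (f == nf) break

      # advect to the next frame with RK4 substeps
      sub <- cfg$n_substeps
      dt_sub <- dt_h / sub
      for (s in seq_len(sub)) {
        P <- sim_rk4_step(P, t + (s - 1) * dt_sub, dt_sub, cfg, sc)
      }

      # meristem divisions: parent track ends at frame f, children first
      # appear at the next frame at the parent's last position +/- offset
      if (cfg$division_rate > 0) {
        in_mz <- which(frames[[f]]$y_um < cfg$skew$meristem_extent)
        p_div <- 1 - exp(-cfg$division_rate * dt_h)
        div <- in_mz[runif(length(in_mz)) < p_div]
        if (length(div) > 0) {
          for (k in div) {
            u <- rnorm(3)
            u <- u / vec_norm(u) * division_offset
            p_last <- c(frames[[f]]$x_um[k], frames[[f]]$y_um[k],
                        frames[[f]]$z_um[k])
            kids <- rbind(p_last + u, p_last - u)
            # keep children inside the root cylinder
            for (ci in 1:2) {
              r <- sqrt(kids[ci, 1]^2 + kids[ci, 3]^2)
              if (r > cfg$root_radius) {
                kids[ci, c(1, 3)] <- kids[ci, c(1, 3)] * cfg$root_radius / r
              }
            }
            P <- rbind(P, kids)
            parent <- c(parent, rep(ids[k], 2))
            ids <- c(ids, next_id, next_id + 1L)
            next_id <- next_id + 2L
          }
          # remove parents (they divided; their last sample is frame f)
          keep <- setdiff(seq_along(ids), div)
          P <- P[keep, , drop = FALSE]
          ids <- ids[keep]
          parent <- parent[keep]
        }
      }
    }

    nuclei <- do.call(rbind, frames)
    nuclei <- nuclei[order(nuclei$nucleus_id, nuclei$frame), ]
    rownames(nuclei) <- NULL
    tip <- data.frame(frame = seq_len(nf), t_h = (seq_len(nf) - 1) * dt_h,
                      x_um = cfg$tip_position[1], y_um = cfg$tip_position[2],
                      z_um = cfg$tip_position[3])
    structure(list(nuclei = nuclei, tip = tip, config = cfg),
              class = "root_truth")
  })
}

#' Apply a kinematic scenario to a simulated root
#'
#' Re-simulates the root (same seed and geometry) under a scenario that
#' modulates the kinematics over time: `control` is the identity;
#' `auxin_induction` multiplies axial velocities by a profile rising to a
#' peak at `t_peak` and then declining exponentially at `decay_rate`, and
#' (optionally) decays the skew rotation to zero; `exogenous_IAA` is the same
#' with the decline scaled by `dose`. Reporter intensities keep their
#' configured onset delay; the auxin level column (driving ratiometric
#' reporters) rises after induction.
#'
#' @param truth a `root_truth` object from [simulate_root()].
#' @param scenario list with `label` (one of `"control"`,
#'   `"auxin_induction"`, `"exogenous_IAA"`) plus optional parameters
#'   `t_peak` (h), `rise_amp`, `decay_rate` (1/h), `skew_suppression`,
#'   `skew_decay` (1/h), `dose`.
#' @return a `root_truth` with the scenario applied.
#' @export
apply_scenario <- function(truth, scenario) {
  stopifnot(inherits(truth, "root_truth"))
  normalize_scenario(scenario)  # validates the label
  cfg <- truth$config
  cfg$scenario <- scenario
  simulate_root(cfg)
}

#' @export
print.root_truth <- function(x, ...) {
  cat("<root_truth>\n")
  cat(sprintf("  %d nuclei over %d frames (%s scenario)\n",
              length(unique(x$nuclei$nucleus_id)), max(x$nuclei$frame),
              x$config$scenario$label %||% "control"))
  cat(sprintf("  %d division lineages\n",
              length(unique(stats::na.omit(x$nuclei$parent_id)))))
  invisible(x)
}

#' True meristem-vs-elongation lateral-speed excess
#'
#' Mean lateral speed `sqrt(vx^2 + vz^2)` of meristem-zone samples minus
#' that of elongation-zone samples, computed on the noiseless ground truth.
#'
#' @param truth a `root_truth`.
#' @return excess in um/h.
#' @export
lateral_speed_excess <- function(truth) {
  nu <- truth$nuclei
  lat <- sqrt(nu$vx^2 + nu$vz^2)
  mean(lat[nu$zone == "MZ"]) - mean(lat[nu$zone == "EZ"])
}

#' Calibrate the skew rotation rate to a target lateral-speed excess
#'
#' Finds, by secant iteration on the noiseless ground truth, the meristem
#' angular rate `omega` at which the true meristem-zone mean lateral speed
#' exceeds the elongation-zone mean by `target_excess` um/h (the reference
#' experiment reports an excess of about 10 um/h). Deterministic for a fixed
#' config seed.
#'
#' @param config a [simulation_config()]; its `skew$omega` is replaced.
#' @param target_excess target excess, um/h.
#' @param tol convergence tolerance on the excess, um/h.
#' @param max_iter maximum secant iterations.
#' @return the calibrated config (with `skew$omega` set).
#' @export
calibrate_skew_omega <- function(config, target_excess = 10, tol = 0.01,
                                 max_iter = 8L) {
  f <- function(om) {
    cfg <- config
    cfg$skew$omega <- om
    lateral_speed_excess(simulate_root(cfg))
  }
  om1 <- 0.2; om2 <- 0.5
  e1 <- f(om1); e2 <- f(om2)
  for (i in seq_len(max_iter)) {
    if (abs(e2 - target_excess) < tol) break
    om3 <- om2 + (target_excess - e2) * (om2 - om1) / (e2 - e1)
    om1 <- om2; e1 <- e2
    om2 <- om3; e2 <- f(om2)
  }
  config$skew$omega <- om2
  config
}

#' Ground truth as a perfectly linked track set
#'
#' Converts simulator ground truth into a `track_set` (one noiseless track
#' per nucleus, no gaps), bypassing rendering and linking. Useful as a
#' tracking oracle and for cohort-level analyses where detection noise is
#' not under study. Nuclei observed in fewer than two frames (e.g. children
#' born at the last frame) are dropped.
#'
#' @param truth a `root_truth`.
#' @return a `track_set` whose `truth_id` equals the nucleus id.
#' @export
truth_track_set <- function(truth) {
  stopifnot(inherits(truth, "root_truth"))
  nu <- truth$nuclei
  keep <- names(which(table(nu$nucleus_id) >= 2))
  nu <- nu[nu$nucleus_id %in% as.integer(keep), ]
  tracks <- data.frame(track_id = nu$nucleus_id, frame = nu$frame,
                       t_h = nu$t_h, x_um = nu$x_um, y_um = nu$y_um,
                       z_um = nu$z_um, gap = FALSE,
                       det_id = NA_integer_, truth_id = nu$nucleus_id,
                       ch_reporter = nu$reporter)
  structure(list(tracks = tracks, config = tracking_config(),
                 delta_t_min = truth$config$frame_interval,
                 stats = list(source = "ground_truth")),
            class = "track_set")
}

#' Write ground truth to CSV (with a JSON config echo alongside)
#'
#' @param truth a `root_truth`.
#' @param path CSV output path; the configuration is echoed to
#'   `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "root_truth"))
  utils::write.csv(truth$nuclei, path, row.names = FALSE)
  jsonlite::write_json(unclass(truth$config), paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
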