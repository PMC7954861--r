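#' Simulation configuration for a synthetic growing root
#'
#' Builds and validates the configuration of the root-growth simulator.
#' Defaults encode the imaging geometry and kinematics of the reference
#' experiment: 40 frames at 8.75-min intervals (6 h), an elongation-zone
#' axial-velocity plateau of 50 um/h, meristem skewing as a rigid rotation
#' sized to give the meristem a ~10 um/h lateral-speed excess over the
#' elongation zone, around 1000 nuclei spanning meristem, elongation and
#' differentiation zones, and a reporter that switches on ~2.5 h after
#' induction.
#'
#' Coordinates are right-handed, in micrometres, with the root axis along +Y
#' pointing shootward and the tip at the origin of the (tip-registered)
#' imaging frame. Time is handled in hours internally; the frame interval is
#' configured in minutes.
#'
#' @param n_nuclei number of nuclei seeded at the first frame.
#' @param root_radius radius of the root cylinder (um).
#' @param root_length axial extent over which nuclei are seeded (um from tip).
#' @param tip_position 3-vector, tip position in the imaging frame (um).
#'   The default keeps the tip fixed at the origin (tip-registered frame).
#' @param axial list with `v_plateau` (um/h), `y_mid` (um) and `width` (um):
#'   the axial velocity field is
#'   `v(y) = v_plateau * plogis((y - y_mid)/width)`, a monotone sigmoid that
#'   is ~0 at the tip and saturates shootward of the transition zone.
#' @param skew list with `omega` (rad/h), `axis_tilt` (degrees from the root
#'   axis), `meristem_extent` (um from tip within which the rigid rotation
#'   applies) and `taper` (um, smooth roll-off width at the meristem edge).
#' @param lateral_drift list with `speed` (um/h) and `period` (h): gentle
#'   whole-root lateral sway (circumnutation-like) giving the elongation zone
#'   its nonzero lateral baseline; direction rotates in the X-Z plane.
#' @param division_rate meristem cell division rate (events/cell/h).
#' @param frame_interval frame interval in minutes.
#' @param n_frames number of time points.
#' @param noise list with `jitter_sd` (um, isotropic detection jitter),
#'   `dropout_rate` (fraction of true nuclei missed per frame),
#'   `false_positive_rate` (spurious detections per true nucleus per frame)
#'   and `intensity_sd` (a.u., channel noise added at rendering).
#' @param reporter list with `onset_delay` (h), `rise_time` (h),
#'   `spatial_origin` (um from tip, centre of the responding region),
#'   `spatial_width` (um), `baseline` and `amplitude` (a.u.).
#' @param zones list with `meristem_end` and `elongation_end` (um from tip).
#' @param scenario scenario list; see [apply_scenario()]. Default is the
#'   control (identity) scenario.
#' @param seed integer seed; all simulator randomness derives from it.
#' @param n_substeps integration substeps per frame interval (RK4).
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_root()], [render_frames()]
#' @export
simulation_config <- function(n_nuclei = 1000,
                              root_radius = 50,
                              root_length = 1200,
                              tip_position = c(0, 0, 0),
                              axial = list(v_plateau = 50, y_mid = 150, width = 35),
                              skew = list(omega = 0.3, axis_tilt = 10,
                                          meristem_extent = 250, taper = 20),
                              lateral_drift = list(speed = 5, period = 4),
                              division_rate = 0.05,
                              frame_interval = 8.75,
                              n_frames = 40,
                              noise = list(jitter_sd = 0.5, dropout_rate = 0.02,
                                           false_positive_rate = 0.01,
                                           intensity_sd = 2),
                              reporter = list(onset_delay = 2.5, rise_time = 1,
                                              spatial_origin = 450,
                                              spatial_width = 150,
                                              baseline = 10, amplitude = 100),
                              zones = list(meristem_end = 250, elongation_end = 700),
                              scenario = list(label = "control"),
                              seed = 1L,
                              n_substeps = 5L) {
  defaults <- lapply(formals(simulation_config), eval,
                     envir = baseenv())
  axial <- utils::modifyList(defaults$axial, axial)
  skew <- utils::modifyList(defaults$skew, skew)
  lateral_drift <- utils::modifyList(defaults$lateral_drift, lateral_drift)
  noise <- utils::modifyList(defaults$noise, noise)
  reporter <- utils::modifyList(defaults$reporter, reporter)
  zones <- utils::modifyList(defaults$zones, zones)

  cfg <- list(n_nuclei = as.integer(n_nuclei), root_radius = root_radius,
              root_length = root_length, tip_position = tip_position,
              axial = axial, skew = skew, lateral_drift = lateral_drift,
              division_rate = division_rate,
              frame_interval = frame_interval, n_frames = as.integer(n_frames),
              noise = noise, reporter = reporter, zones = zones,
              scenario = scenario, seed = as.integer(seed),
              n_substeps = as.integer(n_substeps))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num <- cfg[c("root_radius", "root_length", "division_rate",
               "frame_interval", "n_frames", "n_nuclei")]
  stopifnot_finite(num, "simulation config")
  stopifnot_finite(cfg$axial, "axial profile")
  stopifnot_finite(cfg$skew, "skew block")
  stopifnot_finite(cfg$noise, "noise block")
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (cfg$n_frames < 2) stop("n_frames must be >= 2")
  if (cfg$axial$width <= 0) stop("axial width must be > 0")
  if (cfg$division_rate < 0) stop("division_rate must be >= 0")
  if (cfg$noise$dropout_rate < 0 || cfg$noise$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (cfg$noise$false_positive_rate < 0 || cfg$noise$false_positive_rate >= 1) {
    stop("false_positive_rate must be in [0, 1)")
  }
  if (cfg$noise$jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (cfg$zones$meristem_end <= 0 ||
      cfg$zones$elongation_end <= cfg$zones$meristem_end) {
    stop("zone boundaries must satisfy 0 < meristem_end < elongation_end")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d nuclei, %d frames at %.2f min (%.2f h)\n",
              x$n_nuclei, x$n_frames, x$frame_interval,
              (x$n_frames - 1) * x$frame_interval / 60))
  cat(sprintf("  axial plateau %.1f um/h (y_mid %.0f, width %.0f)\n",
              x$axial$v_plateau, x$axial$y_mid, x$axial$width))
  cat(sprintf("  skew omega %.3f rad/h (tilt %.1f deg, extent %.0f um)\n",
              x$skew$omega, x$skew$axis_tilt, x$skew$meristem_extent))
  cat(sprintf("  scenario: %s, seed %d\n", x$scenario$label, x$seed))
  invisible(x)
}
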