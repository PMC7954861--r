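# Developmental-zone assignment, zone-resolved spatiotemporal maps, and
# skewing metrics (rigid-rotation fit, lateral-velocity scatter).

#' Zone configuration
#'
#' Boundaries of the developmental zones along the root axis, measured from
#' the tip. The reference maps label meristem (MZ), elongation (EZ) and
#' differentiation (DZ) zones; boundary positions are not instrument-defined
#' and default to 250 um (meristem end) and 700 um (elongation end).
#'
#' @param meristem_end MZ/EZ boundary, um from tip.
#' @param elongation_end EZ/DZ boundary, um from tip.
#' @param tip_mode `"quantile"`: estimate the tip per frame as a low quantile
#'   of detected axial positions (robust to outliers); `"config"`: use a
#'   supplied tip position.
#' @param tip_quantile quantile used by `"quantile"` mode.
#' @return an object of class `zone_config`.
#' @export
zone_config <- function(meristem_end = 250, elongation_end = 700,
                        tip_mode = c("quantile", "config"),
                        tip_quantile = 0.02) {
  tip_mode <- match.arg(tip_mode)
  if (!(0 < meristem_end && meristem_end < elongation_end)) {
    stop("need 0 < meristem_end < elongation_end")
  }
  structure(list(meristem_end = meristem_end,
                 elongation_end = elongation_end,
                 tip_mode = tip_mode, tip_quantile = tip_quantile),
            class = "zone_config")
}

#' Estimate the tip axial position per frame
#'
#' @param samples data frame with `frame` and `y_um`.
#' @param config a [zone_config()].
#' @param tip_y optional numeric: known tip position (recycled per frame);
#'   used when `tip_mode = "config"`.
#' @return named numeric vector, tip Y per frame.
#' @export
estimate_tip <- function(samples, config = zone_config(), tip_y = NULL) {
  frames <- sort(unique(samples$frame))
  if (config$tip_mode == "config" || !is.null(tip_y)) {
    if (is.null(tip_y)) stop("tip_mode = 'config' requires tip_y")
    return(setNames(rep_len(tip_y, length(frames)), frames))
  }
  setNames(vapply(frames, function(f) {
    quantile(samples$y_um[samples$frame == f], config$tip_quantile,
             names = FALSE)
  }, 1), frames)
}

#' Assign developmental zones by axial distance from the tip
#'
#' Labels `MZ` for distances in `[0, meristem_end)`, `EZ` for
#' `[meristem_end, elongation_end)` and `DZ` beyond (half-open intervals).
#' Positions tipward of the tip (negative distance) are clamped into the
#' meristem with a warning.
#'
#' @param samples data frame with `frame` and `y_um` (or a numeric vector of
#'   distances from the tip, in which case `tip` is ignored).
#' @param config a [zone_config()].
#' @param tip tip Y position per frame (named vector from [estimate_tip()]),
#'   a single number, or `NULL` to estimate from the samples.
#' @return factor of zone labels (`MZ`, `EZ`, `DZ`), one per row/element.
#' @export
assign_zones <- function(samples, config = zone_config(), tip = NULL) {
  if (is.numeric(samples) && is.null(dim(samples))) {
    dist <- samples
  } else {
    if (is.null(tip)) tip <- estimate_tip(samples, config)
    if (length(tip) == 1 && is.null(names(tip))) {
      dist <- samples$y_um - tip
    } else {
      dist <- samples$y_um - tip[as.character(samples$frame)]
    }
  }
  if (any(dist < 0, na.rm = TRUE)) {
    warning("positions tipward of the tip clamped into the meristem zone")
    dist <- pmax(dist, 0)
  }
  z <- ifelse(dist < config$meristem_end, "MZ",
              ifelse(dist < config$elongation_end, "EZ", "DZ"))
  factor(z, levels = c("MZ", "EZ", "DZ"))
}

#' Zone-resolved spatiotemporal map of a statistic
#'
#' Bins samples by axial position (um from tip, default 25-um bins) and
#' frame, and records the mean of the chosen statistic per bin, mirroring
#' tip-up kymograph displays (axial distance on one axis, time on the
#' other).
#'
#' @param samples kinematics table with `frame`, `y_um` and the statistic
#'   column.
#' @param statistic column name to aggregate (e.g. `"vy"`, `"speed"`,
#'   `"cm"`, `"ch_reporter"`).
#' @param axial_bin bin width along the axis, um.
#' @param config a [zone_config()] (for the tip estimate).
#' @param tip optional tip position(s), as in [assign_zones()].
#' @return object of class `st_map`: list with `values` (bins x frames matrix
#'   of means; `NA` where empty), `counts`, `axial_mid` (bin centres, um from
#'   tip), `frames`, `statistic` and `orientation = "tip_up"`.
#' @export
spatiotemporal_map <- function(samples, statistic, axial_bin = 25,
                               config = zone_config(), tip = NULL) {
  if (!statistic %in% names(samples)) {
    stop("unknown statistic column: ", statistic)
  }
  val <- samples[[statistic]]
  ok <- is.finite(val) & is.finite(samples$y_um)
  if (!any(ok)) stop("no usable samples for the map")
  samples <- samples[ok, ]
  val <- val[ok]
  if (is.null(tip)) tip <- estimate_tip(samples, config)
  if (length(tip) == 1 && is.null(names(tip))) {
    dist <- samples$y_um - tip
  } else {
    dist <- samples$y_um - tip[as.character(samples$frame)]
  }
  dist <- pmax(dist, 0)
  frames <- sort(unique(samples$frame))
  nbin <- max(1L, ceiling(max(dist) / axial_bin))
  bin <- pmin(nbin, floor(dist / axial_bin) + 1L)
  fidx <- match(samples$frame, frames)
  values <- matrix(NA_real_, nbin, length(frames))
  counts <- matrix(0L, nbin, length(frames))
  sums <- rowsum(val, group = (fidx - 1L) * nbin + bin)
  ns <- rowsum(rep(1L, length(val)), group = (fidx - 1L) * nbin + bin)
  key <- as.integer(rownames(sums))
  values[key] <- sums / ns
  counts[key] <- ns
  structure(list(values = values, counts = counts,
                 axial_mid = (seq_len(nbin) - 0.5) * axial_bin,
                 frames = frames, statistic = statistic,
                 axial_bin = axial_bin, orientation = "tip_up"),
            class = "st_map")
}

#' @export
print.st_map <- function(x, ...) {
  cat(sprintf("<st_map> %s: %d axial bins (%.0f um) x %d frames, tip-up\n",
              x$statistic, nrow(x$values), x$axial_bin, length(x$frames)))
  invisible(x)
}

#' Plot a spatiotemporal map as a heat map (tip up)
#'
#' @param x an `st_map`.
#' @param col colour palette.
#' @param ... passed to [graphics::image()].
#' @export
plot.st_map <- function(x, col = grDevices::hcl.colors(64, "RdBu",
                                                       rev = TRUE), ...) {
  v <- x$values[rev(seq_len(nrow(x$values))), , drop = FALSE]  # tip up
  graphics::image(x = x$frames, y = x$axial_mid, z = t(v), col = col,
                  xlab = "frame", ylab = "distance from tip (um, tip up)",
                  main = x$statistic, ...)
  invisible(x)
}

#' Export a spatiotemporal map as CSV
#'
#' @param map an `st_map`.
#' @param path output path.
#' @export
write_st_map <- function(map, path) {
  df <- as.data.frame(map$values)
  names(df) <- paste0("frame_", map$frames)
  df <- cbind(data.frame(axial_mid_um = map$axial_mid), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Least-squares rigid-rotation fit of a velocity field
#'
#' Fits `v_i = omega x (p_i - c) + t_lin` to positions and velocities of
#' (meristem) cells in one frame, returning the angular velocity vector, a
#' rotation centre, and the residual RMS. Captures the skewing signature:
#' anti-parallel lateral motion on opposite flanks of the root is a rigid
#' rotation about an axis near the root axis.
#'
#' @param positions n x 3 matrix (um), n >= 4, non-collinear.
#' @param velocities n x 3 matrix (um/h).
#' @return list with `omega` (rad/h vector), `omega_mag`, `center` (point on
#'   the rotation axis closest to the origin), `translation`, `residual_rms`
#'   (um/h) and `condition` (design condition number).
#' @export
skewing_rotation_fit <- function(positions, velocities) {
  stopifnot(nrow(positions) == nrow(velocities))
  n <- nrow(positions)
  if (n < 4) stop("need at least 4 cells for a rotation fit")
  # v = omega x p + t  (c folded into t);  omega x p = -[p]x omega
  A <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(-cross_mat(positions[i, ]), diag(3))
  }))
  b <- as.vector(t(velocities))
  sv <- svd(A)
  cond <- sv$d[1] / sv$d[length(sv$d)]
  if (!is.finite(cond) || cond > 1e8) {
    stop("degenerate geometry for rotation fit (condition number ",
         format(cond, digits = 3), ")")
  }
  coefs <- sv$v %*% (crossprod(sv$u, b) / sv$d)
  omega <- coefs[1:3]
  t_lin <- coefs[4:6]
  resid <- matrix(A %*% coefs - b, ncol = 3, byrow = TRUE)
  om2 <- sum(omega^2)
  center <- if (om2 > 0) cross3(omega, t_lin) / om2 else c(NA, NA, NA)
  list(omega = omega, omega_mag = sqrt(om2), center = center,
       translation = t_lin,
       residual_rms = sqrt(mean(rowSums(resid^2))),
       condition = cond)
}

#' Lateral (X-Z) velocity scatter summaries
#'
#' Per group and time bin: mean lateral speed `sqrt(vx^2 + vz^2)`, the 2 x 2
#' covariance of `(vx, vz)`, and the sample count, as used for single-cell
#' lateral-velocity scatter displays.
#'
#' @param samples kinematics table with `vx`, `vz`, `t_h`.
#' @param group vector of group labels (recycled), or a column name.
#' @param time_bin width of time bins in hours (default: one value per
#'   frame time).
#' @return data frame with `group`, `t_mid`, `n`, `mean_lateral_speed`,
#'   `cov_xx`, `cov_xz`, `cov_zz` (covariances `NA` when `n < 2`); groups
#'   with no samples are absent (missing marker).
#' @export
xz_velocity_scatter <- function(samples, group = "all", time_bin = NULL) {
  if (is.character(group) && length(group) == 1 &&
      group %in% names(samples)) {
    g <- samples[[group]]
  } else {
    g <- rep_len(group, nrow(samples))
  }
  ok <- is.finite(samples$vx) & is.finite(samples$vz)
  d <- data.frame(vx = samples$vx[ok], vz = samples$vz[ok],
                  t_h = samples$t_h[ok], g = g[ok])
  tb <- if (is.null(time_bin)) d$t_h else floor(d$t_h / time_bin) * time_bin
  sp <- split(d, list(d$g, tb), drop = TRUE)
  out <- lapply(sp, function(s) {
    n <- nrow(s)
    cv <- if (n >= 2) stats::cov(cbind(s$vx, s$vz)) else
      matrix(NA_real_, 2, 2)
    data.frame(group = s$g[1], t_mid = mean(s$t_h), n = n,
               mean_lateral_speed = mean(sqrt(s$vx^2 + s$vz^2)),
               cov_xx = cv[1, 1], cov_xz = cv[1, 2], cov_zz = cv[2, 2])
  })
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$t_mid), ]
  rownames(res) <- NULL
  res
}
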