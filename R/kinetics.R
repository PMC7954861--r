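# Per-cell morphokinetics: velocity components, speed, velocity-total,
# acceleration, displacement-squared, instantaneous angle, coordinated
# motility, and per-track feature summaries.

#' Kinetics configuration
#'
#' @param differencing `"central"` (default; less noise amplification) or
#'   `"forward"` finite differences for velocity.
#' @param cm_radius neighbourhood radius for coordinated motility, um
#'   (reference value: 200 um).
#' @param cm_min_neighbors minimum neighbour count below which coordinated
#'   motility is undefined.
#' @return an object of class `kinetics_config`.
#' @export
kinetics_config <- function(differencing = c("central", "forward"),
                            cm_radius = 200, cm_min_neighbors = 3L) {
  differencing <- match.arg(differencing)
  if (cm_radius <= 0) stop("cm_radius must be > 0")
  structure(list(differencing = differencing, cm_radius = cm_radius,
                 cm_min_neighbors = as.integer(cm_min_neighbors)),
            class = "kinetics_config")
}

#' Per-sample kinematics of linked tracks
#'
#' For every track with at least two samples computes, per time point:
#' velocity components by the configured finite difference (gap samples enter
#' through their linearly interpolated positions and are flagged
#' `from_gap`), Euclidean `speed`, `velocity_total` (the sum of the absolute
#' per-axis velocity components, reported alongside the Euclidean speed),
#' acceleration as the difference of successive velocities, squared
#' displacement from the track's first sample, and the instantaneous angle to
#' the root axis (+Y, shootward) in degrees. Boundary samples where the
#' stencil is incomplete carry `NA`.
#'
#' @param tracks a `track_set` (or a bare track sample data frame with
#'   `track_id`, `frame`, `t_h`, `x_um`, `y_um`, `z_um`, and optionally
#'   `gap`).
#' @param config a [kinetics_config()].
#' @return data frame of kinematic samples keyed by (`track_id`, `frame`),
#'   with columns `vx, vy, vz, speed, velocity_total, ax, ay, az, a_mag,
#'   disp2, theta_deg, from_gap` (plus any intensity columns present).
#' @export
compute_kinematics <- function(tracks, config = kinetics_config()) {
  df <- if (inherits(tracks, "track_set")) tracks$tracks else tracks
  stopifnot(inherits(config, "kinetics_config"))
  if (!"gap" %in% names(df)) df$gap <- FALSE
  df <- df[order(df$track_id, df$frame), ]
  counts <- table(df$track_id)
  if (any(counts < 2)) stop("tracks with a single sample cannot be differenced")

  sp <- split(seq_len(nrow(df)), df$track_id)
  out <- lapply(sp, function(idx) {
    d <- df[idx, ]
    n <- nrow(d)
    P <- cbind(d$x_um, d$y_um, d$z_um)
    th <- d$t_h
    V <- matrix(NA_real_, n, 3)
    if (config$differencing == "central") {
      if (n >= 3) {
        i <- 2:(n - 1)
        V[i, ] <- (P[i + 1, , drop = FALSE] - P[i - 1, , drop = FALSE]) /
          (th[i + 1] - th[i - 1])
      } else {
        # two samples: fall back to the forward difference for both? keep
        # the interior-only convention: no interior points -> define the
        # single difference at the first sample
        V[1, ] <- (P[2, ] - P[1, ]) / (th[2] - th[1])
      }
      v_stencil_gap <- if (n >= 3) {
        c(TRUE, d$gap[1:(n - 2)] | d$gap[2:(n - 1)] | d$gap[3:n], TRUE)
      } else c(d$gap[1] | d$gap[2], TRUE)
    } else {
      i <- 1:(n - 1)
      V[i, ] <- (P[i + 1, , drop = FALSE] - P[i, , drop = FALSE]) /
        (th[i + 1] - th[i])
      v_stencil_gap <- c(d$gap[1:(n - 1)] | d$gap[2:n], TRUE)
    }
    A <- matrix(NA_real_, n, 3)
    has_v <- which(!is.na(V[, 1]))
    if (length(has_v) >= 2) {
      i <- has_v[-1]; im <- has_v[-length(has_v)]
      consec <- (i - im) == 1
      A[i[consec], ] <- (V[i[consec], , drop = FALSE] -
                           V[im[consec], , drop = FALSE]) /
        (th[i[consec]] - th[im[consec]])
    }
    speed <- sqrt(rowSums(V^2))
    data.frame(d,
               vx = V[, 1], vy = V[, 2], vz = V[, 3],
               speed = speed,
               velocity_total = abs(V[, 1]) + abs(V[, 2]) + abs(V[, 3]),
               ax = A[, 1], ay = A[, 2], az = A[, 3],
               a_mag = sqrt(rowSums(A^2)),
               disp2 = rowSums((P - matrix(P[1, ], n, 3, byrow = TRUE))^2),
               theta_deg = instantaneous_angle(V),
               from_gap = d$gap | v_stencil_gap)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "delta_t_min") <- if (inherits(tracks, "track_set")) {
    tracks$delta_t_min
  } else NULL
  res
}

#' Instantaneous angle to the root axis
#'
#' Angle in degrees between a velocity vector and the +Y (shootward) root
#' axis: `theta = acos(vy / |v|)`. Undefined (`NA`) for zero-norm or missing
#' velocities.
#'
#' @param v numeric length-3 vector, or an n x 3 matrix of velocities.
#' @return angle(s) in degrees in `[0, 180]`.
#' @examples
#' instantaneous_angle(c(0, 1, 0))  # 0
#' instantaneous_angle(c(1, 0, 0))  # 90
#' @export
instantaneous_angle <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  out <- rep(NA_real_, nrow(v))
  ok <- !is.na(nrm) & nrm > 0
  out[ok] <- acos(pmin(1, pmax(-1, v[ok, 2] / nrm[ok]))) * 180 / pi
  out
}

#' Coordinated motility of one centre cell
#'
#' The mean, over all other cells within radius `cm_radius` of the centre, of
#' the cosine of the angle between the neighbour's velocity and the centre
#' cell's velocity. 1 means perfectly coordinated motion, 0 no coordination,
#' -1 anti-coordination. Undefined (`NA`) when fewer than
#' `cm_min_neighbors` neighbours with a defined, nonzero velocity exist.
#'
#' @param positions n x 3 matrix of cell positions (um) in one frame.
#' @param velocities n x 3 matrix of matching velocities (um/h).
#' @param center index of the centre cell.
#' @param config a [kinetics_config()].
#' @return list with `cm` (mean cosine) and `n_neighbors`.
#' @export
coordinated_motility <- function(positions, velocities, center,
                                 config = kinetics_config()) {
  stopifnot(nrow(positions) == nrow(velocities))
  vc <- velocities[center, ]
  nc <- vec_norm(vc)
  if (!all(is.finite(vc)) || nc == 0) {
    stop("center cell must have a defined, nonzero velocity")
  }
  d <- sqrt(colSums((t(positions) - positions[center, ])^2))
  nb <- setdiff(which(d <= config$cm_radius), center)
  vn <- velocities[nb, , drop = FALSE]
  nrm <- sqrt(rowSums(vn^2))
  ok <- is.finite(nrm) & nrm > 0
  nb_used <- sum(ok)
  if (nb_used < config$cm_min_neighbors) {
    return(list(cm = NA_real_, n_neighbors = nb_used))
  }
  cosines <- (vn[ok, , drop = FALSE] %*% vc) / (nrm[ok] * nc)
  list(cm = mean(cosines), n_neighbors = nb_used)
}

#' Add per-sample coordinated motility to a kinematics table
#'
#' Computes, frame by frame, the coordinated motility of every cell with a
#' defined velocity against all other such cells within `cm_radius`.
#'
#' @param samples kinematics table from [compute_kinematics()].
#' @param config a [kinetics_config()].
#' @return `samples` with columns `cm` and `cm_n` appended.
#' @export
add_coordination <- function(samples, config = kinetics_config()) {
  samples$cm <- NA_real_
  samples$cm_n <- 0L
  for (f in unique(samples$frame)) {
    idx <- which(samples$frame == f & is.finite(samples$speed) &
                   samples$speed > 0)
    if (length(idx) < 2) next
    P <- cbind(samples$x_um[idx], samples$y_um[idx], samples$z_um[idx])
    V <- cbind(samples$vx[idx], samples$vy[idx], samples$vz[idx])
    nrm <- sqrt(rowSums(V^2))
    U <- V / nrm
    D <- cross_dist(P, P)
    W <- (D <= config$cm_radius)
    diag(W) <- FALSE
    C <- U %*% t(U)           # pairwise cosines
    nnb <- rowSums(W)
    cmv <- rowSums(C * W) / nnb
    cmv[nnb < config$cm_min_neighbors] <- NA_real_
    samples$cm[idx] <- cmv
    samples$cm_n[idx] <- nnb
  }
  samples
}

# mean-squared displacement over frame lags from one track's positions
track_msd <- function(P, max_lag) {
  vapply(seq_len(max_lag), function(L) {
    n <- nrow(P)
    d <- P[(L + 1):n, , drop = FALSE] - P[1:(n - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, 1)
}

# log-log slope of the MSD over the first quarter of available lags,
# capped at 10 lags: time-averaged MSD estimates at long lags have few
# effective degrees of freedom and bias the log-log fit downward, so the
# fit stays in the well-estimated short-lag regime (for 40-frame movies the
# cap is inactive).
msd_slope <- function(P, dt_h) {
  n <- nrow(P)
  if (n < 5) return(NA_real_)
  max_lag <- min(10L, max(2L, floor((n - 1) / 4)))
  msd <- track_msd(P, max_lag)
  lag_t <- seq_len(max_lag) * dt_h
  ok <- msd > 0
  if (sum(ok) < 2) return(NA_real_)
  unname(coef(lm(log(msd[ok]) ~ log(lag_t[ok])))[2])
}

#' The morphokinetic feature manifest
#'
#' Canonical, versioned list of the per-cell features produced by
#' [cell_feature_summary()]: `{mean, sd, max}` over time of the velocity
#' components, speed, velocity-total, acceleration magnitude, instantaneous
#' angle, coordinated motility, squared displacement and lateral speed, plus
#' track duration, net displacement, path length, directionality ratio,
#' MSD log-log slope, and mean nucleus eccentricity and area.
#'
#' @return data frame with `feature`, `statistic`, `base_quantity`, `units`.
#' @export
feature_manifest <- function() {
  base <- data.frame(
    base_quantity = c("vx", "vy", "vz", "speed", "velocity_total", "a_mag",
                      "theta_deg", "cm", "disp2", "lateral_speed"),
    units = c("um/h", "um/h", "um/h", "um/h", "um/h", "um/h^2", "deg", "1",
              "um^2", "um/h"))
  stat <- c("mean", "sd", "max")
  grid <- expand.grid(statistic = stat,
                      base_quantity = base$base_quantity,
                      stringsAsFactors = FALSE)
  grid$units <- base$units[match(grid$base_quantity, base$base_quantity)]
  grid$feature <- paste(grid$base_quantity, grid$statistic, sep = "_")
  extra <- data.frame(
    statistic = "scalar",
    base_quantity = c("duration", "net_displacement", "path_length",
                      "directionality_ratio", "msd_slope",
                      "eccentricity", "area"),
    units = c("s", "um", "um", "1", "1", "1", "um^2"),
    feature = c("duration_s", "net_displacement_um", "path_length_um",
                "directionality_ratio", "msd_slope",
                "eccentricity_mean", "area_um2_mean"))
  rbind(grid[, c("feature", "statistic", "base_quantity", "units")],
        extra[, c("feature", "statistic", "base_quantity", "units")])
}

#' Per-cell morphokinetic feature vector
#'
#' Aggregates a track's kinematic samples into the canonical feature set of
#' [feature_manifest()] (37 features). Undefined entries (e.g. the
#' directionality ratio of a stationary track) are `NA`.
#'
#' @param samples kinematics table (after [add_coordination()] if
#'   coordinated-motility features are wanted; otherwise those features are
#'   `NA`).
#' @param morphology optional data frame `track_id`, `eccentricity`,
#'   `area_um2` (per-track means from the detection stage).
#' @param delta_t_min frame interval in minutes; taken from the samples
#'   attribute if absent.
#' @return data frame, one row per track, columns per the manifest.
#' @export
cell_feature_summary <- function(samples, morphology = NULL,
                                 delta_t_min = NULL) {
  delta_t_min <- delta_t_min %||% attr(samples, "delta_t_min")
  if (is.null(delta_t_min)) {
    dt <- diff(sort(unique(samples$t_h)))[1]
    delta_t_min <- dt * 60
  }
  dt_h <- delta_t_min / 60
  if (!"cm" %in% names(samples)) samples$cm <- NA_real_
  samples$lateral_speed <- sqrt(samples$vx^2 + samples$vz^2)

  agg_stats <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) return(c(mean = NA_real_, sd = NA_real_,
                                 max = NA_real_))
    c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0, max = max(x))
  }
  quants <- c("vx", "vy", "vz", "speed", "velocity_total", "a_mag",
              "theta_deg", "cm", "disp2", "lateral_speed")

  sp <- split(seq_len(nrow(samples)), samples$track_id)
  rows <- lapply(names(sp), function(tid) {
    d <- samples[sp[[tid]], ]
    d <- d[order(d$frame), ]
    if (all(!is.finite(d$speed))) {
      stop("track ", tid, " has no defined kinematic samples")
    }
    P <- cbind(d$x_um, d$y_um, d$z_um)
    v <- unlist(lapply(quants, function(q) agg_stats(d[[q]])))
    names(v) <- paste(rep(quants, each = 3), c("mean", "sd", "max"),
                      sep = "_")
    steps <- sqrt(rowSums(diff(P)^2))
    path <- sum(steps)
    net <- sqrt(sum((P[nrow(P), ] - P[1, ])^2))
    out <- data.frame(track_id = as.integer(tid), t(v))
    out$duration_s <- diff(range(d$frame)) * delta_t_min * 60
    out$net_displacement_um <- net
    out$path_length_um <- path
    out$directionality_ratio <- if (path > 0) net / path else NA_real_
    out$msd_slope <- msd_slope(P, dt_h)
    out$eccentricity_mean <- NA_real_
    out$area_um2_mean <- NA_real_
    out
  })
  res <- do.call(rbind, rows)
  if (!is.null(morphology)) {
    m <- match(res$track_id, morphology$track_id)
    res$eccentricity_mean <- morphology$eccentricity[m]
    res$area_um2_mean <- morphology$area_um2[m]
  }
  rownames(res) <- NULL
  res
}
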