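# Emulated acquisition: true trajectories -> per-frame detections (point
# mode) or voxel stacks (image mode), with jitter, dropouts and false
# positives, plus exact bookkeeping for the mass-balance invariant.

#' Render detected frames from ground truth (emulated acquisition)
#'
#' Point mode: each true position is perturbed by isotropic Gaussian jitter,
#' dropped independently with the configured dropout rate, and spurious
#' detections are added at the configured false-positive rate (per true
#' nucleus per frame, uniform over the root cylinder bounding volume).
#' Channel intensities (nuclear marker, reporter, DII/mDII pair) receive
#' additive Gaussian noise. Per-frame bookkeeping (true count, dropouts,
#' false positives) is recorded so that conservation can be asserted exactly.
#'
#' @param truth a `root_truth` from [simulate_root()].
#' @param config a [simulation_config()]; defaults to the truth's own config.
#' @param seed optional seed overriding `config$seed + 1` for the rendering
#'   noise (kept distinct from the trajectory seed).
#' @return an object of class `frame_set`: list with `detections` (data frame
#'   with one row per detection: `det_id`, `frame`, `t_h`, positions in um,
#'   channel intensities, and `truth_id`, `NA` for false positives),
#'   `delta_t_min`, `channels`, and `bookkeeping`.
#' @export
render_frames <- function(truth, config = truth$config, seed = NULL) {
  stopifnot(inherits(truth, "root_truth"))
  cfg <- config
  nz <- cfg$noise
  seed <- seed %||% (cfg$seed + 1L)
  nuc <- truth$nuclei
  nf <- max(nuc$frame)
  dt_h <- cfg$frame_interval / 60
  nuc_amp <- 100  # nuclear marker mean intensity, a.u.

  with_seed(seed, {
    out <- vector("list", nf)
    book <- data.frame(frame = seq_len(nf), n_true = 0L, n_dropped = 0L,
                       n_fp = 0L)
    for (f in seq_len(nf)) {
      fr <- nuc[nuc$frame == f, ]
      n <- nrow(fr)
      keep <- runif(n) >= nz$dropout_rate
      nk <- sum(keep)
      n_fp <- rbinom(1, n, nz$false_positive_rate)
      book$n_true[f] <- n
      book$n_dropped[f] <- n - nk
      book$n_fp[f] <- n_fp

      pos <- cbind(fr$x_um, fr$y_um, fr$z_um)[keep, , drop = FALSE] +
        matrix(rnorm(3 * nk, sd = nz$jitter_sd), ncol = 3)
      rep_true <- fr$reporter[keep]
      auxin <- fr$auxin[keep]
      tid <- fr$nucleus_id[keep]

      if (n_fp > 0) {
        fp_pos <- cbind(runif(n_fp, -cfg$root_radius, cfg$root_radius),
                        runif(n_fp, 0, cfg$root_length),
                        runif(n_fp, -cfg$root_radius, cfg$root_radius))
        pos <- rbind(pos, fp_pos)
        rep_true <- c(rep_true, rep(cfg$reporter$baseline, n_fp))
        auxin <- c(auxin, rep(0, n_fp))
        tid <- c(tid, rep(NA_integer_, n_fp))
      }
      m <- nrow(pos)
      isd <- nz$intensity_sd
      out[[f]] <- data.frame(
        frame = f, t_h = (f - 1) * dt_h,
        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
        ch_nuclear = nuc_amp + rnorm(m, sd = isd),
        ch_reporter = rep_true + rnorm(m, sd = isd),
        ch_dii = nuc_amp * exp(-auxin) + rnorm(m, sd = isd),
        ch_mdii = nuc_amp + rnorm(m, sd = isd),
        truth_id = tid)
    }
    det <- do.call(rbind, out)
    det$det_id <- seq_len(nrow(det))
    rownames(det) <- NULL
    structure(list(detections = det, delta_t_min = cfg$frame_interval,
                   channels = c("ch_nuclear", "ch_reporter", "ch_dii",
                                "ch_mdii"),
                   bookkeeping = book, config = cfg),
              class = "frame_set")
  })
}

#' @export
print.frame_set <- function(x, ...) {
  cat("<frame_set>\n")
  cat(sprintf("  %d detections over %d frames (dt = %.2f min)\n",
              nrow(x$detections), max(x$detections$frame), x$delta_t_min))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Construct a frame set directly from a detection table
#'
#' Wraps a pre-detected point-cloud table (e.g. read from CSV) as a
#' `frame_set` so it can enter the tracking pipeline without image detection.
#'
#' @param detections data frame with at least `frame`, `x_um`, `y_um`,
#'   `z_um`; `t_h` and `det_id` are added if missing.
#' @param delta_t_min frame interval, minutes.
#' @param channels character vector naming intensity columns (may be empty).
#' @return a `frame_set`.
#' @export
frame_set <- function(detections, delta_t_min, channels = character()) {
  need <- c("frame", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(detections))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.unsorted(detections$frame)) {
    detections <- detections[order(detections$frame), ]
  }
  if (!"t_h" %in% names(detections)) {
    detections$t_h <- (detections$frame - 1) * delta_t_min / 60
  }
  if (!"det_id" %in% names(detections)) {
    detections$det_id <- seq_len(nrow(detections))
  }
  if (!"truth_id" %in% names(detections)) {
    detections$truth_id <- NA_integer_
  }
  structure(list(detections = detections, delta_t_min = delta_t_min,
                 channels = channels,
                 bookkeeping = NULL, config = NULL),
            class = "frame_set")
}

#' Render voxel stacks from ground truth (image mode)
#'
#' Paints each nucleus as a 3D Gaussian blob into a voxel grid, per frame and
#' channel. Intended for exercising the image-detection stage on small
#' volumes; the point mode ([render_frames()]) is the default path.
#'
#' @param truth a `root_truth`.
#' @param frames integer vector of frames to render.
#' @param voxel_size numeric length-3, um per voxel along (x, y, z).
#' @param extent list with numeric length-2 `x`, `y`, `z` ranges in um; must
#'   cover the nuclei to be rendered.
#' @param blob_sigma Gaussian blob sigma in um.
#' @param amplitude peak intensity of the nuclear channel.
#' @param channels which channels to paint (subset of `"ch_nuclear"`,
#'   `"ch_reporter"`).
#' @return named list (one per frame, `"frame_<f>"`) of named lists of 3D
#'   arrays indexed `[x, y, z]`, with attributes `voxel_size` and `origin`.
#' @export
render_voxels <- function(truth, frames = 1L,
                          voxel_size = c(1, 1, 2),
                          extent = NULL, blob_sigma = 2,
                          amplitude = 100,
                          channels = "ch_nuclear") {
  stopifnot(inherits(truth, "root_truth"))
  nuc <- truth$nuclei
  nuc <- nuc[nuc$frame %in% frames, ]
  if (is.null(extent)) {
    pad <- 4 * blob_sigma
    extent <- list(x = range(nuc$x_um) + c(-pad, pad),
                   y = range(nuc$y_um) + c(-pad, pad),
                   z = range(nuc$z_um) + c(-pad, pad))
  }
  dims <- ceiling(c(diff(extent$x), diff(extent$y), diff(extent$z)) /
                    voxel_size)
  if (any(dims < 4)) stop("voxel grid too small for root extent")
  origin <- c(extent$x[1], extent$y[1], extent$z[1])
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_size[1]
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_size[2]
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel_size[3]

  out <- list()
  for (f in frames) {
    fr <- nuc[nuc$frame == f, ]
    chans <- list()
    for (ch in channels) {
      amp <- if (ch == "ch_reporter") fr$reporter else rep(amplitude, nrow(fr))
      vol <- array(0, dim = dims)
      for (i in seq_len(nrow(fr))) {
        p <- c(fr$x_um[i], fr$y_um[i], fr$z_um[i])
        if (p[1] < extent$x[1] || p[1] > extent$x[2] ||
            p[2] < extent$y[1] || p[2] > extent$y[2] ||
            p[3] < extent$z[1] || p[3] > extent$z[2]) {
          stop("voxel grid too small for root extent (nucleus outside grid)")
        }
        # paint within +/- 4 sigma, separably
        gx <- exp(-(cx - p[1])^2 / (2 * blob_sigma^2))
        gy <- exp(-(cy - p[2])^2 / (2 * blob_sigma^2))
        gz <- exp(-(cz - p[3])^2 / (2 * blob_sigma^2))
        ix <- which(gx > 1e-4); iy <- which(gy > 1e-4); iz <- which(gz > 1e-4)
        blob <- amp[i] * outer(outer(gx[ix], gy[iy]), gz[iz])
        vol[ix, iy, iz] <- vol[ix, iy, iz] + blob
      }
      attr(vol, "voxel_size") <- voxel_size
      attr(vol, "origin") <- origin
      chans[[ch]] <- vol
    }
    out[[paste0("frame_", f)]] <- chans
  }
  out
}
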