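# Reporter quantification: ROI intensity series, ratiometric (DII/mDII)
# reporters, and response-onset timing.

#' Define a rectangular region of interest
#'
#' Axis-aligned box in um; any range may be `NULL` (unbounded).
#'
#' @param x,y,z numeric length-2 ranges (um) or `NULL`.
#' @param label ROI label.
#' @return an object of class `roi`.
#' @export
roi <- function(x = NULL, y = NULL, z = NULL, label = "roi") {
  chk <- function(r, nm) {
    if (!is.null(r)) {
      if (length(r) != 2 || !all(is.finite(r)) || r[2] <= r[1]) {
        stop("non-empty range required for ", nm)
      }
    }
    r
  }
  structure(list(x = chk(x, "x"), y = chk(y, "y"), z = chk(z, "z"),
                 label = label), class = "roi")
}

roi_mask <- function(det, box) {
  ok <- rep(TRUE, nrow(det))
  if (!is.null(box$x)) ok <- ok & det$x_um >= box$x[1] & det$x_um <= box$x[2]
  if (!is.null(box$y)) ok <- ok & det$y_um >= box$y[1] & det$y_um <= box$y[2]
  if (!is.null(box$z)) ok <- ok & det$z_um >= box$z[1] & det$z_um <= box$z[2]
  ok
}

#' Mean channel intensity within a region of interest over time
#'
#' Point mode: the mean of the stored per-detection channel intensity over
#' detections falling inside the box, per frame.
#'
#' @param frames a `frame_set`.
#' @param box an [roi()].
#' @param channel channel column name (default the reporter channel).
#' @return an `intensity_series` data frame: `label`, `frame`, `t_h`,
#'   `value`, `n`. Frames where the ROI holds no detections are reported
#'   with `n = 0` and `value = NA`.
#' @export
quantify_roi <- function(frames, box, channel = "ch_reporter") {
  stopifnot(inherits(frames, "frame_set"), inherits(box, "roi"))
  det <- frames$detections
  if (!channel %in% names(det)) stop("channel not present: ", channel)
  det <- det[roi_mask(det, box), ]
  if (nrow(det) == 0) stop("ROI never intersects the data")
  all_f <- seq_len(max(frames$detections$frame))
  sp <- split(det[[channel]], factor(det$frame, levels = all_f))
  out <- data.frame(label = box$label, frame = all_f,
                    t_h = (all_f - 1) * frames$delta_t_min / 60,
                    value = vapply(sp, function(v) {
                      if (length(v) == 0) NA_real_ else mean(v)
                    }, 1),
                    n = lengths(sp))
  rownames(out) <- NULL
  class(out) <- c("intensity_series", "data.frame")
  out
}

#' Ratiometric reporter series (DII/mDII) within a region of interest
#'
#' Per frame, the ratio of the mean DII-channel intensity to the mean
#' mDII-channel intensity over detections in the box. Auxin degrades the DII
#' moiety but not the mutated control, so a falling ratio reports rising
#' auxin. Frames with a non-positive mDII mean carry `NA` (undefined
#' marker).
#'
#' @param frames a `frame_set`.
#' @param box an [roi()].
#' @param dii,mdii channel column names.
#' @return an `intensity_series` with `value` = ratio.
#' @export
dii_ratio <- function(frames, box, dii = "ch_dii", mdii = "ch_mdii") {
  num <- quantify_roi(frames, box, channel = dii)
  den <- quantify_roi(frames, box, channel = mdii)
  out <- num
  out$value <- ifelse(!is.na(den$value) & den$value > 0,
                      num$value / den$value, NA_real_)
  out$label <- paste0(box$label, ":", dii, "/", mdii)
  out
}

#' Response-onset time of an intensity series
#'
#' Operationalises "signal observed": the first time the series exceeds
#' `baseline mean + k * baseline sd` for `persistence` consecutive frames.
#'
#' @param series an `intensity_series` (or data frame with `t_h`, `value`).
#' @param baseline_frames number of initial frames defining the baseline
#'   (>= 3; the default, 8, keeps the baseline-sd estimate stable while
#'   staying well inside a 2.5-h onset delay at 8.75-min frames).
#' @param k multiplier on the baseline standard deviation.
#' @param persistence number of consecutive supra-threshold frames required.
#' @return onset time in hours, or `NA` if the series never crosses
#'   (including constant series).
#' @export
onset_time <- function(series, baseline_frames = 8L, k = 3,
                       persistence = 2L) {
  if (baseline_frames < 3) stop("need >= 3 baseline frames")
  v <- series$value
  t <- series$t_h
  base <- v[seq_len(min(baseline_frames, length(v)))]
  base <- base[is.finite(base)]
  if (length(base) < 3) stop("need >= 3 finite baseline frames")
  thr <- mean(base) + k * sd(base)
  if (!is.finite(thr) || sd(base) == 0 && all(v == v[1], na.rm = TRUE)) {
    return(NA_real_)
  }
  above <- !is.na(v) & v > thr
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= persistence) return(t[i - persistence + 1L])
  }
  NA_real_
}
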