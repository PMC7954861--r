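# Track linking: frame-to-frame assignment with constant-velocity
# ("autoregressive motion") prediction, gap closing and duration filtering.

#' Tracking configuration
#'
#' Defaults follow the reference tracking setup: constant-velocity motion
#' prediction, maximum link distance 12 um (midpoint of the instrument's
#' 9-15 um automatic range), gap closing up to 3 frames, and a minimum track
#' duration of 3600 s.
#'
#' @param max_distance maximum link distance (um) between a detection and a
#'   track's predicted position; the gap-closing search radius scales as
#'   `max_distance * (gap + 1)`.
#' @param max_gap maximum number of consecutive missed frames bridged.
#' @param min_duration minimum track duration in seconds (time span from
#'   first to last frame) retained by [filter_tracks()].
#' @param motion_model `"constant_velocity"` (order-1 extrapolation from the
#'   last two linked samples) or `"none"` (last position).
#' @param assignment `"hungarian"` (optimal, default) or `"greedy"`.
#' @return an object of class `tracking_config`.
#' @export
tracking_config <- function(max_distance = 12, max_gap = 3L,
                            min_duration = 3600,
                            motion_model = c("constant_velocity", "none"),
                            assignment = c("hungarian", "greedy")) {
  motion_model <- match.arg(motion_model)
  assignment <- match.arg(assignment)
  if (max_distance <= 0) stop("max_distance must be > 0")
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (min_duration < 0) stop("min_duration must be >= 0")
  structure(list(max_distance = max_distance, max_gap = as.integer(max_gap),
                 min_duration = min_duration, motion_model = motion_model,
                 assignment = assignment),
            class = "tracking_config")
}

# Solve one frame's assignment between active tracks and detections.
# pred: T x 3 predicted positions; radius: length-T allowed radii;
# det: D x 3 positions; birth: scalar cost of starting a new track.
# Returns integer length-T: detection index per track, NA if unlinked.
# The problem decomposes over connected components of the candidate graph;
# each component is solved exactly with the LAP solver (or greedily).
assign_frame <- function(pred, radius, det, birth, assignment = "hungarian") {
  nt <- nrow(pred)
  nd <- nrow(det)
  link <- rep(NA_integer_, nt)
  if (nt == 0 || nd == 0) return(link)
  d <- cross_dist(pred, det)
  ok <- d <= matrix(radius, nt, nd)
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) == 0) return(link)

  if (assignment == "greedy") {
    o <- order(d[cand])
    used_t <- logical(nt); used_d <- logical(nd)
    for (k in o) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_t[i] && !used_d[j]) {
        link[i] <- j; used_t[i] <- TRUE; used_d[j] <- TRUE
      }
    }
    return(link)
  }

  # connected components over the bipartite candidate graph
  parent <- uf_new(nt + nd)
  for (k in seq_len(nrow(cand))) {
    parent <- uf_union(parent, cand[k, 1], nt + cand[k, 2])
  }
  roots <- vapply(seq_len(nt + nd), function(i) uf_find(parent, i), 1L)
  involved <- sort(unique(roots[unique(c(cand[, 1], nt + cand[, 2]))]))
  for (r in involved) {
    tr <- which(roots[seq_len(nt)] == r)
    de <- which(roots[nt + seq_len(nd)] == r)
    sub <- d[tr, de, drop = FALSE]
    sub[!ok[tr, de, drop = FALSE]] <- NA
    sol <- solve_lap_padded(sub, death = radius[tr], birth = birth)
    link[tr] <- de[sol]
    # (detections in a component are never offered to another component)
  }
  link
}

# Exact minimum-cost matching with unmatched-row cost `death[i]` and
# unmatched-column cost `birth`, via a padded square LAP. `cost` may contain
# NA for forbidden pairs. Returns column index per row (NA = unmatched).
solve_lap_padded <- function(cost, death, birth) {
  nt <- nrow(cost); nd <- ncol(cost)
  BIG <- 1e9
  n <- nt + nd
  M <- matrix(BIG, n, n)
  cc <- cost
  cc[is.na(cc)] <- BIG
  M[seq_len(nt), seq_len(nd)] <- cc
  for (i in seq_len(nt)) M[i, nd + i] <- death[i]
  for (j in seq_len(nd)) M[nt + j, j] <- birth
  M[nt + seq_len(nd), nd + seq_len(nt)] <- 0
  sol <- lap_solve_cpp(M)
  out <- sol[seq_len(nt)]
  out[out > nd] <- NA_integer_
  # guard: never take a forbidden pseudo-link
  bad <- !is.na(out) & is.na(cost[cbind(seq_len(nt), out)])
  out[bad] <- NA_integer_
  out
}

# Brute-force matching oracle used in tests: enumerates all matchings.
brute_force_match <- function(cost, death, birth) {
  nt <- nrow(cost); nd <- ncol(cost)
  best <- list(cost = Inf, link = rep(NA_integer_, nt))
  rec <- function(i, used, acc, link) {
    if (acc >= best$cost) return()
    if (i > nt) {
      acc2 <- acc + birth * sum(!used)
      if (acc2 < best$cost) best <<- list(cost = acc2, link = link)
      return()
    }
    rec(i + 1, used, acc + death[i], link)  # row i unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && !is.na(cost[i, j])) {
        used[j] <- TRUE; link[i] <- j
        rec(i + 1, used, acc + cost[i, j], link)
        used[j] <- FALSE; link[i] <- NA_integer_
      }
    }
  }
  rec(1L, logical(nd), 0, rep(NA_integer_, nt))
  best
}

#' Link detections into tracks
#'
#' Frame-to-frame assignment minimising total link cost, where the cost is
#' the Euclidean distance between a detection and the track's predicted
#' position (constant-velocity extrapolation from the last two linked
#' samples, or the last position for single-sample tracks). Links with cost
#' above the (gap-scaled) maximum distance are forbidden. Tracks left
#' unlinked stay open for up to `max_gap` frames, with the prediction
#' continuing across the gap, then close; unmatched detections seed new
#' tracks. Assignment is exact (Hungarian) per frame pair and deterministic.
#'
#' @param frames a `frame_set`.
#' @param config a [tracking_config()].
#' @return an object of class `track_set`: list with `tracks` (data frame of
#'   samples: `track_id`, `frame`, `t_h`, positions, `gap` flag, `det_id`,
#'   `truth_id`, channel intensities; gap samples carry linearly interpolated
#'   positions and `det_id = NA`), the `config`, `delta_t_min` and a `stats`
#'   list (detections assigned, tracks started/closed).
#' @export
link_tracks <- function(frames, config = tracking_config()) {
  stopifnot(inherits(frames, "frame_set"), inherits(config, "tracking_config"))
  det <- frames$detections
  if (nrow(det) == 0) stop("empty frame set")
  all_frames <- seq_len(max(det$frame))
  if (length(all_frames) < 2) stop("need at least 2 frames to link")
  dt_h <- frames$delta_t_min / 60
  chan <- intersect(frames$channels, names(det))

  # per-track state
  t_last <- NULL        # k x 3 last linked position
  t_prev <- NULL        # k x 3 previous linked position (NA if single)
  t_last_f <- integer() # frame of last link
  t_prev_f <- integer()
  t_active <- logical()
  t_id <- integer()
  next_tid <- 1L
  samples <- list()
  n_closed <- 0L

  emit <- function(tid, fr, rows_det, gap) {
    # rows_det: data frame rows from det (or NULL for a gap sample)
    if (is.null(rows_det)) return(NULL)
    cbind(data.frame(track_id = tid, frame = fr, t_h = (fr - 1) * dt_h,
                     x_um = rows_det$x_um, y_um = rows_det$y_um,
                     z_um = rows_det$z_um, gap = gap,
                     det_id = rows_det$det_id,
                     truth_id = rows_det$truth_id),
          rows_det[, chan, drop = FALSE])
  }

  for (f in all_frames) {
    fr <- det[det$frame == f, , drop = FALSE]
    nd <- nrow(fr)
    if (f == 1 || length(t_id) == 0) {
      if (nd > 0) {
        ids <- seq.int(next_tid, length.out = nd)
        next_tid <- next_tid + nd
        samples[[length(samples) + 1]] <- emit(ids, f, fr, FALSE)
        t_last <- rbind(t_last, cbind(fr$x_um, fr$y_um, fr$z_um))
        t_prev <- rbind(t_prev, matrix(NA_real_, nd, 3))
        t_last_f <- c(t_last_f, rep(f, nd))
        t_prev_f <- c(t_prev_f, rep(NA_integer_, nd))
        t_active <- c(t_active, rep(TRUE, nd))
        t_id <- c(t_id, ids)
      }
      next
    }

    # close tracks whose gap exceeded max_gap
    gap_len <- f - t_last_f - 1L
    to_close <- t_active & gap_len > config$max_gap
    n_closed <- n_closed + sum(to_close)
    t_active[to_close] <- FALSE

    act <- which(t_active)
    link <- rep(NA_integer_, length(act))
    if (length(act) > 0 && nd > 0) {
      g <- gap_len[act]
      pred <- t_last[act, , drop = FALSE]
      if (config$motion_model == "constant_velocity") {
        has_v <- !is.na(t_prev_f[act])
        if (any(has_v)) {
          i <- act[has_v]
          v <- (t_last[i, , drop = FALSE] - t_prev[i, , drop = FALSE]) /
            (t_last_f[i] - t_prev_f[i])
          pred[has_v, ] <- t_last[i, , drop = FALSE] +
            v * (f - t_last_f[i])
        }
      }
      radius <- config$max_distance * (g + 1)
      dpos <- cbind(fr$x_um, fr$y_um, fr$z_um)
      # deterministic tie-break: rows ordered by track id (act is sorted)
      link <- assign_frame(pred, radius, dpos, birth = config$max_distance,
                           assignment = config$assignment)
    }

    linked_i <- act[!is.na(link)]
    linked_j <- link[!is.na(link)]
    if (length(linked_i) > 0) {
      # gap samples for bridged frames, linearly interpolated
      for (kk in seq_along(linked_i)) {
        i <- linked_i[kk]; j <- linked_j[kk]
        lf <- t_last_f[i]
        if (f - lf > 1) {
          miss <- (lf + 1):(f - 1)
          w <- (miss - lf) / (f - lf)
          p0 <- t_last[i, ]; p1 <- c(fr$x_um[j], fr$y_um[j], fr$z_um[j])
          gp <- data.frame(track_id = t_id[i], frame = miss,
                           t_h = (miss - 1) * dt_h,
                           x_um = p0[1] + w * (p1[1] - p0[1]),
                           y_um = p0[2] + w * (p1[2] - p0[2]),
                           z_um = p0[3] + w * (p1[3] - p0[3]),
                           gap = TRUE, det_id = NA_integer_,
                           truth_id = NA_integer_)
          for (ch in chan) gp[[ch]] <- NA_real_
          samples[[length(samples) + 1]] <- gp
        }
      }
      rows <- fr[linked_j, , drop = FALSE]
      samples[[length(samples) + 1]] <- emit(t_id[linked_i], f, rows, FALSE)
      t_prev[linked_i, ] <- t_last[linked_i, ]
      t_prev_f[linked_i] <- t_last_f[linked_i]
      t_last[linked_i, ] <- cbind(rows$x_um, rows$y_um, rows$z_um)
      t_last_f[linked_i] <- f
    }

    unmatched <- setdiff(seq_len(nd), linked_j)
    if (length(unmatched) > 0) {
      rows <- fr[unmatched, , drop = FALSE]
      ids <- seq.int(next_tid, length.out = length(unmatched))
      next_tid <- next_tid + length(unmatched)
      samples[[length(samples) + 1]] <- emit(ids, f, rows, FALSE)
      t_last <- rbind(t_last, cbind(rows$x_um, rows$y_um, rows$z_um))
      t_prev <- rbind(t_prev, matrix(NA_real_, length(unmatched), 3))
      t_last_f <- c(t_last_f, rep(f, length(unmatched)))
      t_prev_f <- c(t_prev_f, rep(NA_integer_, length(unmatched)))
      t_active <- c(t_active, rep(TRUE, length(unmatched)))
      t_id <- c(t_id, ids)
    }
  }

  tracks <- do.call(rbind, samples)
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  # trailing gap samples never occur (gaps are only emitted when bridged)
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, config = config,
                 delta_t_min = frames$delta_t_min,
                 stats = list(n_detections = nrow(det),
                              n_assigned = sum(!is.na(tracks$det_id)),
                              n_tracks = next_tid - 1L,
                              n_closed_by_gap = n_closed)),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  d <- track_durations(x)
  cat("<track_set>\n")
  cat(sprintf("  %d tracks, %d samples (%d gap-filled)\n",
              length(unique(x$tracks$track_id)), nrow(x$tracks),
              sum(x$tracks$gap)))
  cat(sprintf("  duration: median %.0f s, max %.0f s\n",
              stats::median(d$duration_s), max(d$duration_s)))
  invisible(x)
}

#' Track durations (seconds)
#'
#' Duration is the time span from a track's first to its last frame,
#' `(last - first) * dt`.
#'
#' @param tracks a `track_set`.
#' @return data frame with `track_id`, `n_samples`, `duration_s`.
#' @export
track_durations <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  tt <- tracks$tracks
  sp <- split(tt$frame, tt$track_id)
  data.frame(track_id = as.integer(names(sp)),
             n_samples = lengths(sp),
             duration_s = vapply(sp, function(f) diff(range(f)), 1) *
               tracks$delta_t_min * 60,
             row.names = NULL)
}

#' Remove tracks shorter than the configured minimum duration
#'
#' @param tracks a `track_set`.
#' @param config a [tracking_config()]; defaults to the set's own config.
#' @return the filtered `track_set`; `stats$filter` records removed/kept
#'   counts.
#' @export
filter_tracks <- function(tracks, config = tracks$config) {
  stopifnot(inherits(tracks, "track_set"))
  d <- track_durations(tracks)
  keep_ids <- d$track_id[d$duration_s >= config$min_duration]
  out <- tracks
  out$tracks <- tracks$tracks[tracks$tracks$track_id %in% keep_ids, ]
  rownames(out$tracks) <- NULL
  out$stats$filter <- list(kept = length(keep_ids),
                           removed = nrow(d) - length(keep_ids),
                           min_duration = config$min_duration)
  out
}

#' Evaluate linking accuracy against simulator ground truth
#'
#' A frame-to-frame link (two consecutive non-gap samples of a track) is
#' correct when both detections originate from the same true nucleus.
#' Parent-to-child links across a division are tallied separately (the linker
#' has no division model, so one child may legitimately continue the parent's
#' track).
#'
#' @param tracks a `track_set` built from simulator-rendered frames (the
#'   detections must carry `truth_id`).
#' @param truth the originating `root_truth` (used for lineage).
#' @return list with `accuracy` (fraction of links joining the same
#'   nucleus), `accuracy_lineage` (same, counting parent-child links as
#'   correct), `n_links`, `n_switches` (wrong links excluding divisions).
#' @export
match_to_truth <- function(tracks, truth) {
  stopifnot(inherits(tracks, "track_set"), inherits(truth, "root_truth"))
  tt <- tracks$tracks[!tracks$tracks$gap, ]
  if (all(is.na(tt$truth_id))) stop("tracks carry no truth ids")
  tt <- tt[order(tt$track_id, tt$frame), ]
  same_track <- tt$track_id[-1] == tt$track_id[-nrow(tt)]
  a <- tt$truth_id[-nrow(tt)][same_track]
  b <- tt$truth_id[-1][same_track]
  n_links <- length(a)
  correct <- !is.na(a) & !is.na(b) & a == b
  par <- truth$nuclei$parent_id[match(b, truth$nuclei$nucleus_id)]
  div_link <- !is.na(a) & !is.na(par) & par == a
  list(accuracy = mean(correct),
       accuracy_lineage = mean(correct | div_link),
       n_links = n_links,
       n_switches = sum(!correct & !div_link))
}

#' Write / read a track table as CSV
#'
#' @param tracks a `track_set`.
#' @param path output CSV path.
#' @return `path` invisibly (write); a `track_set` (read).
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  df <- tracks$tracks
  df$delta_t_min <- tracks$delta_t_min
  # full-precision doubles so the table round-trips bit-identically
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      x <- sprintf("%.17g", df[[nm]])
      x[is.na(df[[nm]])] <- NA
      df[[nm]] <- x
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path)
  dt <- df$delta_t_min[1]
  df$delta_t_min <- NULL
  structure(list(tracks = df, config = tracking_config(),
                 delta_t_min = dt, stats = list()),
            class = "track_set")
}
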