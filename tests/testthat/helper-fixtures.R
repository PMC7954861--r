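# Shared fixtures: small, fast configurations used across test files.

# clean point-mode world: no noise, no divisions, no skew
quiet_config <- function(n_nuclei = 40, n_frames = 10, seed = 1, ...) {
  simulation_config(n_nuclei = n_nuclei, n_frames = n_frames, seed = seed,
                    skew = list(omega = 0),
                    lateral_drift = list(speed = 0),
                    division_rate = 0,
                    noise = list(jitter_sd = 0, dropout_rate = 0,
                                 false_positive_rate = 0, intensity_sd = 0),
                    ...)
}

# frame_set from explicit positions: pos_list[[frame]] = matrix n x 3
manual_frames <- function(pos_list, delta_t_min = 8.75, truth_ids = NULL) {
  rows <- lapply(seq_along(pos_list), function(f) {
    p <- pos_list[[f]]
    if (is.null(p) || nrow(p) == 0) return(NULL)
    data.frame(frame = f, x_um = p[, 1], y_um = p[, 2], z_um = p[, 3],
               truth_id = if (is.null(truth_ids)) NA_integer_ else
                 truth_ids[[f]])
  })
  det <- do.call(rbind, rows)
  frame_set(det, delta_t_min)
}

# canonical form of a track set ignoring track ids (for permutation tests)
track_canonical <- function(ts) {
  tt <- ts$tracks[!ts$tracks$gap, ]
  sp <- split(tt$det_id, tt$track_id)
  sort(unname(vapply(sp, function(x) paste(sort(x), collapse = ","), "")))
}

# analytic axial velocity of the simulator's stated field (control scenario)
axial_v <- function(y, cfg) {
  cfg$axial$v_plateau * plogis((y - cfg$axial$y_mid) / cfg$axial$width)
}
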