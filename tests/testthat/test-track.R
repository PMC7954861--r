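# Track linking: assignment optimality, gap closing, duration filter,
# conservation, truth matching.

test_that("two distant stationary detections give two full tracks", {
  pos <- lapply(1:5, function(f) rbind(c(0, 0, 0), c(0, 100, 0)))
  fs <- manual_frames(pos)
  ts <- link_tracks(fs, tracking_config(max_distance = 15))
  d <- track_durations(ts)
  expect_equal(nrow(d), 2)
  expect_equal(d$n_samples, c(5L, 5L))
})

test_that("a missed detection is bridged by one flagged gap sample", {
  pos <- lapply(1:5, function(f) {
    if (f == 3) NULL else rbind(c(0, 10 * f, 0))
  })
  fs <- manual_frames(pos)
  ts <- link_tracks(fs, tracking_config(max_gap = 3))
  tt <- ts$tracks
  expect_equal(length(unique(tt$track_id)), 1)
  expect_equal(sum(tt$gap), 1)
  expect_equal(tt$frame[tt$gap], 3)
  expect_equal(tt$y_um[tt$gap], 30)  # linear interpolation
})

test_that("gaps longer than max_gap split the track", {
  pos <- lapply(1:9, function(f) {
    if (f %in% 3:6) NULL else rbind(c(0, 5 * f, 0))
  })
  fs <- manual_frames(pos)
  ts <- link_tracks(fs, tracking_config(max_gap = 3))
  expect_equal(length(unique(ts$tracks$track_id)), 2)
  # and no track carries more than max_gap consecutive gap samples
  for (tid in unique(ts$tracks$track_id)) {
    g <- ts$tracks$gap[ts$tracks$track_id == tid]
    runs <- rle(g)
    expect_true(all(runs$lengths[runs$values] <= 3))
  }
})

test_that("noiseless well-separated linking reproduces lineage segments", {
  cfg <- quiet_config(n_nuclei = 60, n_frames = 12, seed = 4)
  cfg$division_rate <- 0.15
  tr <- simulate_root(cfg)
  fs <- render_frames(tr)
  ts <- link_tracks(fs)
  rep_ <- match_to_truth(ts, tr)
  expect_equal(rep_$accuracy_lineage, 1.0)
  # every non-division link joins one true nucleus
  expect_equal(rep_$n_switches, 0)
})

test_that("constant-velocity prediction survives a crossing better than none", {
  # two particles crossing within max_distance; switches stay localized
  t_seq <- 0:10
  p1 <- cbind(-50 + 10 * t_seq, 0, 0)
  p2 <- cbind(50 - 10 * t_seq, 2, 0)
  pos <- lapply(seq_along(t_seq), function(i) rbind(p1[i, ], p2[i, ]))
  fs <- manual_frames(pos, delta_t_min = 60,
                      truth_ids = lapply(t_seq, function(i) c(1L, 2L)))
  ts <- link_tracks(fs, tracking_config(max_distance = 15))
  tt <- ts$tracks[!ts$tracks$gap, ]
  # with exact constant-velocity motion the predictor resolves the crossing
  sp <- split(tt$truth_id, tt$track_id)
  expect_equal(length(sp), 2)
  for (s in sp) expect_equal(length(unique(s)), 1)
})

test_that("duration filter keeps exactly the tracks spanning >= min_duration", {
  pos <- lapply(1:40, function(f) {
    rows <- rbind(c(0, 5 * f, 0))
    if (f <= 2) rows <- rbind(rows, c(200, 5 * f, 0))
    rows
  })
  fs <- manual_frames(pos)  # dt 8.75 min
  ts <- link_tracks(fs)
  d0 <- track_durations(ts)
  expect_equal(sort(d0$n_samples), c(2L, 40L))
  filt <- filter_tracks(ts, tracking_config(min_duration = 3600))
  d <- track_durations(filt)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_samples, 40L)
  expect_equal(d$duration_s, 39 * 8.75 * 60)   # 341.25 min span
  expect_equal(filt$stats$filter$removed, 1)
  # min_duration 0 is the identity
  expect_identical(filter_tracks(ts, tracking_config(min_duration = 0))$tracks,
                   ts$tracks)
})

test_that("detections are conserved: each belongs to at most one track", {
  cfg <- quiet_config(n_nuclei = 80, n_frames = 8, seed = 5)
  cfg$noise <- list(jitter_sd = 0.5, dropout_rate = 0.05,
                    false_positive_rate = 0.02, intensity_sd = 1)
  fs <- render_frames(simulate_root(cfg))
  ts <- link_tracks(fs)
  ids <- ts$tracks$det_id[!is.na(ts$tracks$det_id)]
  expect_equal(anyDuplicated(ids), 0)
  expect_equal(length(ids), nrow(fs$detections))  # every detection assigned
})

test_that("hungarian assignment is invariant to detection order", {
  cfg <- quiet_config(n_nuclei = 50, n_frames = 6, seed = 6)
  cfg$noise$jitter_sd <- 0.5
  fs <- render_frames(simulate_root(cfg))
  det <- fs$detections
  set.seed(99)
  shuffled <- do.call(rbind, lapply(split(det, det$frame),
                                    function(d) d[sample(nrow(d)), ]))
  fs2 <- frame_set(shuffled, fs$delta_t_min)
  fs2$detections$det_id <- shuffled$det_id  # keep original ids for comparison
  expect_equal(track_canonical(link_tracks(fs)),
               track_canonical(link_tracks(fs2)))
})

test_that("padded LAP equals exhaustive matching on small instances", {
  set.seed(7)
  for (rep in 1:25) {
    nt <- sample(1:5, 1); nd <- sample(1:5, 1)
    cost <- matrix(runif(nt * nd, 0, 20), nt, nd)
    cost[cost > 12] <- NA                  # forbidden beyond max distance
    death <- runif(nt, 8, 20)
    sol <- rootkin:::solve_lap_padded(cost, death, birth = 12)
    oracle <- rootkin:::brute_force_match(cost, death, birth = 12)
    cost_of <- function(link) {
      linked <- !is.na(link)
      sum(cost[cbind(which(linked), link[linked])]) +
        sum(death[!linked]) + 12 * (nd - sum(linked))
    }
    expect_equal(cost_of(sol), oracle$cost, tolerance = 1e-9)
  }
})

test_that("greedy assignment is available and conserves detections", {
  cfg <- quiet_config(n_nuclei = 40, n_frames = 5, seed = 8)
  fs <- render_frames(simulate_root(cfg))
  ts <- link_tracks(fs, tracking_config(assignment = "greedy"))
  rep_ <- match_to_truth(ts, simulate_root(cfg))
  expect_equal(rep_$accuracy, 1.0)
})

test_that("track tables round-trip through CSV", {
  cfg <- quiet_config(n_nuclei = 15, n_frames = 4, seed = 9)
  ts <- link_tracks(render_frames(simulate_root(cfg)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, path)
  back <- read_tracks(path)
  expect_equal(back$tracks$x_um, ts$tracks$x_um)
  expect_equal(back$delta_t_min, ts$delta_t_min)
  expect_equal(validate_io(path, "tracks")$ok, TRUE)
})
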