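two_cell_traj <- function(n_frames = 1, speed = 0, arena = c(40, 40)) {
  d1 <- data.frame(cell = 1L, frame = seq_len(n_frames),
                   x_um = 10 + speed * (seq_len(n_frames) - 1), y_um = 10,
                   orientation_rad = 0.3, length_um = 5, width_um = 0.8,
                   speed_um_min = NA_real_)
  d2 <- data.frame(cell = 2L, frame = seq_len(n_frames),
                   x_um = 10 + speed * (seq_len(n_frames) - 1), y_um = 30,
                   orientation_rad = 2.1, length_um = 5, width_um = 0.8,
                   speed_um_min = NA_real_)
  trajectory_set(rbind(d1, d2), frame_interval = 10, arena = arena)
}

test_that("flat and empty images segment to no detections", {
  expect_equal(nrow(segment_frame(matrix(0, 50, 50), 0.5)), 0)
  expect_equal(nrow(segment_frame(matrix(3.7, 50, 50), 0.5)), 0)
})

test_that("a single rendered capsule is recovered with faithful geometry", {
  tr <- two_cell_traj()[1, ]
  tr <- trajectory_set(tr, 10, c(40, 40))
  st <- suppressWarnings(
    render_frames(tr, pixel_size = 0.25, psf_sigma = 0.2, noise_sd = 0, seed = 1))
  det <- segment_frame(st$frames[, , 1], 0.25)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - 10), 0.25)       # within 1 px
  expect_lt(abs(det$y_um - 10), 0.25)
  expect_lt(abs(det$major_um - 5) / 5, 0.2)
  expect_lt(abs(det$minor_um - 0.8) / 0.8, 0.2)
  # axial orientation agrees modulo pi
  dth <- abs(det$orientation_rad - 0.3) %% pi
  expect_lt(min(dth, pi - dth), 0.05)
})

test_that("well-separated cells give one detection each, matched to truth", {
  tr <- two_cell_traj()
  st <- suppressWarnings(
    render_frames(tr, pixel_size = 0.25, psf_sigma = 0.2, noise_sd = 0, seed = 1))
  det <- segment_frame(st$frames[, , 1], 0.25)
  expect_equal(nrow(det), 2)
  ids <- match_to_truth(det, tr[tr$frame == 1, ])
  expect_setequal(ids, c(1, 2))
  for (i in seq_len(2)) {
    truth <- tr[tr$cell == ids[i] & tr$frame == 1, ]
    expect_lt(sqrt((det$x_um[i] - truth$x_um)^2 + (det$y_um[i] - truth$y_um)^2),
              0.5)
  }
})

test_that("assignment solver matches the brute-force optimum", {
  set.seed(99)
  for (rep in 1:25) {
    nr <- sample(1:5, 1); nc <- sample(nr:6, 1)
    cost <- matrix(runif(nr * nc), nr, nc)
    got <- mxquant:::solve_assignment(cost)
    expect_true(all(!is.na(got)))
    expect_equal(sum(cost[cbind(seq_len(nr), got)]),
                 brute_force_assignment(cost)$cost, tolerance = 1e-12)
  }
})

test_that("forbidden links leave detections unassigned", {
  cost <- matrix(1e9, 2, 2); cost[1, 1] <- 0.5
  got <- mxquant:::solve_assignment(cost)
  expect_equal(got[1], 1L)
  expect_true(is.na(got[2]))
})

test_that("one detection per frame for 10 frames gives a single track", {
  det <- lapply(1:10, function(f) {
    data.frame(x_um = 5 + 0.3 * f, y_um = 5, orientation_rad = 0,
               major_um = 5, minor_um = 0.8, area_um2 = 4,
               mean_intensity = 1)
  })
  tracks <- link_tracks(det, tracking_config(), frame_interval = 10)
  expect_equal(length(unique(tracks$cell)), 1)
  expect_equal(tracks$frame, 1:10)
})

test_that("parallel paths beyond the link gate yield two switch-free tracks", {
  tr <- two_cell_traj(n_frames = 20, speed = 0.8)   # 20 um apart, 0.8 um/frame
  st <- suppressWarnings(
    render_frames(tr, pixel_size = 0.25, psf_sigma = 0.2, noise_sd = 0, seed = 1))
  tracks <- track_stack(st, tracking_config(max_link_distance = 5))
  expect_equal(length(unique(tracks$cell)), 2)
  for (d in split(tracks, tracks$cell)) {
    truth_ids <- vapply(seq_len(nrow(d)), function(i) {
      fr <- tr[tr$frame == d$frame[i], ]
      match_to_truth(d[i, ], fr)
    }, numeric(1))
    expect_equal(length(unique(truth_ids)), 1)   # no identity switches
  }
})

test_that("non-contiguous frame indices raise an error naming the gap", {
  df <- data.frame(frame = c(1, 2, 4), x_um = 1, y_um = 1,
                   orientation_rad = 0, major_um = 5, minor_um = 0.8,
                   area_um2 = 4, mean_intensity = 1)
  expect_error(link_tracks(df), "missing frames: 3")
})

test_that("tracking is deterministic and tracks never reuse a frame", {
  cfg <- motility_sim_config(arena_width = 60, arena_height = 60, n_cells = 8,
                             duration = 300, seed = 21)
  tr <- simulate_trajectories(cfg)
  st <- suppressWarnings(
    render_frames(tr, pixel_size = 0.25, psf_sigma = 0.2, noise_sd = 0.02,
                  seed = 21))
  t1 <- track_stack(st); t2 <- track_stack(st)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  for (d in split(t1, t1$cell)) expect_false(anyDuplicated(d$frame) > 0)
})

test_that("simulate-render-segment-link recovers tracks at sub-pixel accuracy", {
  # well-separated slow cells so identity is unambiguous
  cfg <- motility_sim_config(arena_width = 80, arena_height = 80, n_cells = 6,
                             duration = 300, speed_mean = 6, speed_sd = 2,
                             seed = 13)
  tr <- simulate_trajectories(cfg)
  st <- suppressWarnings(
    render_frames(tr, pixel_size = 0.25, psf_sigma = 0.2, noise_sd = 0, seed = 13))
  tracks <- track_stack(st)
  expect_equal(length(unique(tracks$cell)), cfg$n_cells)
  err2 <- vapply(seq_len(nrow(tracks)), function(i) {
    fr <- tr[tr$frame == tracks$frame[i], ]
    min((fr$x_um - tracks$x_um[i])^2 + (fr$y_um - tracks$y_um[i])^2)
  }, numeric(1))
  expect_lt(sqrt(mean(err2)), 0.25)        # pooled RMSE < 1 px
})

test_that("link accuracy against ground truth exceeds 99% on a clean movie", {
  cfg <- motility_sim_config(arena_width = 100, arena_height = 100,
                             n_cells = 20, duration = 990, seed = 31)
  tr <- simulate_trajectories(cfg)
  st <- suppressWarnings(
    render_frames(tr, pixel_size = 0.4, psf_sigma = 0.2, noise_sd = 0, seed = 31))
  # reject merged blobs of crossing cells (single cell is ~4 um^2) so that
  # transient contacts become gaps rather than ambiguous links
  det <- segment_stack(st, tracking_config(max_area = 6))
  tracks <- link_tracks(det, tracking_config(max_area = 6),
                        frame_interval = 10, arena = c(100, 100))
  # audit consecutive-frame links: both endpoints must map to the same cell
  good <- 0L; total <- 0L
  for (d in split(tracks, tracks$cell)) {
    if (nrow(d) < 2) next
    ids <- vapply(seq_len(nrow(d)), function(i) {
      match_to_truth(d[i, ], tr[tr$frame == d$frame[i], ])
    }, numeric(1))
    consec <- diff(d$frame) == 1
    total <- total + sum(consec)
    good <- good + sum(consec & (diff(ids) == 0))
  }
  expect_gt(total, 1000)
  expect_gte(good / total, 0.99)
})
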