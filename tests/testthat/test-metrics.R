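make_traj <- function(x, y, frames = seq_along(x), width = 0.8,
                      dt = 10, arena = c(50, 50), cell = 1L) {
  n <- length(x)
  df <- data.frame(cell = rep(cell, n), frame = frames, x_um = x,
                   y_um = y, orientation_rad = rep(0, n),
                   length_um = rep(5, n), width_um = rep(width, n),
                   speed_um_min = rep(NA_real_, n))
  trajectory_set(df, frame_interval = dt, arena = arena)
}

test_that("stationary tracks have zero instantaneous velocity", {
  tr <- make_traj(rep(5, 10), rep(5, 10))
  v <- instantaneous_velocities(tr)
  expect_equal(v$pooled, rep(0, 9))
  expect_equal(v$mean, 0)
})

test_that("unit displacement per 10 s step converts to 6 um/min", {
  tr <- make_traj(seq(5, 14), rep(5, 10))
  v <- instantaneous_velocities(tr)
  expect_equal(v$pooled, rep(6, 9), tolerance = 1e-12)
})

test_that("steps spanning gap frames are excluded from the profile", {
  tr <- make_traj(c(5, 6, 9), y = rep(5, 3), frames = c(1, 2, 4))
  v <- instantaneous_velocities(tr)
  expect_equal(v$n_steps, 1)
  expect_equal(v$pooled, 6, tolerance = 1e-12)
})

test_that("velocity estimator is unbiased on ground-truth tracks", {
  cfg <- motility_sim_config(n_cells = 20, duration = 500, speed_mean = 9,
                             speed_sd = 3, seed = 2)
  tr <- simulate_trajectories(cfg)
  # the generating step speeds carried by the set are recovered exactly
  gen <- unlist(lapply(split(tr, tr$cell), function(d) d$speed_um_min[-1]),
                use.names = FALSE)
  v <- instantaneous_velocities(tr)
  expect_equal(v$n_steps, length(gen))
  # displacement-based speeds equal the generating speeds except across
  # boundary reflections, where the chord is shorter than the path
  for (cell in unique(tr$cell)) {
    d <- tr[tr$cell == cell, ]
    got <- v$per_track[[as.character(cell)]]
    truth <- d$speed_um_min[-1]
    expect_true(all(got <= truth + 1e-9))
  }
  matched <- abs(v$pooled - gen) < 1e-9
  expect_gt(mean(matched), 0.95)
})

test_that("percent reduction reproduces worked examples", {
  expect_equal(percent_reduction(10.36, 6.02), 41.89)
  expect_equal(percent_reduction(7.3, 7.3), 0)
  expect_equal(percent_reduction(10, 5), 50)
  expect_error(percent_reduction(0, 5), "reference_mean")
  expect_error(percent_reduction(-2, 5), "reference_mean")
})

test_that("Student's t-test follows the pooled-variance textbook formula", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  got <- student_t_test(a, b)
  # independent hand computation
  sp2 <- ((3 - 1) * var(a) + (3 - 1) * var(b)) / (3 + 3 - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(abs(t_hand), df = 4, lower.tail = FALSE)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)
})

test_that("degenerate t-test cases use the documented conventions", {
  expect_equal(student_t_test(c(1, 1, 1), c(1, 1, 1)), list(t = 0, p = 1))
  z <- student_t_test(c(2, 2), c(1, 1))
  expect_equal(z$p, 0)
  expect_true(is.infinite(z$t) && z$t > 0)
  expect_error(student_t_test(1, c(1, 2)), "at least 2")
})

test_that("coverage of an empty set is zero and of one disc is pi r^2 / A", {
  empty <- make_traj(numeric(0), numeric(0), frames = integer(0))
  expect_equal(cumulative_coverage(empty, arena = c(50, 50),
                                   grid_pixel_size = 0.5)$coverage_fraction, 0)
  tr <- make_traj(25, 25, width = 8)       # disc radius 4 um
  cov <- cumulative_coverage(tr, grid_pixel_size = 0.25)
  expected <- pi * 4^2 / (50 * 50)
  # rasterization error bounded by a 2-px perimeter band
  band <- 2 * pi * 4 * 2 * 0.25 / (50 * 50)
  expect_lt(abs(cov$coverage_fraction - expected), band)
})

test_that("coverage raster equals the brute-force per-pixel union oracle", {
  for (seed in c(101, 202)) {
    cfg <- motility_sim_config(arena_width = 64, arena_height = 64,
                               n_cells = 10, duration = 200, seed = seed)
    tr <- simulate_trajectories(cfg)
    cov <- suppressWarnings(
      cumulative_coverage(tr, grid_pixel_size = 0.5))
    oracle <- brute_force_coverage(tr, c(64, 64), 0.5)
    expect_identical(cov$raster, oracle)
  }
})

test_that("cumulative coverage fractions are non-decreasing", {
  cfg <- motility_sim_config(n_cells = 10, duration = 500, seed = 8)
  tr <- simulate_trajectories(cfg)
  cov <- suppressWarnings(cumulative_coverage(tr, grid_pixel_size = 0.5))
  expect_false(is.unsorted(cov$cumulative_fraction))
  expect_equal(tail(cov$cumulative_fraction, 1), cov$coverage_fraction)
})

test_that("density heatmap conserves mass and localizes point masses", {
  hm1 <- density_heatmap(cbind(5.2, 7.9), bin_size = 1, sigma = 0,
                         arena = c(20, 20))
  expect_equal(sum(hm1$map), 1)
  expect_equal(hm1$map[8, 6], 1)           # row = y bin, col = x bin

  set.seed(4)
  pts <- cbind(runif(500, 0, 40), runif(500, 0, 40))
  hm <- density_heatmap(pts, bin_size = 2, sigma = 3, arena = c(40, 40))
  expect_equal(sum(hm$map), 500, tolerance = 1e-9)
  expect_true(all(hm$map >= 0))
})

test_that("two separated clusters produce maxima in their center bins", {
  set.seed(11)
  c1 <- cbind(rnorm(200, 10, 0.8), rnorm(200, 10, 0.8))
  c2 <- cbind(rnorm(200, 35, 0.8), rnorm(200, 30, 0.8))
  hm <- density_heatmap(rbind(c1, c2), bin_size = 1, sigma = 1,
                        arena = c(45, 40))
  ord <- order(hm$map, decreasing = TRUE)
  top2 <- arrayInd(ord[1:2], dim(hm$map))      # (row = y bin, col = x bin)
  centers <- rbind(c(10, 10), c(30, 35))
  d <- outer(seq_len(2), seq_len(2), Vectorize(function(i, j) {
    max(abs(top2[i, ] - centers[j, ]))
  }))
  # each summit sits in (or adjacent to) a distinct cluster-center bin
  expect_true(all(apply(d, 1, min) <= 1))
  expect_setequal(apply(d, 1, which.min), c(1, 2))
})
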