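#' Configuration for the rod-cell motility simulator
#'
#' Defines the arena, imaging geometry and kinematic statistics of a
#' population of rod-shaped surface-motile cells. Defaults emulate
#' single-cell twitching-motility assays of *Myxococcus xanthus* in
#' methylcellulose: movies of 1,000 s at 10 s intervals, cells about
#' 5 x 0.8 um moving at around 5-15 um/min with persistent runs
#' interrupted by occasional reversals.
#'
#' @param arena_width,arena_height arena size in um.
#' @param pixel_size rendering/trail raster pixel size, um per pixel.
#' @param n_cells number of cells.
#' @param duration total observation time, s.
#' @param frame_interval time between frames, s.
#' @param speed_mean,speed_sd mean and SD of per-step speeds, um/min. Speeds
#'   are drawn from a zero-truncated normal whose realised moments equal
#'   these values.
#' @param persistence directional persistence in `[0, 1]`; 1 gives straight
#'   runs, 0 gives an uncorrelated random walk. The per-step heading
#'   perturbation SD is `(1 - persistence) * pi` radians.
#' @param reversal_rate rate of instantaneous 180-degree reversals, events/s.
#' @param trail_following_strength weight in `[0, 1]` with which headings are
#'   steered toward the locally densest deposited trail.
#' @param trail_decay multiplicative trail retention per frame in `(0, 1]`.
#' @param cell_length_mean,cell_width_mean cell body dimensions, um.
#' @param seed integer RNG seed; identical configs and seeds give
#'   bit-identical output.
#' @return object of class `motility_sim_config` (a named list).
#' @export
motility_sim_config <- function(arena_width = 100, arena_height = 100,
                                pixel_size = 0.5, n_cells = 20,
                                duration = 1000, frame_interval = 10,
                                speed_mean = 10.36, speed_sd = 5.03,
                                persistence = 0.85, reversal_rate = 0.002,
                                trail_following_strength = 0,
                                trail_decay = 0.995,
                                cell_length_mean = 5, cell_width_mean = 0.8,
                                seed = 1) {
  check_positive(arena_width, "arena_width")
  check_positive(arena_height, "arena_height")
  check_positive(pixel_size, "pixel_size")
  check_positive(n_cells, "n_cells")
  check_positive(duration, "duration")
  check_positive(frame_interval, "frame_interval")
  if (duration < frame_interval) stop_field("duration", "must be >= frame_interval")
  check_positive(speed_mean, "speed_mean", strict = FALSE)
  check_positive(speed_sd, "speed_sd", strict = FALSE)
  check_fraction(persistence, "persistence")
  check_positive(reversal_rate, "reversal_rate", strict = FALSE)
  check_fraction(trail_following_strength, "trail_following_strength")
  if (trail_decay <= 0 || trail_decay > 1) stop_field("trail_decay", "must be in (0, 1]")
  check_positive(cell_length_mean, "cell_length_mean")
  check_positive(cell_width_mean, "cell_width_mean")
  if (cell_width_mean > cell_length_mean) {
    stop_field("cell_width_mean", "must not exceed cell_length_mean")
  }
  structure(list(
    arena_width = arena_width, arena_height = arena_height,
    pixel_size = pixel_size, n_cells = as.integer(n_cells),
    duration = duration, frame_interval = frame_interval,
    speed_mean = speed_mean, speed_sd = speed_sd,
    persistence = persistence, reversal_rate = reversal_rate,
    trail_following_strength = trail_following_strength,
    trail_decay = trail_decay,
    cell_length_mean = cell_length_mean, cell_width_mean = cell_width_mean,
    seed = as.integer(seed)
  ), class = "motility_sim_config")
}

#' Trajectory container
#'
#' A data frame of per-cell, per-frame positions and morphology with imaging
#' metadata attached. The common currency between the simulator, the tracker
#' and the motility metrics.
#'
#' @param df data frame with columns `cell`, `frame`, `x_um`, `y_um`,
#'   `orientation_rad`, `length_um`, `width_um`, `speed_um_min` (NA on each
#'   track's first frame), and optionally `gap_flag`.
#' @param frame_interval s between frames.
#' @param arena numeric length-2, arena width and height in um.
#' @param provenance `"ground_truth"` or `"tracked"`.
#' @return object of class `trajectory_set`.
#' @export
trajectory_set <- function(df, frame_interval, arena,
                           provenance = c("ground_truth", "tracked")) {
  provenance <- match.arg(provenance)
  needed <- c("cell", "frame", "x_um", "y_um", "orientation_rad",
              "length_um", "width_um", "speed_um_min")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("trajectory data frame lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_positive(frame_interval, "frame_interval")
  structure(df[order(df$cell, df$frame), , drop = FALSE],
            frame_interval = frame_interval,
            arena = arena, provenance = provenance,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set: %d track(s), %d rows, dt = %g s, %s>\n",
              length(unique(x$cell)), nrow(x),
              attr(x, "frame_interval"), attr(x, "provenance")))
  invisible(x)
}

# Trail raster sampling: value at continuous position (x, y) um.
trail_at <- function(trail, x, y, ps) {
  nr <- nrow(trail); nc <- ncol(trail)
  c_ <- pmin(pmax(ceiling(x / ps), 1L), nc)
  r_ <- pmin(pmax(ceiling(y / ps), 1L), nr)
  trail[cbind(r_, c_)]
}

#' Simulate ground-truth cell trajectories
#'
#' Persistent random walk with Poisson-timed instantaneous reversals.
#' Per-step speeds are drawn from a zero-truncated normal matching the
#' configured mean/SD. When `trail_following_strength > 0` every cell
#' deposits an exponentially decaying occupancy trail on a shared raster and
#' headings are steered toward the densest trail among look-ahead directions
#' within +/-60 degrees. Arena boundaries are reflective.
#'
#' @param config a [motility_sim_config()].
#' @return a [trajectory_set()] with one row per cell per frame;
#'   `speed_um_min` holds the generating speed of the step that leads into
#'   each frame (NA at the first frame).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "motility_sim_config"))
  set.seed(config$seed)
  W <- config$arena_width; H <- config$arena_height
  dt <- config$frame_interval
  n_frames <- floor(config$duration / dt) + 1L
  n <- config$n_cells

  if (config$speed_sd > 0 && config$speed_mean > 0) {
    mm <- truncnorm_match_moments(config$speed_mean, config$speed_sd)
  } else if (config$speed_sd == 0) {
    mm <- list(mu0 = config$speed_mean, sigma0 = 0)
  } else {
    stop_field("speed_mean", "must be > 0 when speed_sd > 0")
  }

  margin <- config$cell_length_mean / 2
  x <- runif(n, margin, W - margin)
  y <- runif(n, margin, H - margin)
  heading <- runif(n, 0, 2 * pi)
  len <- rep(config$cell_length_mean, n)
  wid <- rep(config$cell_width_mean, n)

  ps <- config$pixel_size
  use_trail <- config$trail_following_strength > 0
  if (use_trail) {
    trail <- matrix(0, nrow = ceiling(H / ps), ncol = ceiling(W / ps))
    look <- deg2rad(seq(-60, 60, by = 20))
  }
  turn_sd <- (1 - config$persistence) * pi
  p_rev <- 1 - exp(-config$reversal_rate * dt)

  res <- vector("list", n_frames)
  res[[1]] <- data.frame(cell = seq_len(n), frame = 1L, x_um = x, y_um = y,
                         orientation_rad = heading %% pi,
                         length_um = len, width_um = wid,
                         speed_um_min = NA_real_)

  deposit <- function(trail) {
    # stamp trail along each cell's body axis (5 samples tip to tip)
    for (i in seq_len(n)) {
      s <- seq(-len[i] / 2, len[i] / 2, length.out = 5)
      xs <- x[i] + s * cos(heading[i]); ys <- y[i] + s * sin(heading[i])
      cc <- pmin(pmax(ceiling(xs / ps), 1L), ncol(trail))
      rr <- pmin(pmax(ceiling(ys / ps), 1L), nrow(trail))
      trail[cbind(rr, cc)] <- trail[cbind(rr, cc)] + 1
    }
    trail
  }
  if (use_trail) trail <- deposit(trail)

  for (f in 2L:n_frames) {
    rev_flip <- runif(n) < p_rev
    heading <- wrap_angle(heading + rnorm(n, 0, turn_sd) + ifelse(rev_flip, pi, 0))

    if (use_trail) {
      step_len_nominal <- config$speed_mean * dt / 60
      for (i in seq_len(n)) {
        cand <- wrap_angle(heading[i] + look)
        lx <- x[i] + pmax(step_len_nominal, ps) * cos(cand)
        ly <- y[i] + pmax(step_len_nominal, ps) * sin(cand)
        vals <- trail_at(trail, pmin(pmax(lx, 0), W), pmin(pmax(ly, 0), H), ps)
        if (max(vals) > 0) {
          best <- cand[which.max(vals)]
          d <- atan2(sin(best - heading[i]), cos(best - heading[i]))
          heading[i] <- wrap_angle(heading[i] + config$trail_following_strength * d)
        }
      }
    }

    speeds <- rtruncnorm0(n, mm$mu0, mm$sigma0)
    step <- speeds * dt / 60
    x <- x + step * cos(heading)
    y <- y + step * sin(heading)

    # reflective boundaries (position and heading)
    out_lo <- x < 0; out_hi <- x > W
    x[out_lo] <- -x[out_lo]; x[out_hi] <- 2 * W - x[out_hi]
    heading[out_lo | out_hi] <- wrap_angle(pi - heading[out_lo | out_hi])
    out_lo <- y < 0; out_hi <- y > H
    y[out_lo] <- -y[out_lo]; y[out_hi] <- 2 * H - y[out_hi]
    heading[out_lo | out_hi] <- wrap_angle(-heading[out_lo | out_hi])

    if (use_trail) {
      trail <- trail * config$trail_decay
      trail <- deposit(trail)
    }

    res[[f]] <- data.frame(cell = seq_len(n), frame = f, x_um = x, y_um = y,
                           orientation_rad = heading %% pi,
                           length_um = len, width_um = wid,
                           speed_um_min = speeds)
  }

  trajectory_set(do.call(rbind, res), frame_interval = dt,
                 arena = c(W, H), provenance = "ground_truth")
}
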