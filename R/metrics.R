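#' Instantaneous velocity profile of a trajectory set
#'
#' Per step, speed is the Euclidean displacement between detections in
#' consecutive frames divided by the frame interval, converted to um/min.
#' Steps spanning skipped (gap) frames are excluded. Speeds are pooled
#' across tracks at step level.
#'
#' @param traj a [trajectory_set()].
#' @param per_track_means if `TRUE`, also aggregate a per-track mean speed.
#' @return object of class `velocity_profile`: list with `pooled` (numeric
#'   vector of step speeds, um/min), `per_track` (named list), `mean`, `sd`,
#'   `n_steps`, and optionally `track_means`.
#' @export
instantaneous_velocities <- function(traj, per_track_means = FALSE) {
  stopifnot(inherits(traj, "trajectory_set"))
  dt <- attr(traj, "frame_interval")
  per_track <- lapply(split(traj[, c("frame", "x_um", "y_um")], traj$cell),
                      function(d) {
    if (nrow(d) < 2) return(numeric(0))
    d <- d[order(d$frame), ]
    keep <- diff(d$frame) == 1L
    sp <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2) / dt * 60
    sp[keep]
  })
  n_single <- sum(vapply(split(traj$frame, traj$cell), length, 1L) < 2)
  if (n_single > 0) {
    message(n_single, " single-detection track(s) contributed no steps")
  }
  pooled <- unlist(per_track, use.names = FALSE)
  out <- list(pooled = pooled, per_track = per_track,
              mean = if (length(pooled)) mean(pooled) else NA_real_,
              sd = if (length(pooled) > 1) sd(pooled) else NA_real_,
              n_steps = length(pooled))
  if (per_track_means) {
    out$track_means <- vapply(per_track, function(v)
      if (length(v)) mean(v) else NA_real_, 1)
  }
  structure(out, class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile: %d steps, mean %.2f +/- %.2f um/min>\n",
              x$n_steps, x$mean, x$sd))
  invisible(x)
}

#' Percent reduction of a test mean relative to a reference mean
#'
#' `100 * (reference - test) / reference`, reported to 2 decimals.
#'
#' @param reference_mean,test_mean group means (same units);
#'   `reference_mean` must be > 0.
#' @return percent reduction (negative for an increase).
#' @export
percent_reduction <- function(reference_mean, test_mean) {
  if (!is.numeric(reference_mean) || reference_mean <= 0) {
    stop_field("reference_mean", "must be > 0")
  }
  round(100 * (reference_mean - test_mean) / reference_mean, 2)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Pooled-variance two-sample t statistic with a two-sided p-value. With
#' zero pooled variance the conventions are: equal means give `t = 0,
#' p = 1`; unequal means give `t = +/-Inf, p = 0`.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return list with `t` and `p`.
#' @export
student_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample must have at least 2 observations", call. = FALSE)
  }
  if (var(sample_a) == 0 && var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(sample_a) - mean(sample_b)) * Inf, p = 0))
  }
  ht <- t.test(sample_a, sample_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' Cumulative surface coverage of tracked cells
#'
#' For every detection a disc of radius equal to the cell's minor semi-axis
#' (half the fitted width) is stamped at the centroid onto an arena raster;
#' coverage is the union over all cells and frames. A pixel is covered when
#' its center lies within the disc.
#'
#' @param traj a [trajectory_set()].
#' @param arena arena width/height in um; defaults to the set's metadata.
#' @param grid_pixel_size raster pixel size, um.
#' @param radius `"semi_minor"` (default: disc radius = width/2) or
#'   `"minor"` (radius = full fitted width).
#' @return object of class `coverage_map`: list with `raster` (logical
#'   matrix), `coverage_fraction`, `cumulative_fraction` (per frame,
#'   non-decreasing), `grid_pixel_size`.
#' @export
cumulative_coverage <- function(traj, arena = NULL, grid_pixel_size = 0.5,
                                radius = c("semi_minor", "minor")) {
  stopifnot(inherits(traj, "trajectory_set"))
  radius <- match.arg(radius)
  check_positive(grid_pixel_size, "grid_pixel_size")
  if (is.null(arena)) arena <- attr(traj, "arena")
  nr <- ceiling(arena[2] / grid_pixel_size)
  nc <- ceiling(arena[1] / grid_pixel_size)
  raster <- matrix(FALSE, nr, nc)
  frames <- if (nrow(traj)) sort(unique(traj$frame)) else integer(0)
  cum_frac <- numeric(length(frames))
  if (nrow(traj)) {
    rad <- if (radius == "semi_minor") traj$width_um / 2 else traj$width_um
    if (any(rad < grid_pixel_size)) {
      warning("grid_pixel_size larger than the smallest disc radius; ",
              "coverage will be quantization-limited", call. = FALSE)
    }
    ps <- grid_pixel_size
    for (k in seq_along(frames)) {
      idx <- which(traj$frame == frames[k])
      for (i in idx) {
        r <- rad[i]; cx <- traj$x_um[i]; cy <- traj$y_um[i]
        cols <- max(1L, floor((cx - r) / ps)):min(nc, ceiling((cx + r) / ps))
        rows <- max(1L, floor((cy - r) / ps)):min(nr, ceiling((cy + r) / ps))
        if (!length(cols) || !length(rows)) next
        dx2 <- ((cols - 0.5) * ps - cx)^2
        dy2 <- ((rows - 0.5) * ps - cy)^2
        inside <- outer(dy2, dx2, "+") <= r * r
        raster[rows, cols] <- raster[rows, cols] | inside
      }
      cum_frac[k] <- sum(raster) / length(raster)
    }
  }
  structure(list(raster = raster,
                 coverage_fraction = sum(raster) / length(raster),
                 cumulative_fraction = cum_frac,
                 grid_pixel_size = grid_pixel_size),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("<coverage_map: %d x %d px, coverage %.1f%%>\n",
              nrow(x$raster), ncol(x$raster), 100 * x$coverage_fraction))
  invisible(x)
}

#' Gaussian-smoothed 2-D density heatmap of cell center coordinates
#'
#' A 2-D histogram of points smoothed with a normalized Gaussian kernel
#' under reflect padding, so the array sum equals the number of points
#' (mass conservation).
#'
#' @param points matrix or data frame whose first two columns are x and y in
#'   um (columns named `x_um`/`y_um` are used when present).
#' @param bin_size spatial bin size, um.
#' @param sigma smoothing SD in um (0 disables smoothing).
#' @param arena arena width/height in um; defaults to the point bounding
#'   box.
#' @return object of class `density_heatmap`: list with `map` (matrix,
#'   rows = y bins), `bin_size`, `sigma`.
#' @export
density_heatmap <- function(points, bin_size, sigma, arena = NULL) {
  check_positive(bin_size, "bin_size")
  check_positive(sigma, "sigma", strict = FALSE)
  if (is.data.frame(points)) {
    xy <- if (all(c("x_um", "y_um") %in% names(points))) {
      cbind(points$x_um, points$y_um)
    } else as.matrix(points[, 1:2])
  } else xy <- as.matrix(points)[, 1:2, drop = FALSE]
  if (is.null(arena)) {
    arena <- if (nrow(xy)) c(max(xy[, 1]), max(xy[, 2])) else c(1, 1)
  }
  nr <- max(1L, ceiling(arena[2] / bin_size))
  nc <- max(1L, ceiling(arena[1] / bin_size))
  map <- matrix(0, nr, nc)
  if (nrow(xy)) {
    cc <- pmin(pmax(ceiling(xy[, 1] / bin_size), 1L), nc)
    rr <- pmin(pmax(ceiling(xy[, 2] / bin_size), 1L), nr)
    for (i in seq_along(cc)) map[rr[i], cc[i]] <- map[rr[i], cc[i]] + 1
    if (sigma > 0) map <- gauss_smooth2d(map, sigma / bin_size)
  }
  structure(list(map = map, bin_size = bin_size, sigma = sigma),
            class = "density_heatmap")
}
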