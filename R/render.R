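#' Frame stack container
#'
#' Time-ordered grayscale frames with imaging metadata. Frames are stored as
#' a numeric array `[row, col, frame]`; the pixel at `[r, c]` covers the
#' square `((c-1)*ps, c*ps] x ((r-1)*ps, r*ps]` um with the origin at the
#' top-left, x increasing along columns.
#'
#' @param frames numeric array `[nrow, ncol, n_frames]`.
#' @param pixel_size um per pixel.
#' @param frame_interval s between frames.
#' @param seed seed used to generate the stack (provenance), or NA.
#' @return object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size, frame_interval, seed = NA_integer_) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, seed = seed),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack: %d frame(s) of %d x %d px, %g um/px, dt = %g s>\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

# Stamp an oriented capsule (segment of half-length hl dilated by radius r)
# onto `img`, pixel centers at ((c-0.5)*ps, (r-0.5)*ps).
stamp_capsule <- function(img, ps, cx, cy, theta, length_um, width_um) {
  r <- width_um / 2
  hl <- max(length_um / 2 - r, 0)
  ex <- hl * cos(theta); ey <- hl * sin(theta)
  pad <- r + ps
  cols <- max(1L, floor((cx - abs(ex) - pad) / ps)):min(ncol(img), ceiling((cx + abs(ex) + pad) / ps))
  rows <- max(1L, floor((cy - abs(ey) - pad) / ps)):min(nrow(img), ceiling((cy + abs(ey) + pad) / ps))
  if (!length(cols) || !length(rows)) return(img)
  px <- (cols - 0.5) * ps
  py <- (rows - 0.5) * ps
  X <- matrix(px, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  Y <- matrix(py, nrow = length(rows), ncol = length(cols))
  # distance from pixel center to the capsule spine segment
  wx <- X - (cx - ex); wy <- Y - (cy - ey)
  seg2 <- (2 * ex)^2 + (2 * ey)^2
  tproj <- if (seg2 > 0) pmin(pmax((wx * 2 * ex + wy * 2 * ey) / seg2, 0), 1) else 0
  dx <- wx - tproj * 2 * ex; dy <- wy - tproj * 2 * ey
  inside <- (dx * dx + dy * dy) <= r * r
  sub <- img[rows, cols, drop = FALSE]
  sub[inside] <- 1
  img[rows, cols] <- sub
  img
}

#' Render trajectories into a synthetic time-lapse movie
#'
#' Each cell is drawn as an oriented capsule (rectangle with semicircular
#' caps) of its length and width, blurred with a Gaussian point-spread
#' kernel, with additive Gaussian background noise.
#'
#' @param traj a [trajectory_set()].
#' @param pixel_size um per pixel of the rendered frames.
#' @param psf_sigma Gaussian blur SD in um (0 disables blurring).
#' @param noise_sd additive Gaussian noise SD in intensity units (cell
#'   amplitude is 1).
#' @param seed RNG seed for the noise.
#' @param n_frames number of frames; defaults to the trajectory span. Must be
#'   given for an empty trajectory set.
#' @return a [frame_stack()].
#' @export
render_frames <- function(traj, pixel_size = 0.5, psf_sigma = 0.2,
                          noise_sd = 0.02, seed = 1, n_frames = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  check_positive(pixel_size, "pixel_size")
  check_positive(psf_sigma, "psf_sigma", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  arena <- attr(traj, "arena")
  if (is.null(n_frames)) {
    if (!nrow(traj)) stop("n_frames must be given for an empty trajectory set",
                          call. = FALSE)
    n_frames <- max(traj$frame)
  }
  if (nrow(traj) && any(traj$width_um / pixel_size < 2)) {
    warning("pixel_size too coarse to resolve cell width (< 2 px across)",
            call. = FALSE)
  }
  nr <- ceiling(arena[2] / pixel_size)
  nc <- ceiling(arena[1] / pixel_size)
  set.seed(seed)
  stack <- array(0, dim = c(nr, nc, n_frames))
  sigma_bins <- psf_sigma / pixel_size
  for (f in seq_len(n_frames)) {
    img <- matrix(0, nr, nc)
    rows <- which(traj$frame == f)
    for (i in rows) {
      img <- stamp_capsule(img, pixel_size, traj$x_um[i], traj$y_um[i],
                           traj$orientation_rad[i], traj$length_um[i],
                           traj$width_um[i])
    }
    if (sigma_bins > 0 && length(rows)) img <- gauss_smooth2d(img, sigma_bins)
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    stack[, , f] <- img
  }
  frame_stack(stack, pixel_size, attr(traj, "frame_interval"), seed = seed)
}
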