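#' Configuration for the two-channel colocalization image generator
#'
#' Emulates a pair of co-registered fluorescence channels in which a known
#' fraction of the second channel's objects sit on top of first-channel
#' objects (partially overlapping punctate signals).
#'
#' @param shape image dimensions in px, `c(rows, cols)`.
#' @param n_objects number of disc objects per channel (length 1 or 2).
#' @param object_radius disc radius in px.
#' @param overlap_fraction fraction in `[0, 1]` of channel-2 objects placed
#'   exactly on channel-1 object centers.
#' @param intensity peak object intensity per channel (length 1 or 2).
#' @param noise_sd additive Gaussian background noise SD.
#' @param seed integer RNG seed.
#' @return object of class `coloc_sim_config`.
#' @export
coloc_sim_config <- function(shape = c(256, 256), n_objects = 30,
                             object_radius = 3, overlap_fraction = 0.5,
                             intensity = 1, noise_sd = 0.02, seed = 1) {
  stopifnot(length(shape) == 2)
  check_positive(shape, "shape")
  check_positive(n_objects, "n_objects")
  check_positive(object_radius, "object_radius")
  check_fraction(overlap_fraction, "overlap_fraction")
  check_positive(intensity, "intensity")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  n_objects <- rep(as.integer(n_objects), length.out = 2)
  intensity <- rep(intensity, length.out = 2)
  structure(list(shape = as.integer(shape), n_objects = n_objects,
                 object_radius = object_radius,
                 overlap_fraction = overlap_fraction,
                 intensity = intensity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "coloc_sim_config")
}

disc_mask <- function(shape, centers, radius) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (!nrow(centers)) return(m)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rows <- max(1L, floor(r0 - radius)):min(shape[1], ceiling(r0 + radius))
    cols <- max(1L, floor(c0 - radius)):min(shape[2], ceiling(c0 + radius))
    inside <- outer((rows - r0)^2, (cols - c0)^2, "+") <= radius^2
    m[rows, cols] <- m[rows, cols] | inside
  }
  m
}

#' Generate a synthetic two-channel colocalization image pair
#'
#' Channel-1 discs are placed uniformly at random. A fraction
#' `overlap_fraction` of channel-2 discs is placed on distinct channel-1
#' centers (perfect co-registration); the rest are placed independently.
#' Ground-truth object masks are returned alongside the intensity images.
#'
#' @param config a [coloc_sim_config()].
#' @return list with `pair` (a [channel_pair()]), logical ground-truth
#'   masks `mask_r`, `mask_g`, and the object `centers_r`, `centers_g`
#'   (row, col).
#' @export
generate_coloc_pair <- function(config) {
  stopifnot(inherits(config, "coloc_sim_config"))
  set.seed(config$seed)
  sh <- config$shape; rad <- config$object_radius
  place <- function(n) cbind(runif(n, rad + 1, sh[1] - rad),
                             runif(n, rad + 1, sh[2] - rad))
  centers_r <- place(config$n_objects[1])
  n_overlap <- round(config$overlap_fraction * config$n_objects[2])
  n_overlap <- min(n_overlap, config$n_objects[1])
  on_idx <- if (n_overlap > 0) sample(config$n_objects[1], n_overlap) else integer(0)
  centers_g <- rbind(centers_r[on_idx, , drop = FALSE],
                     place(config$n_objects[2] - n_overlap))
  mask_r <- disc_mask(sh, centers_r, rad)
  mask_g <- disc_mask(sh, centers_g, rad)
  img_r <- mask_r * config$intensity[1] +
    matrix(rnorm(prod(sh), 0, config$noise_sd), sh[1], sh[2])
  img_g <- mask_g * config$intensity[2] +
    matrix(rnorm(prod(sh), 0, config$noise_sd), sh[1], sh[2])
  list(pair = channel_pair(pmax(img_r, 0), pmax(img_g, 0)),
       mask_r = mask_r, mask_g = mask_g,
       centers_r = centers_r, centers_g = centers_g)
}
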