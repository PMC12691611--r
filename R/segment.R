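#' Detection and tracking configuration
#'
#' @param intensity_threshold_mode `"automatic"` (Otsu's criterion on the
#'   frame histogram) or `"fixed"`.
#' @param intensity_threshold threshold used when mode is `"fixed"`.
#' @param min_area smallest accepted component area, um^2.
#' @param max_area largest accepted component area, um^2 (default `Inf`).
#'   Setting it near twice the single-cell area rejects merged blobs of
#'   touching cells, which are then bridged by gap closing instead of
#'   being linked ambiguously.
#' @param max_link_distance largest allowed frame-to-frame centroid
#'   displacement, um.
#' @param morphology_weight weight of the relative area change term in the
#'   linking cost (um of equivalent distance per unit relative area change).
#' @param max_gap_frames number of frames a track may go undetected before it
#'   is terminated.
#' @return object of class `tracking_config`.
#' @export
tracking_config <- function(intensity_threshold_mode = c("automatic", "fixed"),
                            intensity_threshold = NULL,
                            min_area = 1, max_area = Inf,
                            max_link_distance = 6,
                            morphology_weight = 0.5, max_gap_frames = 1) {
  intensity_threshold_mode <- match.arg(intensity_threshold_mode)
  if (intensity_threshold_mode == "fixed" && is.null(intensity_threshold)) {
    stop_field("intensity_threshold", "must be given when mode is \"fixed\"")
  }
  check_positive(min_area, "min_area", strict = FALSE)
  if (max_area <= min_area) stop_field("max_area", "must exceed min_area")
  check_positive(max_link_distance, "max_link_distance")
  check_positive(morphology_weight, "morphology_weight", strict = FALSE)
  if (max_gap_frames < 0) stop_field("max_gap_frames", "must be >= 0")
  structure(list(intensity_threshold_mode = intensity_threshold_mode,
                 intensity_threshold = intensity_threshold,
                 min_area = min_area, max_area = max_area,
                 max_link_distance = max_link_distance,
                 morphology_weight = morphology_weight,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "tracking_config")
}

#' Segment one frame into cell detections
#'
#' Global threshold (Otsu or fixed), connected-component labelling, and
#' per-component second-moment ellipse statistics on the binary mask.
#' Orientation is axial, reported in `[0, pi)`. Deterministic for a fixed
#' input.
#'
#' @param image 2-D numeric intensity matrix (row = y, column = x).
#' @param pixel_size um per pixel.
#' @param config a [tracking_config()].
#' @return data frame of detections: `x_um`, `y_um`, `orientation_rad`,
#'   `major_um`, `minor_um`, `area_um2`, `mean_intensity`. Zero rows for an
#'   empty or flat frame.
#' @export
segment_frame <- function(image, pixel_size, config = tracking_config()) {
  stopifnot(is.matrix(image))
  check_positive(pixel_size, "pixel_size")
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      orientation_rad = numeric(0), major_um = numeric(0),
                      minor_um = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0))
  if (diff(range(image)) == 0) return(empty)
  thr <- if (config$intensity_threshold_mode == "automatic") {
    otsu_threshold(image)
  } else {
    config$intensity_threshold
  }
  mask <- image > thr
  if (!any(mask)) return(empty)
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(image)) + 1L
  cc <- ((idx - 1L) %/% nrow(image)) + 1L
  xs <- (cc - 0.5) * pixel_size
  ys <- (rr - 0.5) * pixel_size
  ints <- image[idx]

  out <- lapply(split(seq_along(lab), lab), function(k) {
    npx <- length(k)
    area <- npx * pixel_size^2
    if (area < config$min_area || area > config$max_area) return(NULL)
    mx <- mean(xs[k]); my <- mean(ys[k])
    # second moments with the pixel-extent (sheet) correction
    vxx <- mean((xs[k] - mx)^2) + pixel_size^2 / 12
    vyy <- mean((ys[k] - my)^2) + pixel_size^2 / 12
    vxy <- if (npx > 1) mean((xs[k] - mx) * (ys[k] - my)) else 0
    tr2 <- (vxx - vyy) / 2
    disc <- sqrt(tr2^2 + vxy^2)
    l1 <- (vxx + vyy) / 2 + disc
    l2 <- (vxx + vyy) / 2 - disc
    theta <- 0.5 * atan2(2 * vxy, vxx - vyy)
    data.frame(x_um = mx, y_um = my,
               orientation_rad = theta %% pi,
               major_um = 4 * sqrt(max(l1, 0)),
               minor_um = 4 * sqrt(max(l2, 0)),
               area_um2 = area, mean_intensity = mean(ints[k]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else {
    rownames(out) <- NULL
    out
  }
}

#' Segment every frame of a stack
#'
#' @param stack a [frame_stack()].
#' @param config a [tracking_config()].
#' @return list of detection data frames, one per frame (see
#'   [segment_frame()]).
#' @export
segment_stack <- function(stack, config = tracking_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$frames)[3]
  lapply(seq_len(n), function(f) {
    segment_frame(stack$frames[, , f], stack$pixel_size, config)
  })
}
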