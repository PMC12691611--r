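BIG_COST <- 1e9

# Globally optimal one-to-one assignment on a cost matrix; entries >=
# BIG_COST/2 are forbidden. Returns integer vector: for each row, the
# assigned column or NA.
solve_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(rep(NA_integer_, nr))
  if (nr <= nc) {
    a <- .solve_lsap_cpp(cost)
    picked <- cost[cbind(seq_len(nr), a)]
    ifelse(picked >= BIG_COST / 2, NA_integer_, a)
  } else {
    a <- .solve_lsap_cpp(t(cost))   # rows = detections
    out <- rep(NA_integer_, nr)
    picked <- cost[cbind(a, seq_len(nc))]
    ok <- picked < BIG_COST / 2
    out[a[ok]] <- seq_len(nc)[ok]
    out
  }
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame globally optimal one-to-one assignment (Hungarian /
#' Jonker-Volgenant) minimizing `centroid distance + morphology_weight *
#' |delta area| / mean area`, with links beyond `max_link_distance`
#' forbidden. Unmatched detections start new tracks; tracks undetected for
#' more than `max_gap_frames` frames are terminated; links that span a gap
#' are flagged.
#'
#' @param detections_by_frame list of detection data frames as returned by
#'   [segment_stack()], one element per consecutive frame starting at 1, or
#'   a single data frame with a `frame` column covering a contiguous frame
#'   range.
#' @param config a [tracking_config()].
#' @param frame_interval s between frames (propagated to the output).
#' @param arena arena width/height in um (needed downstream by coverage);
#'   defaults to the detection bounding box.
#' @return a [trajectory_set()] with provenance `"tracked"`; extra columns
#'   `area_um2` and `gap_flag`.
#' @export
link_tracks <- function(detections_by_frame, config = tracking_config(),
                        frame_interval = 10, arena = NULL) {
  if (is.data.frame(detections_by_frame)) {
    fr <- detections_by_frame$frame
    all_fr <- seq(min(fr), max(fr))
    missing_fr <- setdiff(all_fr, unique(fr))
    if (length(missing_fr)) {
      stop("non-contiguous frame indices; missing frames: ",
           paste(missing_fr, collapse = ", "), call. = FALSE)
    }
    detections_by_frame <- lapply(all_fr, function(f) {
      detections_by_frame[fr == f, setdiff(names(detections_by_frame), "frame"),
                          drop = FALSE]
    })
  }
  F_ <- length(detections_by_frame)
  stopifnot(F_ >= 1)

  rows <- list()
  # active track state
  state <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), last_frame = integer(0))
  next_id <- 1L

  emit <- function(id, f, det, gap) {
    data.frame(cell = id, frame = f, x_um = det$x_um, y_um = det$y_um,
               orientation_rad = det$orientation_rad,
               length_um = det$major_um, width_um = det$minor_um,
               speed_um_min = NA_real_, area_um2 = det$area_um2,
               gap_flag = gap)
  }

  for (f in seq_len(F_)) {
    det <- detections_by_frame[[f]]
    nd <- if (is.null(det)) 0L else nrow(det)
    # drop tracks that have aged out
    state <- state[f - state$last_frame - 1L <= config$max_gap_frames, ,
                   drop = FALSE]
    nt <- nrow(state)
    assigned_det <- rep(FALSE, nd)
    if (nt > 0 && nd > 0) {
      dx <- outer(state$x, det$x_um, "-")
      dy <- outer(state$y, det$y_um, "-")
      dist <- sqrt(dx^2 + dy^2)
      darea <- abs(outer(state$area, det$area_um2, "-")) /
        ((outer(state$area, det$area_um2, "+")) / 2)
      cost <- dist + config$morphology_weight * darea
      cost[dist > config$max_link_distance] <- BIG_COST
      match_col <- solve_assignment(cost)
      for (i in seq_len(nt)) {
        j <- match_col[i]
        if (!is.na(j)) {
          gap <- (f - state$last_frame[i]) > 1L
          rows[[length(rows) + 1L]] <- emit(state$id[i], f, det[j, ], gap)
          state$x[i] <- det$x_um[j]; state$y[i] <- det$y_um[j]
          state$area[i] <- det$area_um2[j]; state$last_frame[i] <- f
          assigned_det[j] <- TRUE
        }
      }
    }
    if (nd > 0) {
      for (j in which(!assigned_det)) {
        id <- next_id; next_id <- next_id + 1L
        rows[[length(rows) + 1L]] <- emit(id, f, det[j, ], FALSE)
        state <- rbind(state, data.frame(id = id, x = det$x_um[j],
                                         y = det$y_um[j],
                                         area = det$area_um2[j],
                                         last_frame = f))
      }
    }
  }

  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), frame = integer(0), x_um = numeric(0),
               y_um = numeric(0), orientation_rad = numeric(0),
               length_um = numeric(0), width_um = numeric(0),
               speed_um_min = numeric(0), area_um2 = numeric(0),
               gap_flag = logical(0))
  if (is.null(arena)) {
    arena <- if (nrow(df)) c(max(df$x_um), max(df$y_um)) else c(1, 1)
  }
  trajectory_set(df, frame_interval = frame_interval, arena = arena,
                 provenance = "tracked")
}

#' Segment and track a whole movie
#'
#' Convenience wrapper: [segment_stack()] followed by [link_tracks()],
#' carrying the stack's pixel size, frame interval and arena through.
#'
#' @param stack a [frame_stack()].
#' @param config a [tracking_config()].
#' @return a [trajectory_set()] with provenance `"tracked"`.
#' @export
track_stack <- function(stack, config = tracking_config()) {
  det <- segment_stack(stack, config)
  d <- dim(stack$frames)
  link_tracks(det, config, frame_interval = stack$frame_interval,
              arena = c(d[2] * stack$pixel_size, d[1] * stack$pixel_size))
}
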