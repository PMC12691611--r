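#' Write and read trajectory CSV files
#'
#' Tracks are stored as plain CSV with one row per cell per frame and a
#' `provenance` column distinguishing ground truth from inferred tracks;
#' imaging metadata travels in a JSON sidecar (`<path>.json`).
#'
#' @param traj a [trajectory_set()].
#' @param path CSV file path.
#' @return `path`, invisibly (writer); a [trajectory_set()] (reader).
#' @export
write_tracks_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  df <- as.data.frame(traj)
  df$provenance <- attr(traj, "provenance")
  write.csv(df, path, row.names = FALSE)
  meta <- list(frame_interval_s = attr(traj, "frame_interval"),
               arena_um = attr(traj, "arena"),
               provenance = attr(traj, "provenance"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    fi <- meta$frame_interval_s
    arena <- meta$arena_um
    prov <- meta$provenance
  } else {
    fi <- 10
    arena <- c(max(df$x_um), max(df$y_um))
    prov <- if ("provenance" %in% names(df)) df$provenance[1] else "tracked"
  }
  df$provenance <- NULL
  if (!"speed_um_min" %in% names(df)) df$speed_um_min <- NA_real_
  trajectory_set(df, frame_interval = fi, arena = arena, provenance = prov)
}

#' Write and read a frame stack as multi-page TIFF with JSON metadata
#'
#' Intensities are min-max normalized to `[0, 1]` for 32-bit float TIFF
#' storage; the affine scale is recorded in the sidecar so reading restores
#' the original values.
#'
#' @param stack a [frame_stack()].
#' @param path TIFF file path; metadata goes to `<path>.json`.
#' @return `path`, invisibly (writer); a [frame_stack()] (reader).
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  lo <- min(stack$frames); hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  n <- dim(stack$frames)[3]
  pages <- lapply(seq_len(n), function(f) (stack$frames[, , f] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval,
               seed = stack$seed, intensity_offset = lo,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) {
    arr[, , f] <- pages[[f]] * meta$intensity_scale + meta$intensity_offset
  }
  frame_stack(arr, meta$pixel_size_um, meta$frame_interval_s,
              seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Write and read SPR equilibrium tables
#'
#' @param data an [spr_dataset()].
#' @param path CSV file path.
#' @return `path`, invisibly (writer); an [spr_dataset()] (reader).
#' @export
write_spr_csv <- function(data, path) {
  stopifnot(inherits(data, "spr_dataset"))
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spr_csv
#' @export
read_spr_csv <- function(path) {
  df <- read.csv(path)
  spr_dataset(df$concentration_M, df$response_RU)
}

#' Write and read ITC titration tables
#'
#' The CSV carries injection heats and, when present, the control series;
#' instrument geometry goes to a JSON sidecar.
#'
#' @param data an [itc_dataset()].
#' @param path CSV file path.
#' @return `path`, invisibly (writer); an [itc_dataset()] (reader).
#' @export
write_itc_csv <- function(data, path) {
  stopifnot(inherits(data, "itc_dataset"))
  df <- as.data.frame(data)
  ctrl <- attr(data, "control")
  if (!is.null(ctrl)) df$control_kcal_mol <- ctrl
  write.csv(df, path, row.names = FALSE)
  meta <- list(cell_volume_ul = attr(data, "cell_volume"),
               injection_volume_ul = attr(data, "injection_volume"),
               cell_conc_M = attr(data, "cell_conc"),
               syringe_conc_M = attr(data, "syringe_conc"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_itc_csv
#' @export
read_itc_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  itc_dataset(df$heat_kcal_mol, meta$cell_volume_ul, meta$injection_volume_ul,
              meta$cell_conc_M, meta$syringe_conc_M,
              control = df$control_kcal_mol)
}
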