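#' Run an analysis pipeline stage from a configuration
#'
#' Orchestrates the package's stages from a single configuration (a named
#' list or the path of a YAML file): movie simulation, tracking, motility
#' quantification, colocalization, and binding-model fitting, or the full
#' simulate-track-quantify chain. Every run writes its resolved
#' configuration (including the seed) and a machine-readable
#' `summary.json` into the output directory, so each artifact is fully
#' reproducible.
#'
#' Recognised `stage` values: `simulate-movie`, `track`,
#' `quantify-motility`, `chain`, `simulate-coloc`, `coloc`, `simulate-spr`,
#' `fit-spr`, `simulate-itc`, `fit-itc`.
#'
#' Configuration layout: `stage`, `outdir`, optional `seed` (overrides any
#' seed in `params`), and `params`, a named list forwarded to the stage's
#' config constructor or naming its input files (`movie`, `tracks`,
#' `spr_csv`, `itc_csv`).
#'
#' @param config named list or path to a YAML file.
#' @return list of in-memory stage results, invisibly; artifacts and
#'   `summary.json` are written to `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$stage)) stop_field("stage", "must be given")
  if (is.null(config$outdir)) stop_field("outdir", "must be given")
  params <- if (is.null(config$params)) list() else config$params
  if (!is.null(config$seed)) params$seed <- config$seed
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(c(config, list(params = params)),
                   file.path(outdir, "run-config.yaml"))

  res <- switch(
    config$stage,
    "simulate-movie" = stage_simulate_movie(params, outdir),
    "track" = stage_track(params, outdir),
    "quantify-motility" = stage_quantify(params, outdir),
    "chain" = stage_chain(params, outdir),
    "simulate-coloc" = stage_simulate_coloc(params, outdir),
    "coloc" = stage_coloc(params, outdir),
    "simulate-spr" = stage_simulate_spr(params, outdir),
    "fit-spr" = stage_fit_spr(params, outdir),
    "simulate-itc" = stage_simulate_itc(params, outdir),
    "fit-itc" = stage_fit_itc(params, outdir),
    stop_field("stage", paste("unknown stage", config$stage))
  )
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

take <- function(params, names_) params[intersect(names(params), names_)]

sim_config_from <- function(params) {
  do.call(motility_sim_config, take(params, names(formals(motility_sim_config))))
}

tracking_config_from <- function(params) {
  do.call(tracking_config, take(params, names(formals(tracking_config))))
}

stage_simulate_movie <- function(params, outdir) {
  cfg <- sim_config_from(params)
  traj <- simulate_trajectories(cfg)
  render_args <- take(params, c("pixel_size", "psf_sigma", "noise_sd"))
  render_args$pixel_size <- if (is.null(render_args$pixel_size)) cfg$pixel_size
    else render_args$pixel_size
  stack <- do.call(render_frames, c(list(traj = traj, seed = cfg$seed),
                                    render_args))
  write_tracks_csv(traj, file.path(outdir, "ground-truth.csv"))
  write_frame_stack(stack, file.path(outdir, "movie.tif"))
  list(traj = traj, stack = stack,
       summary = list(stage = "simulate-movie", seed = cfg$seed,
                      n_cells = cfg$n_cells,
                      n_frames = dim(stack$frames)[3]))
}

stage_track <- function(params, outdir, stack = NULL) {
  if (is.null(stack)) stack <- read_frame_stack(params$movie)
  tracks <- track_stack(stack, tracking_config_from(params))
  write_tracks_csv(tracks, file.path(outdir, "tracks.csv"))
  list(tracks = tracks,
       summary = list(stage = "track",
                      n_tracks = length(unique(tracks$cell)),
                      n_detections = nrow(tracks)))
}

stage_quantify <- function(params, outdir, tracks = NULL) {
  if (is.null(tracks)) tracks <- read_tracks_csv(params$tracks)
  vel <- instantaneous_velocities(tracks)
  cov <- cumulative_coverage(tracks,
                             grid_pixel_size = if (is.null(params$grid_pixel_size))
                               0.5 else params$grid_pixel_size)
  hm <- density_heatmap(tracks,
                        bin_size = if (is.null(params$bin_size)) 2 else params$bin_size,
                        sigma = if (is.null(params$sigma)) 2 else params$sigma,
                        arena = attr(tracks, "arena"))
  write.csv(hm$map, file.path(outdir, "density-heatmap.csv"), row.names = FALSE)
  tiff::writeTIFF(matrix(as.numeric(cov$raster), nrow(cov$raster)),
                  file.path(outdir, "coverage.tif"))
  summary <- list(stage = "quantify-motility",
                  mean_speed_um_min = vel$mean, sd_speed_um_min = vel$sd,
                  n_steps = vel$n_steps,
                  coverage_fraction = cov$coverage_fraction)
  list(velocities = vel, coverage = cov, heatmap = hm, summary = summary)
}

stage_chain <- function(params, outdir) {
  sim <- stage_simulate_movie(params, outdir)
  trk <- stage_track(params, outdir, stack = sim$stack)
  qnt <- stage_quantify(params, outdir, tracks = trk$tracks)
  summary <- c(list(stage = "chain", seed = sim$summary$seed),
               trk$summary["n_tracks"], qnt$summary[-1])
  list(sim = sim, tracks = trk$tracks, quantify = qnt, summary = summary)
}

stage_simulate_coloc <- function(params, outdir) {
  cfg <- do.call(coloc_sim_config, take(params, names(formals(coloc_sim_config))))
  gen <- generate_coloc_pair(cfg)
  tiff::writeTIFF(gen$pair$channel_r / max(gen$pair$channel_r, 1),
                  file.path(outdir, "channel-r.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(gen$pair$channel_g / max(gen$pair$channel_g, 1),
                  file.path(outdir, "channel-g.tif"), bits.per.sample = 32L)
  list(gen = gen, summary = list(stage = "simulate-coloc", seed = cfg$seed,
                                 overlap_fraction = cfg$overlap_fraction))
}

stage_coloc <- function(params, outdir, pair = NULL) {
  if (is.null(pair)) {
    r <- tiff::readTIFF(params$channel_r)
    g <- tiff::readTIFF(params$channel_g)
    pair <- channel_pair(r, g)
  }
  st <- coloc_stats(pair)
  list(stats = st,
       summary = list(stage = "coloc", M1 = st$M1, M2 = st$M2,
                      PCC = st$PCC, ICQ = st$ICQ, n_pixels = st$n_pixels))
}

stage_simulate_spr <- function(params, outdir) {
  cfg <- do.call(spr_sim_config, take(params, names(formals(spr_sim_config))))
  data <- generate_spr_dataset(cfg)
  write_spr_csv(data, file.path(outdir, "spr.csv"))
  list(data = data, summary = list(stage = "simulate-spr", seed = cfg$seed,
                                   K_D = cfg$K_D, Rmax = cfg$Rmax))
}

stage_fit_spr <- function(params, outdir, data = NULL) {
  if (is.null(data)) data <- read_spr_csv(params$spr_csv)
  fit <- fit_spr_steady_state(data)
  list(fit = fit,
       summary = list(stage = "fit-spr", K_D = fit$K_D, Rmax = fit$Rmax,
                      rss = fit$rss, reliable = fit$reliable))
}

stage_simulate_itc <- function(params, outdir) {
  cfg <- do.call(itc_sim_config, take(params, names(formals(itc_sim_config))))
  data <- generate_itc_dataset(cfg)
  write_itc_csv(data, file.path(outdir, "itc.csv"))
  list(data = data, summary = list(stage = "simulate-itc", seed = cfg$seed,
                                   n = cfg$n, K_D = cfg$K_D, dH = cfg$dH))
}

stage_fit_itc <- function(params, outdir, data = NULL) {
  if (is.null(data)) data <- read_itc_csv(params$itc_csv)
  if (!is.null(attr(data, "control"))) data <- subtract_dilution(data)
  fit <- fit_itc_one_site(data)
  list(fit = fit,
       summary = list(stage = "fit-itc", n = fit$n, K_D = fit$K_D,
                      dH = fit$dH, rss = fit$rss,
                      low_confidence = fit$low_confidence))
}
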