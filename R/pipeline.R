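#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end synthetic pipeline
#' (simulate -> render -> track -> qc -> segment -> stats -> spread) with
#' defaults equal to the measured-data processing constants: 20 fps; bulk
#' QC thresholds 10 um/s, 5 um, 2 s; agar QC thresholds 1.5 s, 1 um;
#' segmentation threshold 7 um/s with 2 um trap merging.
#'
#' @param strain Strain label or \code{\link{strain_profile}}.
#' @param env Environment label or \code{\link{environment_profile}}.
#' @param n Number of simulated cells.
#' @param duration Simulated time per cell, s.
#' @param fps Frame rate (1/dt), Hz.
#' @param seed Master seed; all stage seeds derive from it.
#' @param sigma_loc Localisation noise of the rendered detections, um.
#' @param p_detect Per-frame detection probability.
#' @param fp_per_frame Expected false positives per rendered frame.
#' @param batch_size Cells per rendered recording (movies are rendered and
#'   linked in independent batches, like separate fields of view).
#' @param spacing_um Grid spacing between cells within a batch, um.
#' @param link A \code{\link{link_config}}.
#' @param seg A \code{\link{segmentation_params}}.
#' @param qc A \code{\link{qc_rules}}; defaults to the dialect matching the
#'   environment kind.
#' @param spread_duration Spreading observation time, h.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(strain = "WT", env = "bulk", n = 100,
                            duration = 10, fps = 20, seed = 1,
                            sigma_loc = 0.05, p_detect = 0.98,
                            fp_per_frame = 0.2, batch_size = 10,
                            spacing_um = 150,
                            link = link_config(fps = fps),
                            seg = segmentation_params(),
                            qc = NULL, spread_duration = 24) {
  if (is.character(strain)) strain <- strain_profile(strain)
  if (is.character(env)) env <- environment_profile(env)
  if (is.null(qc))
    qc <- qc_rules(if (env$kind == "agar") "agar" else "bulk")
  structure(list(strain = strain, env = env, n = n, duration = duration,
                 fps = fps, dt = 1 / fps, seed = as.integer(seed),
                 sigma_loc = sigma_loc, p_detect = p_detect,
                 fp_per_frame = fp_per_frame, batch_size = batch_size,
                 spacing_um = spacing_um, link = link, seg = seg, qc = qc,
                 spread_duration = spread_duration),
            class = "pipeline_config")
}

# lay out `k` cells on a square grid with the given spacing, centred at 0
.grid_offsets <- function(k, spacing) {
  side <- ceiling(sqrt(k))
  ix <- (seq_len(k) - 1) %% side
  iy <- (seq_len(k) - 1) %/% side
  cbind((ix - (side - 1) / 2) * spacing,
        (iy - (side - 1) / 2) * spacing)
}

#' Run the synthetic analysis pipeline
#'
#' Executes simulate -> render -> track -> qc -> segment -> stats (and a
#' spreading simulation + fit) for one strain/environment configuration.
#' Cells are rendered and linked in independent batches emulating separate
#' recordings. When \code{out_dir} is given, every stage output is written
#' as CSV together with a resolved-configuration manifest (YAML) and a
#' plain-text log of record counts per stage.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param out_dir Output directory, or NULL to keep results in memory.
#' @param stages Character vector of stages to run (later stages require
#'   earlier ones; an informative error names any missing prerequisite).
#' @return List with (depending on stages) \code{truth},
#'   \code{detections}, \code{tracks}, \code{qc}, \code{phases},
#'   \code{episodes}, \code{speed_whole}, \code{speed_runs}, \code{msd},
#'   \code{spreading}, \code{spreading_fit}, \code{log}.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("simulate", "track", "qc", "segment",
                                    "stats", "spread")) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  logline <- character(0)
  note <- function(...) logline <<- c(logline, sprintf(...))
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      stop("stage '", stage, "' needs output of an earlier stage ('",
           what, "'); include it in `stages`")
  }
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)

  if ("simulate" %in% stages) {
    pop <- simulate_population(config$n, config$strain, config$env,
                               config$duration, config$dt,
                               seed = stage_seeds[1])
    res$population <- pop
    res$truth <- as.data.frame(pop)
    note("simulate: %d paths x %d frames", config$n,
         length(pop[[1]]$times))

    # render per batch with grid offsets
    nb <- ceiling(config$n / config$batch_size)
    set.seed(stage_seeds[2])
    batch_seeds <- sample.int(.Machine$integer.max - 1L, max(nb, 1))
    det_list <- vector("list", nb)
    res$batches <- vector("list", nb)
    for (b in seq_len(nb)) {
      idx <- ((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                   config$n)
      paths <- unclass(pop)[idx]
      off <- .grid_offsets(length(idx), config$spacing_um)
      reach <- max(vapply(paths, function(p)
        max(abs(c(p$x, p$y))), numeric(1))) + config$spacing_um
      fov <- c(-1, 1, -1, 1) * (max(abs(off)) + reach)
      det <- render_detections(paths, sigma_loc = config$sigma_loc,
                               p_detect = config$p_detect,
                               fp_per_frame = config$fp_per_frame,
                               fov = fov, seed = batch_seeds[b],
                               offsets = off)
      det$batch <- b
      det_list[[b]] <- det
      res$batches[[b]] <- list(idx = idx, offsets = off)
    }
    res$detections <- do.call(rbind, det_list)
    note("render: %d detections in %d batches", nrow(res$detections), nb)
  }

  if ("track" %in% stages) {
    need("detections", "track")
    tr_list <- list()
    id_offset <- 0L
    for (b in sort(unique(res$detections$batch))) {
      det <- res$detections[res$detections$batch == b,
                            c("frame", "x_um", "y_um")]
      det <- det[order(det$frame), ]
      tr <- link_detections(det, config$link)
      tr$track_id <- tr$track_id + id_offset
      id_offset <- id_offset + length(unique(tr$track_id))
      tr_list[[length(tr_list) + 1]] <- tr
    }
    res$tracks <- do.call(rbind, tr_list)
    note("track: %d tracks from %d detections",
         length(unique(res$tracks$track_id)), nrow(res$detections))
  }

  if ("qc" %in% stages) {
    need("tracks", "qc")
    fl <- filter_trajectories(res$tracks, config$qc)
    res$qc <- fl
    n_in <- length(unique(res$tracks$track_id))
    n_kept <- length(unique(fl$kept$track_id))
    note("qc (%s): %d in = %d kept + %d removed", config$qc$dialect,
         n_in, n_kept, nrow(fl$removed))
    stopifnot(n_in == n_kept + nrow(fl$removed))
  }

  if ("segment" %in% stages) {
    need("qc", "segment")
    kept <- res$qc$kept
    ph_list <- list()
    ep_list <- list()
    for (tr in split(kept, kept$track_id)) {
      if (nrow(tr) <= config$seg$window) next
      lab <- segment_runs(tr, config$seg)
      ph_list[[length(ph_list) + 1]] <-
        data.frame(track_id = tr$track_id[1], frame = tr$frame,
                   phase = lab$phase)
      rs <- run_episode_stats(lab, tr)
      if (rs$n_runs > 0)
        ep_list[[length(ep_list) + 1]] <-
          cbind(track_id = tr$track_id[1], rs$episodes)
    }
    res$phases <- if (length(ph_list)) do.call(rbind, ph_list) else NULL
    res$episodes <- if (length(ep_list)) do.call(rbind, ep_list) else NULL
    note("segment: %d run episodes on %d tracks",
         if (is.null(res$episodes)) 0L else nrow(res$episodes),
         length(ph_list))
  }

  if ("stats" %in% stages) {
    need("qc", "stats")
    kept <- res$qc$kept
    if (nrow(kept) > 0) {
      res$speed_whole <- population_speed(kept, "whole", config$seg)
      res$speed_runs <- tryCatch(
        population_speed(kept, "runs", config$seg), error = function(e) NULL)
      res$msd <- compute_msd(kept, max_lag = min(2, config$duration / 2))
      note("stats: whole %.2f um/s (n=%d)%s", res$speed_whole$mean_um_s,
           res$speed_whole$n,
           if (!is.null(res$speed_runs))
             sprintf("; runs %.2f um/s (n=%d)",
                     res$speed_runs$mean_um_s, res$speed_runs$n) else "")
    } else note("stats: skipped, no tracks kept")
  }

  if ("spread" %in% stages) {
    sp <- simulate_spreading(config$strain, config$env,
                             config$spread_duration,
                             seed = stage_seeds[4])
    res$spreading <- sp
    res$spreading_fit <- fit_spreading(sp)
    note("spread: slope %.3f mm/h over %g h",
         res$spreading_fit$slope_mm_h, config$spread_duration)
  }

  res$log <- logline
  if (!is.null(out_dir)) .write_pipeline_outputs(res, config, out_dir)
  invisible(res)
}

.write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) {
    if (!is.null(x) && is.data.frame(x))
      utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(res$truth, "truth.csv")
  wcsv(res$detections, "detections.csv")
  wcsv(res$tracks, "tracks.csv")
  if (!is.null(res$qc)) {
    wcsv(res$qc$kept, "qc_kept.csv")
    wcsv(res$qc$removed, "qc_removed.csv")
  }
  wcsv(res$phases, "phases.csv")
  wcsv(res$episodes, "episodes.csv")
  if (!is.null(res$speed_whole)) {
    sw <- res$speed_whole
    sr <- res$speed_runs
    tab <- data.frame(
      strain = config$strain$name, env = config$env$name,
      dialect = c("whole", if (!is.null(sr)) "runs"),
      mean_um_s = c(sw$mean_um_s, if (!is.null(sr)) sr$mean_um_s),
      sem_um_s = c(sw$sem_um_s, if (!is.null(sr)) sr$sem_um_s),
      n = c(sw$n, if (!is.null(sr)) sr$n))
    utils::write.csv(tab, file.path(out_dir, "speed_summary.csv"),
                     row.names = FALSE)
  }
  wcsv(res$msd, "msd.csv")
  wcsv(res$spreading, "spreading.csv")
  if (!is.null(res$spreading_fit)) {
    f <- res$spreading_fit
    utils::write.csv(data.frame(strain = config$strain$name,
                                slope_mm_h = f$slope_mm_h,
                                intercept_mm = f$intercept_mm,
                                lag_h = f$lag_h,
                                residual_rms = f$residual_rms),
                     file.path(out_dir, "spreading_fit.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = config$seed, fps = config$fps, n = config$n,
    duration_s = config$duration,
    strain = config$strain$name, env = config$env$name,
    sigma_loc_um = config$sigma_loc, p_detect = config$p_detect,
    fp_per_frame = config$fp_per_frame,
    link = list(max_disp_um = config$link$max_disp,
                memory_frames = config$link$memory),
    qc = list(dialect = config$qc$dialect,
              min_mean_speed_um_s = config$qc$min_mean_speed,
              min_displacement_um = config$qc$min_displacement,
              min_duration_s = config$qc$min_duration,
              min_straightness = config$qc$min_straightness),
    segmentation = list(
      speed_threshold_um_s = config$seg$speed_threshold,
      merge_distance_um = config$seg$merge_distance,
      window_frames = config$seg$window))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  writeLines(res$log, file.path(out_dir, "log.txt"))
  invisible(NULL)
}
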