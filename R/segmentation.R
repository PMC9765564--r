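#' Run/trap segmentation parameters
#'
#' @param speed_threshold um/s; timepoints slower than this are not runs
#'   (default 7).
#' @param merge_distance um; two successive traps closer than this (end
#'   point of the first to start point of the second) merge into one trap,
#'   absorbing the timepoints between them (default 2).
#' @param window Finite-difference half-window of the speed estimator, in
#'   frames (default 1).
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(speed_threshold = 7, merge_distance = 2,
                                window = 1) {
  if (speed_threshold <= 0 || merge_distance <= 0)
    stop("speed_threshold and merge_distance must be positive")
  if (window < 1) stop("window must be >= 1 frame")
  structure(list(speed_threshold = speed_threshold,
                 merge_distance = merge_distance,
                 window = as.integer(window)),
            class = "segmentation_params")
}

#' Instantaneous speed along a trajectory
#'
#' Central finite difference over \code{window} frames on either side;
#' boundary points fall back to a one-sided difference (window clamped to
#' the trajectory). The result has one value per timepoint.
#'
#' @param traj data.frame with columns \code{t_s}, \code{x_um},
#'   \code{y_um}; at least 2 points.
#' @param window Half-window in frames, >= 1.
#' @return Numeric vector of speeds, um/s.
#' @export
instantaneous_speed <- function(traj, window = 1) {
  n <- nrow(traj)
  if (n < 2) stop("instantaneous speed needs at least 2 points")
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  lo <- pmax(seq_len(n) - window, 1L)
  hi <- pmin(seq_len(n) + window, n)
  d <- sqrt((traj$x_um[hi] - traj$x_um[lo])^2 +
            (traj$y_um[hi] - traj$y_um[lo])^2)
  d / (traj$t_s[hi] - traj$t_s[lo])
}

# contiguous episodes of a run/trap label vector
.label_episodes <- function(phase, traj) {
  r <- rle(phase)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(episode = seq_along(r$values), kind = r$values,
             start = start, end = end,
             x_start = traj$x_um[start], y_start = traj$y_um[start],
             x_end = traj$x_um[end], y_end = traj$y_um[end],
             stringsAsFactors = FALSE)
}

#' Segment a trajectory into run and trap phases
#'
#' Two-condition segmentation. Pass 1: every timepoint whose instantaneous
#' speed is below \code{speed_threshold} is labelled a trap. Pass 2: for
#' each pair of successive traps, if the spatial start point of the later
#' trap lies within \code{merge_distance} of the spatial end point of the
#' earlier trap, all timepoints between them are relabelled trap (the traps
#' merge). Pass 2 is iterated to a fixed point, so the result does not
#' depend on merge order. Remaining timepoints are runs.
#'
#' @param traj Single-trajectory data.frame (\code{t_s}, \code{x_um},
#'   \code{y_um}); longer than the speed window.
#' @param params A \code{\link{segmentation_params}}.
#' @return Object of class \code{phase_labeling}: list with \code{phase}
#'   (per-timepoint \code{"run"}/\code{"trap"}), \code{episodes}
#'   (data.frame with kind, index range and spatial end points), and the
#'   \code{params} used.
#' @export
segment_runs <- function(traj, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  n <- nrow(traj)
  if (n <= params$window)
    stop("trajectory shorter than the speed window")
  v <- instantaneous_speed(traj, params$window)
  phase <- ifelse(v < params$speed_threshold, "trap", "run")

  repeat {
    ep <- .label_episodes(phase, traj)
    traps <- ep[ep$kind == "trap", ]
    changed <- FALSE
    if (nrow(traps) >= 2) {
      for (i in seq_len(nrow(traps) - 1)) {
        gap_d <- sqrt((traps$x_start[i + 1] - traps$x_end[i])^2 +
                      (traps$y_start[i + 1] - traps$y_end[i])^2)
        if (gap_d < params$merge_distance) {
          idx <- (traps$end[i] + 1L):(traps$start[i + 1] - 1L)
          if (any(phase[idx] == "run")) {
            phase[idx] <- "trap"
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }

  structure(list(phase = phase,
                 episodes = .label_episodes(phase, traj),
                 params = params),
            class = "phase_labeling")
}

#' @export
print.phase_labeling <- function(x, ...) {
  cat(sprintf("<phase_labeling> %d timepoints: %.0f%% run, %d episodes\n",
              length(x$phase), 100 * mean(x$phase == "run"),
              nrow(x$episodes)))
  invisible(x)
}

#' Per-run-episode statistics
#'
#' Mean speed, duration and net displacement of every run episode, plus the
#' pooled mean and SEM across episodes. The episode mean speed is the path
#' length over the episode's internal steps divided by the episode
#' duration; steps that cross a run/trap boundary are outside the episode's
#' index range by construction, so trap dwells do not dilute run speeds.
#' Single-timepoint episodes fall back to the finite-difference speed at
#' that point.
#'
#' @param labeling A \code{\link{segment_runs}} result.
#' @param traj The trajectory it was computed from.
#' @return List with \code{episodes} (data.frame \code{episode},
#'   \code{start}, \code{end}, \code{mean_speed_um_s}, \code{duration_s},
#'   \code{displacement_um}), \code{mean_speed_um_s}, \code{sem_um_s},
#'   \code{n_runs}. Zero run episodes give an empty table, not an error.
#' @export
run_episode_stats <- function(labeling, traj) {
  stopifnot(inherits(labeling, "phase_labeling"))
  n <- nrow(traj)
  if (length(labeling$phase) != n)
    stop("labeling does not match trajectory length")
  w <- labeling$params$window
  v <- instantaneous_speed(traj, w)
  runs <- labeling$episodes[labeling$episodes$kind == "run", ]
  if (nrow(runs) == 0) {
    return(list(episodes = data.frame(episode = integer(0),
                                      start = integer(0), end = integer(0),
                                      mean_speed_um_s = numeric(0),
                                      duration_s = numeric(0),
                                      displacement_um = numeric(0)),
                mean_speed_um_s = NA_real_, sem_um_s = NA_real_,
                n_runs = 0L))
  }
  stats_one <- function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    dur <- traj$t_s[e] - traj$t_s[s]
    speed <- if (e > s) {
      sum(sqrt(diff(traj$x_um[s:e])^2 + diff(traj$y_um[s:e])^2)) / dur
    } else v[s]
    c(mean_speed = speed,
      duration = dur,
      displacement = sqrt((traj$x_um[e] - traj$x_um[s])^2 +
                          (traj$y_um[e] - traj$y_um[s])^2))
  }
  m <- t(vapply(seq_len(nrow(runs)), stats_one, numeric(3)))
  ep <- data.frame(episode = runs$episode, start = runs$start,
                   end = runs$end, mean_speed_um_s = m[, 1],
                   duration_s = m[, 2], displacement_um = m[, 3])
  k <- nrow(ep)
  list(episodes = ep,
       mean_speed_um_s = mean(ep$mean_speed_um_s),
       sem_um_s = if (k > 1) stats::sd(ep$mean_speed_um_s) / sqrt(k)
                  else NA_real_,
       n_runs = k)
}
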