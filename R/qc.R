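#' Trajectory quality-control rule sets
#'
#' Two filter dialects are used depending on the environment. In bulk
#' fluid, trajectories are removed when the mean speed is below 10 um/s,
#' the net displacement below 5 um, the duration below 2 s, or the
#' trajectory is highly curved (straightness below 0.5). In agar, where
#' speeds are lower and paths are tortuous by construction, only very short
#' (< 1.5 s) and very low-displacement (< 1 um) trajectories are removed.
#'
#' @param dialect \code{"bulk"} or \code{"agar"}.
#' @param min_mean_speed um/s, or NA to disable.
#' @param min_displacement Net end-to-end displacement, um.
#' @param min_duration s.
#' @param min_straightness Dimensionless in [0, 1], or NA to disable.
#' @return An object of class \code{qc_rules}.
#' @export
qc_rules <- function(dialect = c("bulk", "agar"),
                     min_mean_speed = NULL, min_displacement = NULL,
                     min_duration = NULL, min_straightness = NULL) {
  dialect <- match.arg(dialect)
  def <- if (dialect == "bulk") {
    list(min_mean_speed = 10, min_displacement = 5, min_duration = 2,
         min_straightness = 0.5)
  } else {
    list(min_mean_speed = NA_real_, min_displacement = 1,
         min_duration = 1.5, min_straightness = NA_real_)
  }
  r <- list(
    dialect = dialect,
    min_mean_speed = if (is.null(min_mean_speed)) def$min_mean_speed
                     else min_mean_speed,
    min_displacement = if (is.null(min_displacement)) def$min_displacement
                       else min_displacement,
    min_duration = if (is.null(min_duration)) def$min_duration
                   else min_duration,
    min_straightness = if (is.null(min_straightness)) def$min_straightness
                       else min_straightness)
  thr <- unlist(r[-1])
  if (any(thr[!is.na(thr)] < 0)) stop("thresholds must be >= 0")
  structure(r, class = "qc_rules")
}

#' Straightness of a trajectory
#'
#' Net end-to-end displacement divided by summed path length: 1 for a
#' straight constant-direction path, 0 for a closed loop.
#'
#' @param traj data.frame with columns \code{x_um}, \code{y_um} (single
#'   trajectory, time-ordered), at least 2 points.
#' @return Value in [0, 1]; 1 when the total path length is zero.
#' @export
straightness <- function(traj) {
  n <- nrow(traj)
  if (n < 2) stop("straightness needs at least 2 points")
  net <- sqrt((traj$x_um[n] - traj$x_um[1])^2 +
              (traj$y_um[n] - traj$y_um[1])^2)
  path <- sum(sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2))
  if (path == 0) return(1)
  min(1, net / path)
}

# per-trajectory summary used by the QC rules
.traj_qc_stats <- function(traj) {
  n <- nrow(traj)
  dur <- traj$t_s[n] - traj$t_s[1]
  path <- sum(sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2))
  list(
    duration = dur,
    displacement = sqrt((traj$x_um[n] - traj$x_um[1])^2 +
                        (traj$y_um[n] - traj$y_um[1])^2),
    mean_speed = if (dur > 0) path / dur else 0,
    straightness = if (n >= 2) straightness(traj) else NA_real_)
}

#' Filter trajectories by a QC rule set
#'
#' A trajectory is removed iff it violates any active rule (OR semantics);
#' each removal is tagged with the first violated rule, checked in the
#' order mean speed, displacement, duration, straightness.
#'
#' @param tracks data.frame with columns \code{track_id}, \code{frame},
#'   \code{t_s}, \code{x_um}, \code{y_um}.
#' @param rules A \code{\link{qc_rules}}.
#' @return List with \code{kept} (subset of \code{tracks}, unmodified rows)
#'   and \code{removed} (data.frame \code{track_id}, \code{reason}).
#' @export
filter_trajectories <- function(tracks, rules = qc_rules("bulk")) {
  stopifnot(inherits(rules, "qc_rules"))
  ids <- unique(tracks$track_id)
  reasons <- character(0)
  bad_ids <- c()
  for (id in ids) {
    traj <- tracks[tracks$track_id == id, ]
    s <- .traj_qc_stats(traj)
    reason <- NA_character_
    if (!is.na(rules$min_mean_speed) && s$mean_speed < rules$min_mean_speed)
      reason <- "mean_speed"
    else if (!is.na(rules$min_displacement) &&
             s$displacement < rules$min_displacement)
      reason <- "displacement"
    else if (!is.na(rules$min_duration) && s$duration < rules$min_duration)
      reason <- "duration"
    else if (!is.na(rules$min_straightness) && !is.na(s$straightness) &&
             s$straightness < rules$min_straightness)
      reason <- "straightness"
    if (!is.na(reason)) {
      bad_ids <- c(bad_ids, id)
      reasons <- c(reasons, reason)
    }
  }
  list(
    kept = tracks[!tracks$track_id %in% bad_ids, , drop = FALSE],
    removed = data.frame(track_id = if (length(bad_ids)) bad_ids
                         else integer(0),
                         reason = reasons, stringsAsFactors = FALSE))
}
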