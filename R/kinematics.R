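#' Population speed summary
#'
#' Per-trajectory mean speeds and their population mean and SEM, in one of
#' two dialects. \code{"whole"} takes each trajectory's path length over
#' its elapsed time (runs and turns included) and summarises over
#' trajectories with an unweighted mean. \code{"runs"} first segments every
#' trajectory into run and trap phases (\code{\link{segment_runs}}) and
#' pools per-episode path-over-time speeds; slow phases are excluded. Both
#' dialects use the same path-over-time estimator, so they agree exactly on
#' a trajectory that is 100\% run.
#'
#' @param tracks data.frame with columns \code{track_id}, \code{t_s},
#'   \code{x_um}, \code{y_um}; nonempty.
#' @param dialect \code{"whole"} or \code{"runs"}.
#' @param params \code{\link{segmentation_params}} (speed window for both
#'   dialects; thresholds for \code{"runs"}).
#' @param weighting \code{"per_trajectory"} (default: unweighted mean over
#'   units) or \code{"per_point"} (units weighted by their number of
#'   timepoints).
#' @return Object of class \code{speed_summary}. For both dialects
#'   \code{mean_um_s} and \code{sem_um_s} are the unweighted mean and SEM
#'   over trajectories (NA SEM for a single trajectory) and \code{per_unit}
#'   holds the per-unit mean speeds. For \code{"whole"} the unit is the
#'   trajectory (\code{n} trajectories). For \code{"runs"} the unit is the
#'   run episode (\code{n} episodes, \code{episode_mean_um_s} /
#'   \code{episode_sem_um_s} summarise them) while \code{per_traj} and
#'   \code{n_traj} carry the per-trajectory pooled run speeds behind
#'   \code{mean_um_s}; trajectory-level summaries are used because episodes
#'   within one trajectory are correlated.
#' @export
population_speed <- function(tracks, dialect = c("whole", "runs"),
                             params = segmentation_params(),
                             weighting = c("per_trajectory", "per_point")) {
  dialect <- match.arg(dialect)
  weighting <- match.arg(weighting)
  if (nrow(tracks) == 0) stop("no trajectories")
  trajs <- split(tracks, tracks$track_id)

  if (dialect == "whole") {
    per_unit <- vapply(trajs, function(tr) {
      dur <- tr$t_s[nrow(tr)] - tr$t_s[1]
      if (dur <= 0) return(0)
      sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)) / dur
    }, numeric(1))
    wts <- if (weighting == "per_point")
      vapply(trajs, nrow, numeric(1)) else rep(1, length(per_unit))
    n <- length(per_unit)
    mu <- stats::weighted.mean(per_unit, wts)
    out <- list(per_unit = per_unit, mean_um_s = mu,
                sem_um_s = if (n > 1) stats::sd(per_unit) / sqrt(n)
                           else NA_real_,
                n = n, dialect = dialect)
  } else {
    ep_means <- list()
    traj_means <- numeric(0)
    for (tr in trajs) {
      lab <- segment_runs(tr, params)
      rs <- run_episode_stats(lab, tr)
      if (rs$n_runs > 0) {
        ep_means[[length(ep_means) + 1]] <- rs$episodes$mean_speed_um_s
        # per-trajectory pooled run speed: run path length / run time
        ok <- rs$episodes$duration_s > 0
        traj_means <- c(traj_means, if (any(ok))
          sum(rs$episodes$mean_speed_um_s[ok] * rs$episodes$duration_s[ok]) /
            sum(rs$episodes$duration_s[ok])
          else rs$mean_speed_um_s)
      }
    }
    per_unit <- unlist(ep_means)
    if (is.null(per_unit)) per_unit <- numeric(0)
    if (length(per_unit) == 0) stop("no run episodes in any trajectory")
    nt <- length(traj_means)
    out <- list(per_unit = per_unit,
                mean_um_s = mean(traj_means),
                sem_um_s = if (nt > 1) stats::sd(traj_means) / sqrt(nt)
                           else NA_real_,
                n = length(per_unit), dialect = dialect,
                per_traj = traj_means, n_traj = nt,
                episode_mean_um_s = mean(per_unit),
                episode_sem_um_s = if (length(per_unit) > 1)
                  stats::sd(per_unit) / sqrt(length(per_unit)) else NA_real_)
  }
  structure(out, class = "speed_summary")
}

#' @export
print.speed_summary <- function(x, ...) {
  sem <- if (is.na(x$sem_um_s)) "NA" else sprintf("%.2f", x$sem_um_s)
  cat(sprintf("<speed_summary> %s: %.2f +/- %s um/s (n = %d)\n",
              x$dialect, x$mean_um_s, sem, x$n))
  invisible(x)
}

#' Ensemble mean square displacement
#'
#' Time-averaged MSD per trajectory over all overlapping lag windows, then
#' ensemble-averaged across trajectories with per-lag pair counts as
#' weights. Trajectories must share a uniform frame interval.
#'
#' @param tracks Trajectory data.frame (\code{track_id}, \code{t_s},
#'   \code{x_um}, \code{y_um}).
#' @param max_lag Largest lag, s; at least one frame interval.
#' @return data.frame of class \code{msd_curve}: \code{lag_s},
#'   \code{msd_um2}, \code{n_pairs}; includes lag 0 with MSD 0.
#' @export
compute_msd <- function(tracks, max_lag) {
  if (nrow(tracks) == 0) stop("no trajectories")
  trajs <- split(tracks, tracks$track_id)
  dts <- unlist(lapply(trajs, function(tr) diff(tr$t_s)))
  dt <- min(dts)
  if (dt <= 0) stop("time must be strictly increasing")
  steps <- dts / dt
  if (any(abs(steps - round(steps)) > 1e-6))
    stop("frame interval must be uniform within and across trajectories")
  if (max_lag < dt) stop("max_lag is below one frame interval")
  L <- floor(max_lag / dt + 1e-9)
  sums <- numeric(L)
  counts <- numeric(L)
  for (tr in trajs) {
    f <- round(tr$t_s / dt)
    f <- f - f[1] + 1
    m <- f[length(f)]
    x <- rep(NA_real_, m)
    y <- rep(NA_real_, m)
    x[f] <- tr$x_um
    y[f] <- tr$y_um
    for (l in seq_len(min(L, m - 1))) {
      dx <- x[(1 + l):m] - x[1:(m - l)]
      dy <- y[(1 + l):m] - y[1:(m - l)]
      ok <- !is.na(dx)
      sums[l] <- sums[l] + sum(dx[ok]^2 + dy[ok]^2)
      counts[l] <- counts[l] + sum(ok)
    }
  }
  keep <- counts > 0
  structure(data.frame(lag_s = c(0, dt * seq_len(L)[keep]),
                       msd_um2 = c(0, sums[keep] / counts[keep]),
                       n_pairs = c(sum(vapply(trajs, nrow, numeric(1))),
                                   counts[keep])),
            class = c("msd_curve", "data.frame"))
}

#' Diffusivity from an MSD curve
#'
#' Least-squares slope of MSD against lag over a fit window, divided by 4
#' (two dimensions). A log-log slope above 1.5 over the window flags the
#' curve as superdiffusive (ballistic-like) and a warning is issued, since
#' a diffusivity is then not meaningful.
#'
#' @param msd A \code{\link{compute_msd}} result.
#' @param fit_range Length-2 numeric: lag window (s) used for the fit.
#' @return List: \code{D_um2_s}, \code{loglog_slope},
#'   \code{superdiffusive} (logical).
#' @export
estimate_diffusivity <- function(msd, fit_range = range(msd$lag_s)) {
  sel <- msd$lag_s >= fit_range[1] & msd$lag_s <= fit_range[2]
  lag <- msd$lag_s[sel]
  val <- msd$msd_um2[sel]
  if (sum(sel) < 2) stop("fewer than 2 lags in the fit window")
  slope <- unname(stats::coef(stats::lm(val ~ lag))[2])
  pos <- lag > 0 & val > 0
  ll <- if (sum(pos) >= 2)
    unname(stats::coef(stats::lm(log(val[pos]) ~ log(lag[pos])))[2])
  else NA_real_
  super <- is.finite(ll) && ll > 1.5
  if (super)
    warning("MSD grows superdiffusively (log-log slope ",
            sprintf("%.2f", ll), "); D is not a diffusive coefficient")
  list(D_um2_s = slope / 4, loglog_slope = ll, superdiffusive = super)
}
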