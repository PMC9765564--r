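#' Effective diffusivity and front speed of a spreading culture
#'
#' The colony edge in semisolid agar is modelled as a Fisher reaction-
#' diffusion front: the radius grows linearly at speed
#' \code{c = 2 * sqrt(D_eff * g_eff)}, where \code{D_eff} is the effective
#' translational diffusivity of a run-and-trap swimmer and \code{g_eff} the
#' growth rate of the motile subpopulation, i.e. the division rate times
#' the probability that a daughter resumes swimming. This is how sessile
#' clustering slows spreading without any change in swimming speed.
#'
#' \code{effective_diffusivity} uses \code{D_eff = v^2 * tau_run / 2} (2-D),
#' with \code{v} the expected run speed and \code{1/tau_run} the total
#' reorientation rate: heading reversals of the mode chain, trap encounters,
#' and rotational decorrelation.
#'
#' @inheritParams expected_mode_occupancy
#' @return \code{effective_diffusivity}: um^2/s.
#'   \code{spreading_front_speed}: mm/h (radius growth rate).
#' @export
effective_diffusivity <- function(strain, env) {
  v <- expected_run_speed(strain, env)
  if (v <= 0) return(0)
  sr <- strain$switch_rate
  b <- strain$ccw_bias
  rev_rate <- b * sr$push_to_cw + (1 - b) * sr$cw_to_push
  reorient <- rev_rate + trap_rate_per_um(env) * v +
    strain_rot_diffusion(strain, env)
  tau_run <- 1 / reorient
  v^2 * tau_run / 2
}

#' @rdname effective_diffusivity
#' @export
spreading_front_speed <- function(strain, env) {
  D_um2_s <- effective_diffusivity(strain, env)
  D_mm2_h <- D_um2_s * 3600 / 1e6
  g_eff <- strain$division_rate * p_motile(strain, env)
  2 * sqrt(D_mm2_h * g_eff)
}

#' Simulate the time evolution of a colony diameter in swimming agar
#'
#' Diameter series of a growing, swimming culture: after an initial lag the
#' diameter grows linearly at twice the Fisher front speed
#' \code{\link{spreading_front_speed}} (the front speed is a radius growth
#' rate). A nonmotile strain keeps a constant diameter.
#'
#' @inheritParams expected_mode_occupancy
#' @param duration Observation time, h; > 0.
#' @param seed Optional integer seed (only used when \code{noise_sd > 0}).
#' @param dt_h Sampling interval, h.
#' @param d0_mm Initial colony diameter, mm.
#' @param lag_h Lag before the front starts moving, h.
#' @param noise_sd Additive measurement noise on the diameter, mm.
#' @return data.frame of class \code{spreading_series} with columns
#'   \code{strain}, \code{agar_pct}, \code{t_h}, \code{diameter_mm}.
#' @export
simulate_spreading <- function(strain, env, duration, seed = NULL,
                               dt_h = 0.5, d0_mm = 2, lag_h = 0.5,
                               noise_sd = 0) {
  stopifnot(inherits(strain, "strain_profile"),
            inherits(env, "environment_profile"))
  if (duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  t_h <- seq(0, duration, by = dt_h)
  cc <- spreading_front_speed(strain, env)
  d <- d0_mm + 2 * cc * pmax(0, t_h - lag_h)
  if (noise_sd > 0) {
    d <- d + stats::rnorm(length(d), 0, noise_sd)
    d <- cummax(d)  # a colony front does not retreat
  }
  structure(data.frame(strain = strain$name, agar_pct = env$agar_pct,
                       t_h = t_h, diameter_mm = d,
                       stringsAsFactors = FALSE),
            class = c("spreading_series", "data.frame"))
}

#' Fit the linear spreading regime of a diameter series
#'
#' Detects the initial lag as the longest initial window whose slope is
#' statistically consistent with zero (t-test at 5\%), then fits an ordinary
#' least-squares line to the remaining points.
#'
#' @param series A \code{spreading_series} or data.frame with columns
#'   \code{t_h} and \code{diameter_mm}.
#' @return List of class \code{spreading_fit}: \code{slope_mm_h},
#'   \code{intercept_mm}, \code{lag_h}, \code{residual_rms},
#'   \code{window} (indices fitted), \code{front_speed_mm_h}
#'   (= slope / 2, radius growth rate).
#' @export
fit_spreading <- function(series) {
  t <- series$t_h
  d <- series$diameter_mm
  n <- length(t)
  if (n < 3) stop("need at least 3 timepoints")
  if (any(diff(d) < -6 * stats::sd(diff(d)) - 1e-12))
    warning("diameter series is non-monotone beyond noise")

  flat_p <- function(k) {
    fit <- stats::lm(d[1:k] ~ t[1:k])
    # noiseless series fit exactly; the zero-residual warning is expected
    s <- suppressWarnings(summary(fit))$coefficients
    if (nrow(s) < 2 || !is.finite(s[2, 4])) 1 else s[2, 4]
  }
  lag_idx <- 1
  for (k in 3:n) {
    if (flat_p(k) > 0.05) lag_idx <- k else break
  }
  win <- if (lag_idx >= n - 1) seq_len(n) else lag_idx:n
  fit <- stats::lm(d[win] ~ t[win])
  slope <- max(0, unname(stats::coef(fit)[2]))
  if (!is.finite(slope)) slope <- 0
  structure(list(
    slope_mm_h = slope,
    intercept_mm = unname(stats::coef(fit)[1]),
    lag_h = if (lag_idx > 1) t[lag_idx] else 0,
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    window = range(win),
    front_speed_mm_h = slope / 2
  ), class = "spreading_fit")
}

#' @export
print.spreading_fit <- function(x, ...) {
  cat(sprintf("<spreading_fit> slope %.3f mm/h (front %.3f mm/h), lag %.2f h, RMS %.3g mm\n",
              x$slope_mm_h, x$front_speed_mm_h, x$lag_h, x$residual_rms))
  invisible(x)
}

#' Compare spreading fits across strains
#'
#' @param fits Named list of \code{\link{fit_spreading}} results, one per
#'   strain; at least two.
#' @return List with \code{table} (data.frame strain, slope_mm_h, rank,
#'   ordered fastest first) and \code{ratios} (matrix of pairwise slope
#'   ratios, row / column).
#' @export
compare_strains <- function(fits) {
  if (length(fits) < 2) stop("need fits for at least 2 strains")
  slopes <- vapply(fits, function(f) f$slope_mm_h, numeric(1))
  ord <- order(slopes, decreasing = TRUE)
  tab <- data.frame(strain = names(slopes)[ord],
                    slope_mm_h = unname(slopes[ord]),
                    rank = seq_along(slopes))
  ratios <- outer(slopes, slopes, function(a, b) ifelse(b > 0, a / b,
                                                        ifelse(a > 0, Inf, 1)))
  dimnames(ratios) <- list(names(slopes), names(slopes))
  list(table = tab, ratios = ratios)
}
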