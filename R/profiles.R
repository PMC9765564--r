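#' Load the shipped strain and environment profiles
#'
#' Reads the YAML file of default generative parameters for the four strains
#' (wild type, the single stator knockouts \code{dmotAB} and \code{dmotCD},
#' and the nonmotile double knockout \code{dmotABCD}) and the default media
#' (bulk aqueous, 10/15/20\% Ficoll, 0.25\% and 0.30\% semisolid agar).
#'
#' @param path Path to a profiles YAML file. Defaults to the file shipped
#'   with the package.
#' @return A list with elements \code{strains} and \code{environments}, each
#'   a named list of \code{\link{strain_profile}} /
#'   \code{\link{environment_profile}} objects.
#' @export
load_profiles <- function(path = system.file("extdata", "profiles.yaml",
                                             package = "bactrack")) {
  raw <- yaml::read_yaml(path)
  strains <- lapply(names(raw$strains), function(nm) {
    do.call(strain_profile, c(list(name = nm), raw$strains[[nm]]))
  })
  names(strains) <- names(raw$strains)
  envs <- lapply(names(raw$environments), function(nm) {
    do.call(environment_profile, c(list(name = nm), raw$environments[[nm]]))
  })
  names(envs) <- names(raw$environments)
  list(strains = strains, environments = envs)
}

#' Generative parameters for one strain
#'
#' A strain profile collects everything the swimmer generator needs to know
#' about a genotype: the speed of each run mode (push, pull, wrapped) in
#' water, the mode-switching rates of the continuous-time Markov chain
#' (including the stop state), the CCW bias (fraction of run time with CCW
#' flagellar rotation, i.e. in the push mode), the load-dependence of
#' wrapped-mode formation, rotational diffusion, and division outcomes.
#'
#' If \code{name} matches a shipped profile and no other arguments are
#' given, the shipped defaults are returned.
#'
#' @param name Strain label, e.g. \code{"WT"}, \code{"dmotAB"},
#'   \code{"dmotCD"}, \code{"dmotABCD"}.
#' @param mode_speed Named list/vector with elements \code{push},
#'   \code{pull}, \code{wrapped}; swimming speeds in water, um/s.
#' @param agar_mode_speed Optional mode speeds inside the agar meshwork,
#'   um/s; defaults to \code{mode_speed}. Confinement-driven stator
#'   recruitment can make these differ strongly from the fluid speeds
#'   (the \code{dmotAB} knockout is barely motile in fluids yet swims
#'   nearly like the wild type in agar).
#' @param agar_rot_diffusion Optional rotational diffusion in agar,
#'   rad^2/s; defaults to \code{rot_diffusion}.
#' @param switch_rate Named list with rates (1/s): \code{push_to_cw},
#'   \code{cw_to_push}, \code{run_to_stop}, \code{stop_to_run}.
#' @param ccw_bias Fraction of run time in the push (CCW) mode.
#' @param wrapped_propensity_params List with \code{shape}
#'   (\code{"logistic"} or \code{"peaked"}), \code{midpoint} (cP; the peak
#'   position for the peaked shape), \code{steepness}, and \code{max}.
#' @param rot_diffusion Rotational diffusion coefficient, rad^2/s.
#' @param division_rate Division rate, 1/h.
#' @param p_motile_daughter Named list mapping environment label to the
#'   probability that a daughter cell is motile after division.
#' @return An object of class \code{strain_profile}.
#' @export
strain_profile <- function(name = "WT", mode_speed = NULL, switch_rate = NULL,
                           ccw_bias = NULL, wrapped_propensity_params = NULL,
                           rot_diffusion = NULL, division_rate = NULL,
                           p_motile_daughter = NULL, agar_mode_speed = NULL,
                           agar_rot_diffusion = NULL) {
  if (is.null(mode_speed)) {
    defaults <- .default_profiles()$strains
    if (!name %in% names(defaults))
      stop("unknown strain '", name, "' and no parameters given")
    return(defaults[[name]])
  }
  p <- structure(list(
    name = name,
    mode_speed = lapply(mode_speed, as.numeric),
    agar_mode_speed = lapply(
      if (is.null(agar_mode_speed)) mode_speed else agar_mode_speed,
      as.numeric),
    agar_rot_diffusion = as.numeric(
      if (is.null(agar_rot_diffusion)) rot_diffusion
      else agar_rot_diffusion),
    switch_rate = lapply(switch_rate, as.numeric),
    ccw_bias = as.numeric(ccw_bias),
    wrapped_propensity_params = wrapped_propensity_params,
    rot_diffusion = as.numeric(rot_diffusion),
    division_rate = as.numeric(division_rate),
    p_motile_daughter = lapply(p_motile_daughter, as.numeric)
  ), class = "strain_profile")
  validate_strain_profile(p)
}

validate_strain_profile <- function(p) {
  sp <- c(unlist(p$mode_speed), unlist(p$agar_mode_speed))
  if (!all(c("push", "pull", "wrapped") %in% names(p$mode_speed)) ||
      !all(c("push", "pull", "wrapped") %in% names(p$agar_mode_speed)))
    stop("mode_speed must name push, pull and wrapped")
  if (any(sp < 0)) stop("mode speeds must be >= 0")
  if (any(unlist(p$switch_rate) < 0)) stop("switch rates must be >= 0")
  if (p$ccw_bias < 0 || p$ccw_bias > 1) stop("ccw_bias must be in [0, 1]")
  pm <- unlist(p$p_motile_daughter)
  if (any(pm < 0 | pm > 1)) stop("p_motile_daughter must be in [0, 1]")
  if (p$rot_diffusion < 0) stop("rot_diffusion must be >= 0")
  if (p$division_rate < 0) stop("division_rate must be >= 0")
  wp <- p$wrapped_propensity_params
  if (wp$max < 0 || wp$max > 1) stop("wrapped propensity max must be in [0, 1]")
  p
}

#' @export
print.strain_profile <- function(x, ...) {
  cat("<strain_profile>", x$name, "\n")
  cat(sprintf("  mode speeds (um/s): push %.1f, pull %.1f, wrapped %.1f\n",
              x$mode_speed$push, x$mode_speed$pull, x$mode_speed$wrapped))
  cat(sprintf("  ccw bias %.2f, rot. diffusion %.2f rad^2/s, division %.2f /h\n",
              x$ccw_bias, x$rot_diffusion, x$division_rate))
  invisible(x)
}

#' Generative parameters for one medium
#'
#' @param name Environment label (used to look up division outcomes in a
#'   strain profile, e.g. \code{"agar0.25"}).
#' @param kind \code{"bulk"} (open fluid, possibly viscosified with Ficoll)
#'   or \code{"agar"} (fluid-filled porous meshwork).
#' @param ficoll_pct Ficoll 400 concentration, \% wt/vol.
#' @param viscosity Dynamic viscosity, cP; >= 1.
#' @param agar_pct Agar concentration, \%, for agar environments.
#' @param pore_range Numeric length-2: (min, max) pore diameter in nm.
#' @param trap_rate Trap encounters per um of run path at a 1 um reference
#'   pore size; the effective rate scales inversely with the mean pore size.
#'   Must be 0 in bulk.
#' @param trap_duration_mean Mean trap dwell time, s (exponential).
#' @param load_equiv Effective mechanical load in agar, cP-equivalent, used
#'   by the wrapped-mode propensity.
#' @return An object of class \code{environment_profile}.
#' @export
environment_profile <- function(name = "bulk", kind = NULL, ficoll_pct = 0,
                                viscosity = NULL, agar_pct = NA_real_,
                                pore_range = NULL, trap_rate = 0,
                                trap_duration_mean = 0, load_equiv = NULL) {
  if (is.null(kind)) {
    defaults <- .default_profiles()$environments
    if (!name %in% names(defaults))
      stop("unknown environment '", name, "' and no parameters given")
    return(defaults[[name]])
  }
  if (is.null(viscosity)) viscosity <- ficoll_viscosity(ficoll_pct)
  e <- structure(list(
    name = name, kind = kind, ficoll_pct = as.numeric(ficoll_pct),
    viscosity = as.numeric(viscosity), agar_pct = as.numeric(agar_pct),
    pore_range = if (is.null(pore_range)) c(NA_real_, NA_real_)
                 else as.numeric(pore_range),
    trap_rate = as.numeric(trap_rate),
    trap_duration_mean = as.numeric(trap_duration_mean),
    load_equiv = if (is.null(load_equiv)) as.numeric(viscosity)
                 else as.numeric(load_equiv)
  ), class = "environment_profile")
  validate_environment_profile(e)
}

validate_environment_profile <- function(e) {
  if (!e$kind %in% c("bulk", "agar")) stop("kind must be 'bulk' or 'agar'")
  if (e$viscosity < 1) stop("viscosity must be >= 1 cP")
  if (e$kind == "bulk" && e$trap_rate != 0)
    stop("trap_rate must be 0 in bulk fluid")
  if (!any(is.na(e$pore_range)) && e$pore_range[1] > e$pore_range[2])
    stop("pore_range must be (min, max)")
  if (e$trap_rate < 0) stop("trap_rate must be >= 0")
  e
}

#' @export
print.environment_profile <- function(x, ...) {
  cat("<environment_profile>", x$name, sprintf("(%s)\n", x$kind))
  cat(sprintf("  viscosity %.1f cP", x$viscosity))
  if (x$kind == "agar")
    cat(sprintf(", %.2f%% agar, pores %.0f-%.0f nm", x$agar_pct,
                x$pore_range[1], x$pore_range[2]))
  cat("\n")
  invisible(x)
}

# cache of the shipped defaults
.profile_cache <- new.env(parent = emptyenv())
.default_profiles <- function() {
  if (is.null(.profile_cache$p)) .profile_cache$p <- load_profiles()
  .profile_cache$p
}

# Ficoll 400 concentration -> viscosity anchors (pct, cP)
.ficoll_anchors <- data.frame(pct = c(0, 10, 15, 20),
                              visc = c(1, 5, 10, 18))

#' Ficoll concentration to viscosity
#'
#' Maps a Ficoll 400 concentration (\% wt/vol) to a dynamic viscosity in cP.
#' The anchor points 0/10/15/20\% -> 1/5/10/18 cP are interpolated
#' monotonically on the log-viscosity scale; extrapolation beyond the
#' highest anchor is refused.
#'
#' @param pct Ficoll concentration, \% wt/vol, in [0, 20].
#' @return Viscosity in cP.
#' @examples
#' ficoll_viscosity(c(0, 10, 15, 20))
#' @export
ficoll_viscosity <- function(pct) {
  pct <- as.numeric(pct)
  if (any(!is.finite(pct)) || any(pct < 0))
    stop("Ficoll concentration must be a finite percentage >= 0")
  if (any(pct > 30)) stop("Ficoll concentration above 30% is out of range")
  if (any(pct > 20))
    stop("no viscosity anchor above 20% Ficoll; extrapolation refused")
  a <- .ficoll_anchors
  out <- exp(stats::approx(a$pct, log(a$visc), xout = pct,
                           method = "linear")$y)
  hit <- match(pct, a$pct)
  out[!is.na(hit)] <- a$visc[hit[!is.na(hit)]]  # anchors are exact
  out
}

#' Viscosity-dependent speed scale
#'
#' Swimming speed is modelled as a power law of viscosity,
#' v(eta) = v(1 cP) * (eta / 1 cP)^(-alpha). The default exponent is the
#' ordinary least-squares slope of log speed against log viscosity through
#' the measured wild-type means (1, 32.1), (5, 11.4), (10, 8.9),
#' (18, 6.3) (cP, um/s).
#'
#' @param viscosity Viscosity in cP, >= 1.
#' @param alpha Power-law exponent, >= 0.
#' @return Dimensionless factor in (0, 1]; 1 at 1 cP.
#' @export
viscosity_speed_factor <- function(viscosity, alpha = wt_viscosity_exponent()) {
  viscosity <- as.numeric(viscosity)
  if (any(!is.finite(viscosity)) || any(viscosity < 1))
    stop("viscosity must be >= 1 cP")
  if (alpha < 0) stop("alpha must be >= 0")
  viscosity^(-alpha)
}

#' Default viscosity exponent fitted to wild-type speeds
#'
#' Closed-form least-squares slope of log speed vs log viscosity over the
#' four wild-type (viscosity, mean speed) points measured in bulk and
#' Ficoll media.
#'
#' @return The exponent alpha (about 0.56).
#' @export
wt_viscosity_exponent <- function() {
  x <- log(c(1, 5, 10, 18))
  y <- log(c(32.1, 11.4, 8.9, 6.3))
  -unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Probability of entering the wrapped mode under CW rotation
#'
#' Load-dependent propensity for a CW run to take place in the wrapped mode
#' rather than the pull mode. Wild-type-like strains follow a saturating
#' logistic in log(load): wrapped runs become dominant at high viscosity.
#' The \code{dmotAB} knockout instead follows a peaked (gamma-shaped in
#' log-load) curve that is exactly zero in water, rises to a strain maximum
#' near the configured midpoint, and declines again at the highest loads.
#'
#' @param strain A \code{\link{strain_profile}}.
#' @param load Mechanical load, cP-equivalent, >= 1.
#' @return Probability in [0, max].
#' @export
wrapped_propensity <- function(strain, load) {
  stopifnot(inherits(strain, "strain_profile"))
  load <- as.numeric(load)
  if (any(!is.finite(load)) || any(load < 1)) stop("load must be >= 1")
  wp <- strain$wrapped_propensity_params
  x <- log(load)
  if (identical(wp$shape, "peaked")) {
    xp <- log(wp$midpoint)
    r <- x / xp
    p <- wp$max * (r * exp(1 - r))^wp$steepness
    p[x <= 0] <- 0
    p
  } else {
    wp$max * stats::plogis(wp$steepness * (x - log(wp$midpoint)))
  }
}

#' Sample pore diameters of a semisolid agar meshwork
#'
#' Draws pore diameters uniformly between the configured minimum and
#' maximum pore size of an agar environment (740-4800 nm for the default
#' 0.25\% agar).
#'
#' @param env An agar \code{\link{environment_profile}}.
#' @param n Number of pores to draw.
#' @param seed Optional integer seed.
#' @return Numeric vector of pore diameters in nm.
#' @export
sample_pore_size <- function(env, n, seed = NULL) {
  stopifnot(inherits(env, "environment_profile"))
  if (env$kind != "agar" || any(is.na(env$pore_range)))
    stop("pore sizes are only defined for agar environments")
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, env$pore_range[1], env$pore_range[2])
}
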