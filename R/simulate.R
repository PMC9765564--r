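.mode_states <- c("push", "pull", "wrapped", "stop")

# condition-dependent phenotype: speeds and heading noise differ between
# open fluid and the agar meshwork (stator recruitment under confinement)
strain_mode_speeds <- function(strain, env) {
  if (env$kind == "agar") strain$agar_mode_speed else strain$mode_speed
}
strain_rot_diffusion <- function(strain, env) {
  if (env$kind == "agar") strain$agar_rot_diffusion else strain$rot_diffusion
}

# Continuous-time Markov rate matrix over {push, pull, wrapped, stop}.
# CW entries (from push or from stop) are split between pull and wrapped by
# the load-dependent wrapped propensity.
mode_rate_matrix <- function(strain, load) {
  pw <- wrapped_propensity(strain, load)
  sr <- strain$switch_rate
  Q <- matrix(0, 4, 4, dimnames = list(.mode_states, .mode_states))
  Q["push", "pull"] <- sr$push_to_cw * (1 - pw)
  Q["push", "wrapped"] <- sr$push_to_cw * pw
  Q["pull", "push"] <- sr$cw_to_push
  Q["wrapped", "push"] <- sr$cw_to_push
  Q[c("push", "pull", "wrapped"), "stop"] <- sr$run_to_stop
  Q["stop", "push"] <- sr$stop_to_run * strain$ccw_bias
  Q["stop", "pull"] <- sr$stop_to_run * (1 - strain$ccw_bias) * (1 - pw)
  Q["stop", "wrapped"] <- sr$stop_to_run * (1 - strain$ccw_bias) * pw
  diag(Q) <- -rowSums(Q)
  Q
}

ctmc_stationary <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  stats::setNames(pi / sum(pi), rownames(Q))
}

#' Stationary mode occupancy of a strain in an environment
#'
#' Fraction of time spent in each of push, pull, wrapped and stop under the
#' strain's mode-switching Markov chain, at the environment's mechanical
#' load (traps excluded; the mode clock keeps running while trapped).
#'
#' @param strain A \code{\link{strain_profile}}.
#' @param env An \code{\link{environment_profile}}.
#' @return Named numeric vector over push/pull/wrapped/stop, summing to 1.
#' @export
expected_mode_occupancy <- function(strain, env) {
  ctmc_stationary(mode_rate_matrix(strain, env$load_equiv))
}

#' Expected swimming speeds implied by a profile pair
#'
#' Closed-form mixture means of the instantaneous speed under the stationary
#' mode occupancy, with speeds scaled by the environment's viscosity.
#' \code{expected_run_speed} conditions on the run modes (push, pull,
#' wrapped); \code{expected_speed} includes the stop state at speed zero.
#'
#' @inheritParams expected_mode_occupancy
#' @return Speed in um/s.
#' @export
expected_run_speed <- function(strain, env) {
  occ <- expected_mode_occupancy(strain, env)
  fac <- viscosity_speed_factor(env$viscosity)
  v <- unlist(strain_mode_speeds(strain, env)[c("push", "pull", "wrapped")]) * fac
  w <- occ[c("push", "pull", "wrapped")]
  sum(w * v) / sum(w)
}

#' @rdname expected_run_speed
#' @export
expected_speed <- function(strain, env) {
  occ <- expected_mode_occupancy(strain, env)
  fac <- viscosity_speed_factor(env$viscosity)
  v <- c(unlist(strain_mode_speeds(strain, env)[c("push", "pull", "wrapped")]) * fac, 0)
  sum(occ[c("push", "pull", "wrapped", "stop")] * v)
}

# effective trap encounter rate per um of run path
trap_rate_per_um <- function(env) {
  if (env$kind != "agar" || env$trap_rate == 0) return(0)
  mean_pore_um <- mean(env$pore_range) / 1000
  env$trap_rate / mean_pore_um
}

.rotation_sense <- c(push = "ccw", pull = "cw", wrapped = "cw")

#' Simulate one swimming cell
#'
#' Agent-based generator of a single 2-D swimmer. Run modes (push, pull,
#' wrapped) and stops switch as a continuous-time Markov chain; during runs
#' the cell translates at the mode speed scaled by the viscosity power law
#' and its heading diffuses rotationally. A switch between CCW (push) and
#' CW (pull/wrapped) rotation reverses the heading by 180 degrees plus a
#' small jitter; pull/wrapped interchanges keep the heading. In agar, trap
#' events fire as a Poisson process along the run path (rate inversely
#' proportional to the mean pore size); a trapped cell is immobilised for an
#' exponential dwell and resumes with a uniformly random heading.
#'
#' @param strain A \code{\link{strain_profile}}.
#' @param env An \code{\link{environment_profile}}.
#' @param duration Total simulated time, s.
#' @param dt Time step, s (default 0.05, i.e. 20 frames per second).
#' @param seed Optional integer seed; identical seeds give identical paths.
#' @param id Track identifier stored in the result.
#' @return An object of class \code{swimmer_path}: list with \code{times}
#'   (s), \code{x}, \code{y} (um), per-timepoint \code{mode} and
#'   \code{phase} ("run"/"trap"), and metadata. Convert with
#'   \code{as.data.frame}.
#' @export
simulate_swimmer <- function(strain, env, duration, dt = 0.05, seed = NULL,
                             id = 1L) {
  stopifnot(inherits(strain, "strain_profile"),
            inherits(env, "environment_profile"))
  if (duration < 0) stop("duration must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (duration > 0 && dt >= duration)
    stop("dt must be smaller than duration")
  if (!is.null(seed)) set.seed(seed)

  n <- round(duration / dt)
  times <- (0:n) * dt
  Q <- mode_rate_matrix(strain, env$load_equiv)
  pi0 <- ctmc_stationary(Q)

  # continuous-time jump chain, sampled on the grid
  state <- sample(.mode_states, 1, prob = pi0)
  jump_t <- 0
  seq_states <- state
  seq_times <- 0
  while (jump_t <= duration) {
    out <- -Q[state, state]
    if (out <= 0) break
    jump_t <- jump_t + stats::rexp(1, out)
    probs <- Q[state, ]
    probs[state] <- 0
    state <- sample(.mode_states, 1, prob = probs)
    seq_states <- c(seq_states, state)
    seq_times <- c(seq_times, jump_t)
  }
  mode <- seq_states[findInterval(times, seq_times)]

  fac <- viscosity_speed_factor(env$viscosity)
  vmode <- c(unlist(strain_mode_speeds(strain, env)[c("push", "pull", "wrapped")]) * fac,
             stop = 0)
  rate_trap <- trap_rate_per_um(env)
  rot_diff <- strain_rot_diffusion(strain, env)
  jitter_sd <- 15 * pi / 180

  x <- y <- numeric(n + 1)
  phase <- rep("run", n + 1)
  theta <- stats::runif(1, 0, 2 * pi)
  last_sense <- NA_character_
  trap_left <- 0

  if (n > 0) for (k in seq_len(n)) {
    if (trap_left > 0) {
      phase[k] <- "trap"
      x[k + 1] <- x[k]; y[k + 1] <- y[k]
      trap_left <- trap_left - dt
      if (trap_left <= 0) {
        trap_left <- 0
        theta <- stats::runif(1, 0, 2 * pi)
        last_sense <- NA_character_
      }
      next
    }
    m <- mode[k]
    if (m != "stop") {
      sense <- .rotation_sense[[m]]
      if (!is.na(last_sense) && sense != last_sense)
        theta <- theta + pi + stats::rnorm(1, 0, jitter_sd)
      last_sense <- sense
    }
    v <- vmode[[m]]
    x[k + 1] <- x[k] + v * dt * cos(theta)
    y[k + 1] <- y[k] + v * dt * sin(theta)
    if (v > 0) {
      theta <- theta + sqrt(2 * rot_diff * dt) * stats::rnorm(1)
      if (rate_trap > 0 && stats::runif(1) < rate_trap * v * dt)
        trap_left <- stats::rexp(1, 1 / env$trap_duration_mean)
    }
  }
  phase[n + 1] <- if (trap_left > 0) "trap" else "run"

  structure(list(id = id, times = times, x = x, y = y, mode = mode,
                 phase = phase, dt = dt, strain = strain$name,
                 env = env$name),
            class = "swimmer_path")
}

#' @export
as.data.frame.swimmer_path <- function(x, ...) {
  data.frame(track_id = x$id, frame = seq_along(x$times) - 1L,
             t_s = x$times, x_um = x$x, y_um = x$y,
             mode = x$mode, phase = x$phase, stringsAsFactors = FALSE)
}

#' @export
print.swimmer_path <- function(x, ...) {
  cat(sprintf("<swimmer_path> id %s: %d timepoints over %.2f s (%s in %s)\n",
              x$id, length(x$times), max(x$times), x$strain, x$env))
  invisible(x)
}

#' Total path length of a swimmer path
#'
#' @param path A \code{swimmer_path}.
#' @return Summed step length, um.
#' @export
path_length <- function(path) {
  sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
}

#' Simulate a population of independent swimmers
#'
#' Each path gets its own seed derived reproducibly from the master seed.
#'
#' @param n Number of cells, >= 0.
#' @inheritParams simulate_swimmer
#' @return Object of class \code{swimmer_population}: list of
#'   \code{swimmer_path}, convertible with \code{as.data.frame}.
#' @export
simulate_population <- function(n, strain, env, duration, dt = 0.05,
                                seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer(0)
  paths <- lapply(seq_len(n), function(i)
    simulate_swimmer(strain, env, duration, dt, seed = seeds[i], id = i))
  structure(paths, class = "swimmer_population")
}

#' @export
as.data.frame.swimmer_population <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' @export
print.swimmer_population <- function(x, ...) {
  cat(sprintf("<swimmer_population> %d paths\n", length(x)))
  invisible(x)
}

#' Fraction of timepoints spent trapped, per path
#'
#' @param pop A \code{swimmer_population}.
#' @return Numeric vector of per-path trap fractions.
#' @export
trap_fraction <- function(pop) {
  vapply(unclass(pop), function(p) mean(p$phase == "trap"), numeric(1))
}
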