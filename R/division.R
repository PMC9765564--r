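#' Division outcome probability for a strain in an environment
#'
#' Looks up the probability that a daughter cell resumes swimming after the
#' division of a trapped cell. Falls back from the exact environment name to
#' the environment class (\code{bulk}, \code{ficoll}, or the agar
#' concentration label).
#'
#' @inheritParams expected_mode_occupancy
#' @return Probability in [0, 1].
#' @export
p_motile <- function(strain, env) {
  pm <- strain$p_motile_daughter
  if (env$name %in% names(pm)) return(pm[[env$name]])
  key <- if (env$kind == "bulk") {
    if (env$ficoll_pct > 0 && "ficoll" %in% names(pm)) "ficoll" else "bulk"
  } else {
    lab <- paste0("agar", sub("0+$", "", format(env$agar_pct)))
    if (lab %in% names(pm)) lab else grep("^agar", names(pm), value = TRUE)[1]
  }
  if (is.na(key) || !key %in% names(pm))
    stop("no p_motile_daughter entry for environment '", env$name, "'")
  pm[[key]]
}

#' Simulate divisions of trapped cells and sessile cluster growth
#'
#' Stochastic (Gillespie) branching process: every cell divides at the
#' strain's division rate; each of the two daughters independently resumes
#' swimming with probability \code{p_motile(strain, env)}. Sessile daughters
#' of a motile parent found a new cluster; sessile daughters of a clustered
#' cell stay in their parent's cluster, so clusters keep growing by further
#' divisions.
#'
#' @inheritParams expected_mode_occupancy
#' @param n0 Initial number of (motile) cells, >= 1.
#' @param duration Simulated time, h.
#' @param seed Optional integer seed.
#' @param n_grid Number of grid points for the reported time series.
#' @return List of class \code{division_sim} with elements
#'   \describe{
#'     \item{records}{data.frame of division events: \code{parent_id},
#'       \code{time_h}, \code{daughter1}, \code{daughter2} (each
#'       \code{"motile"}/\code{"sessile"}), \code{cluster_id} (NA if no
#'       sessile daughter).}
#'     \item{series}{data.frame \code{time_h}, \code{n_motile},
#'       \code{n_sessile}, \code{n_clusters}, \code{max_cluster}.}
#'     \item{cluster_sizes}{final cluster sizes.}
#'   }
#' @export
simulate_division_clusters <- function(strain, env, n0, duration,
                                       seed = NULL, n_grid = 50) {
  stopifnot(inherits(strain, "strain_profile"),
            inherits(env, "environment_profile"), n0 >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- p_motile(strain, env)
  g <- strain$division_rate

  state <- rep("motile", n0)           # per-cell state
  cluster <- rep(NA_integer_, n0)      # per-cell cluster id
  alive <- rep(TRUE, n0)
  next_id <- n0 + 1L
  next_cluster <- 1L
  records <- list()

  grid <- seq(0, duration, length.out = n_grid)
  series <- data.frame(time_h = grid, n_motile = NA_real_,
                       n_sessile = NA_real_, n_clusters = NA_real_,
                       max_cluster = NA_real_)
  snap <- function(gi) {
    cl <- cluster[alive & state == "sessile"]
    series$n_motile[gi] <<- sum(alive & state == "motile")
    series$n_sessile[gi] <<- length(cl)
    series$n_clusters[gi] <<- length(unique(cl))
    series$max_cluster[gi] <<- if (length(cl)) max(table(cl)) else 0
  }

  t <- 0
  gi <- 1
  if (g > 0) repeat {
    n_alive <- sum(alive)
    t_next <- t + stats::rexp(1, g * n_alive)
    while (gi <= n_grid && grid[gi] < min(t_next, duration)) {
      snap(gi); gi <- gi + 1
    }
    if (t_next > duration) break
    t <- t_next
    idx <- sample(which(alive), 1)
    d_state <- ifelse(stats::runif(2) < p, "motile", "sessile")
    cl_id <- NA_integer_
    if (any(d_state == "sessile")) {
      cl_id <- if (state[idx] == "sessile") cluster[idx] else {
        cid <- next_cluster
        next_cluster <- next_cluster + 1L
        cid
      }
    }
    alive[idx] <- FALSE
    state <- c(state, d_state)
    cluster <- c(cluster,
                 ifelse(d_state == "sessile", cl_id, NA_integer_))
    alive <- c(alive, TRUE, TRUE)
    records[[length(records) + 1]] <- data.frame(
      parent_id = idx, time_h = t, daughter1 = d_state[1],
      daughter2 = d_state[2], cluster_id = cl_id)
    next_id <- next_id + 2L
  }
  while (gi <= n_grid) { snap(gi); gi <- gi + 1 }

  cl <- cluster[alive & state == "sessile"]
  structure(list(
    records = if (length(records)) do.call(rbind, records) else
      data.frame(parent_id = integer(0), time_h = numeric(0),
                 daughter1 = character(0), daughter2 = character(0),
                 cluster_id = integer(0)),
    series = series,
    cluster_sizes = if (length(cl)) as.integer(table(cl)) else integer(0)
  ), class = "division_sim")
}

#' @export
print.division_sim <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf("<division_sim> %d divisions; final: %d motile, %d sessile in %d clusters\n",
              nrow(x$records), last$n_motile, last$n_sessile,
              last$n_clusters))
  invisible(x)
}
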