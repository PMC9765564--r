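#' Linking configuration
#'
#' @param max_disp Maximum per-frame displacement, um; links beyond this
#'   gate are forbidden.
#' @param memory Maximum number of consecutive frames a track may go
#'   unmatched before it is terminated.
#' @param fps Frame rate used to convert frame numbers to seconds.
#' @return An object of class \code{link_config}.
#' @export
link_config <- function(max_disp = 3, memory = 2, fps = 20) {
  if (max_disp <= 0) stop("max_disp must be > 0")
  if (memory < 0) stop("memory must be >= 0")
  if (fps <= 0) stop("fps must be > 0")
  structure(list(max_disp = max_disp, memory = as.integer(memory),
                 fps = fps), class = "link_config")
}

# Exact solver for the square linear assignment problem (shortest
# augmenting path / Hungarian, O(n^3)). Returns, for each row, the column
# assigned to it.
solve_assignment <- function(a) {
  n <- nrow(a)
  m <- ncol(a)
  stopifnot(n <= m)
  u <- numeric(n)
  v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  res <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) res[p[j + 1]] <- j
  res
}

# Match active track heads to detections in one frame.
# Returns an integer vector over tracks: detection index or 0 (unmatched).
# Objective: maximise the number of links within the max_disp gate, then
# minimise the total squared displacement (Crocker-Grier cost principle),
# realised with birth/death dummy costs that dominate any real cost.
match_frame <- function(px, py, dx, dy, max_disp) {
  nt <- length(px)
  nd <- length(dx)
  if (nt == 0 || nd == 0) return(integer(nt))
  d2 <- outer(px, dx, "-")^2 + outer(py, dy, "-")^2
  gate2 <- max_disp^2
  B <- (gate2 + 1) * (nt + nd + 1)   # cost of leaving one side unmatched
  M <- B * (nt + nd + 1) * 4         # forbidden link
  size <- nt + nd
  cost <- matrix(0, size, size)
  cost[seq_len(nt), seq_len(nd)] <- ifelse(d2 <= gate2, d2, M)
  cost[seq_len(nt), nd + seq_len(nt)] <- M
  cost[cbind(seq_len(nt), nd + seq_len(nt))] <- B
  cost[nt + seq_len(nd), seq_len(nd)] <- M
  cost[cbind(nt + seq_len(nd), seq_len(nd))] <- B
  assign <- solve_assignment(cost)
  res <- assign[seq_len(nt)]
  res[res > nd] <- 0L
  # safety: a forbidden pairing can never be optimal, but never emit one
  for (i in seq_len(nt)) {
    if (res[i] > 0 && d2[i, res[i]] > gate2) res[i] <- 0L
  }
  res
}

#' Link per-frame detections into trajectories
#'
#' Crocker-Grier style frame-to-frame linking: between consecutive frames,
#' active track heads and new detections are paired by an exact
#' minimum-cost assignment on squared displacements, with pairings beyond
#' \code{max_disp} forbidden. Unmatched detections start new tracks;
#' unmatched tracks survive up to \code{memory} frames (re-entering the
#' matching at their last known position, without motion prediction) and
#' are then terminated. Ties are broken by the solver deterministically in
#' favour of lower (track, detection) indices, so results are reproducible
#' for a given input order.
#'
#' @param detections data.frame with columns \code{frame} (integer),
#'   \code{x_um}, \code{y_um}.
#' @param config A \code{\link{link_config}}.
#' @return data.frame with columns \code{track_id}, \code{frame},
#'   \code{t_s}, \code{x_um}, \code{y_um}; one row per linked detection
#'   (gap frames carry no row).
#' @export
link_detections <- function(detections, config = link_config()) {
  stopifnot(inherits(config, "link_config"))
  req <- c("frame", "x_um", "y_um")
  if (!all(req %in% names(detections)))
    stop("detections must have columns frame, x_um, y_um")
  if (nrow(detections) == 0) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      t_s = numeric(0), x_um = numeric(0),
                      y_um = numeric(0)))
  }
  if (is.unsorted(detections$frame))
    stop("detections must be ordered by frame")

  frames <- sort(unique(detections$frame))
  by_frame <- split(detections[, c("x_um", "y_um")], detections$frame)

  # active track state
  act_id <- integer(0)
  act_x <- numeric(0)
  act_y <- numeric(0)
  act_age <- integer(0)   # frames since last match
  next_id <- 1L
  rows <- vector("list", length(frames))

  first <- by_frame[[1]]
  n0 <- nrow(first)
  act_id <- seq_len(n0)
  act_x <- first$x_um
  act_y <- first$y_um
  act_age <- rep(0L, n0)
  next_id <- n0 + 1L
  rows[[1]] <- data.frame(track_id = act_id, frame = frames[1],
                          x_um = act_x, y_um = act_y)

  for (fi in seq_along(frames)[-1]) {
    gap <- frames[fi] - frames[fi - 1]
    act_age <- act_age + gap - 1L
    keep <- act_age <= config$memory
    act_id <- act_id[keep]; act_x <- act_x[keep]; act_y <- act_y[keep]
    act_age <- act_age[keep]

    det <- by_frame[[fi]]
    m <- match_frame(act_x, act_y, det$x_um, det$y_um, config$max_disp)
    matched_tracks <- which(m > 0)
    matched_dets <- m[matched_tracks]

    act_x[matched_tracks] <- det$x_um[matched_dets]
    act_y[matched_tracks] <- det$y_um[matched_dets]
    act_age[matched_tracks] <- 0L
    act_age[setdiff(seq_along(act_id), matched_tracks)] <-
      act_age[setdiff(seq_along(act_id), matched_tracks)] + 1L

    new_dets <- setdiff(seq_len(nrow(det)), matched_dets)
    new_ids <- seq.int(next_id, length.out = length(new_dets))
    next_id <- next_id + length(new_dets)

    rows[[fi]] <- data.frame(
      track_id = c(act_id[matched_tracks], new_ids),
      frame = frames[fi],
      x_um = c(det$x_um[matched_dets], det$x_um[new_dets]),
      y_um = c(det$y_um[matched_dets], det$y_um[new_dets]))

    act_id <- c(act_id, new_ids)
    act_x <- c(act_x, det$x_um[new_dets])
    act_y <- c(act_y, det$y_um[new_dets])
    act_age <- c(act_age, rep(0L, length(new_dets)))
    drop <- act_age > config$memory
    if (any(drop)) {
      act_id <- act_id[!drop]; act_x <- act_x[!drop]
      act_y <- act_y[!drop]; act_age <- act_age[!drop]
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  out$t_s <- out$frame / config$fps
  rownames(out) <- NULL
  out[, c("track_id", "frame", "t_s", "x_um", "y_um")]
}

#' Fraction of correctly linked consecutive pairs
#'
#' Scores linked tracks against ground-truth swimmer paths: every
#' consecutive pair of points within a track is correct iff both points
#' are nearest to the same ground-truth cell at their respective frames.
#'
#' @param tracks data.frame from \code{\link{link_detections}}.
#' @param truth A \code{swimmer_population} (optionally with the same
#'   per-path \code{offsets} used when rendering).
#' @param offsets Optional n x 2 offset matrix matching
#'   \code{\link{render_detections}}.
#' @return Fraction in [0, 1].
#' @export
track_recovery_score <- function(tracks, truth, offsets = NULL) {
  truth <- unclass(truth)
  if (nrow(tracks) == 0 || length(truth) == 0)
    stop("empty tracks or truth")
  nearest_truth <- function(frame, x, y) {
    f <- frame + 1L
    tx <- vapply(truth, function(p) p$x[f], numeric(1))
    ty <- vapply(truth, function(p) p$y[f], numeric(1))
    if (!is.null(offsets)) {
      tx <- tx + offsets[, 1]
      ty <- ty + offsets[, 2]
    }
    which.min((tx - x)^2 + (ty - y)^2)
  }
  ids <- mapply(nearest_truth, tracks$frame, tracks$x_um, tracks$y_um)
  total <- 0L
  good <- 0L
  for (tr in split(seq_len(nrow(tracks)), tracks$track_id)) {
    if (length(tr) < 2) next
    total <- total + length(tr) - 1L
    good <- good + sum(ids[tr[-length(tr)]] == ids[tr[-1]])
  }
  if (total == 0) stop("no consecutive pairs to score")
  good / total
}
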