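# Independent brute-force oracles used to validate the optimised
# implementations on small instances.

# Exhaustive enumeration of all gated partial matchings between track
# heads (px, py) and detections (dx, dy); returns the matching with
# maximum cardinality and, among those, minimum summed squared
# displacement.
oracle_match <- function(px, py, dx, dy, max_disp) {
  nt <- length(px)
  nd <- length(dx)
  best <- list(card = -1L, cost = Inf, match = integer(nt))
  if (nt == 0) return(best)
  d2 <- outer(px, dx, "-")^2 + outer(py, dy, "-")^2
  feas <- d2 <= max_disp^2
  rec <- function(i, used, match, card, cost) {
    if (i > nt) {
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12)) {
        best <<- list(card = card, cost = cost, match = match)
      }
      return(invisible(NULL))
    }
    rec(i + 1L, used, match, card, cost)
    if (nd > 0) {
      for (j in seq_len(nd)) {
        if (!used[j] && feas[i, j]) {
          used[j] <- TRUE
          match[i] <- j
          rec(i + 1L, used, match, card + 1L, cost + d2[i, j])
          used[j] <- FALSE
          match[i] <- 0L
        }
      }
    }
  }
  rec(1L, rep(FALSE, max(nd, 1L)), integer(nt), 0L, 0)
  best
}

# Frame-by-frame oracle tracker: same contract as link_detections (gate,
# memory, max-cardinality-then-min-cost matching) but built on the
# exhaustive enumeration above and an independent bookkeeping loop.
oracle_link <- function(det, config) {
  frames <- sort(unique(det$frame))
  tracks <- list()   # each: data.frame(frame, x_um, y_um)
  last <- list()     # per-track last position
  age <- integer(0)  # frames unmatched
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    d <- det[det$frame == f, , drop = FALSE]
    if (fi > 1) age <- age + (f - frames[fi - 1]) - 1L
    act <- which(age <= config$memory)
    px <- vapply(last[act], `[[`, numeric(1), 1)
    py <- vapply(last[act], `[[`, numeric(1), 2)
    m <- if (length(act))
      oracle_match(px, py, d$x_um, d$y_um, config$max_disp)$match
    else integer(0)
    taken <- m[m > 0]
    for (ii in seq_along(act)) {
      ti <- act[ii]
      if (length(m) >= ii && m[ii] > 0) {
        j <- m[ii]
        tracks[[ti]] <- rbind(tracks[[ti]],
                              data.frame(frame = f, x_um = d$x_um[j],
                                         y_um = d$y_um[j]))
        last[[ti]] <- c(d$x_um[j], d$y_um[j])
        age[ti] <- 0L
      } else {
        age[ti] <- age[ti] + 1L
      }
    }
    for (j in setdiff(seq_len(nrow(d)), taken)) {
      tracks[[length(tracks) + 1]] <-
        data.frame(frame = f, x_um = d$x_um[j], y_um = d$y_um[j])
      last[[length(last) + 1]] <- c(d$x_um[j], d$y_um[j])
      age <- c(age, 0L)
    }
  }
  tracks
}

# canonical fingerprint of a set of tracks for comparison across
# implementations (order- and id-independent)
canonical_tracks <- function(df) {
  pieces <- lapply(split(df[, c("frame", "x_um", "y_um")], df$track_id),
                   function(tr) {
                     tr <- tr[order(tr$frame), ]
                     paste(sprintf("%d:%.6f:%.6f", tr$frame, tr$x_um,
                                   tr$y_um), collapse = "|")
                   })
  sort(unlist(pieces, use.names = FALSE))
}

canonical_track_list <- function(lst) {
  sort(vapply(lst, function(tr) {
    tr <- tr[order(tr$frame), ]
    paste(sprintf("%d:%.6f:%.6f", tr$frame, tr$x_um, tr$y_um),
          collapse = "|")
  }, character(1)))
}

# Brute-force run/trap segmentation: threshold pass, then repeatedly
# rescan all successive trap-episode pairs from scratch, merging one pair
# at a time, until nothing changes. Iteration order deliberately differs
# from the implementation.
oracle_segment <- function(traj, params) {
  n <- nrow(traj)
  w <- params$window
  v <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - w)
    hi <- min(n, i + w)
    v[i] <- sqrt((traj$x_um[hi] - traj$x_um[lo])^2 +
                 (traj$y_um[hi] - traj$y_um[lo])^2) /
      (traj$t_s[hi] - traj$t_s[lo])
  }
  phase <- ifelse(v < params$speed_threshold, "trap", "run")
  repeat {
    eps <- list()
    i <- 1
    while (i <= n) {
      if (phase[i] == "trap") {
        j <- i
        while (j < n && phase[j + 1] == "trap") j <- j + 1
        eps[[length(eps) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    changed <- FALSE
    if (length(eps) >= 2) {
      for (k in rev(seq_len(length(eps) - 1))) {  # scan back to front
        a <- eps[[k]]
        b <- eps[[k + 1]]
        gd <- sqrt((traj$x_um[b[1]] - traj$x_um[a[2]])^2 +
                   (traj$y_um[b[1]] - traj$y_um[a[2]])^2)
        if (gd < params$merge_distance) {
          seg <- (a[2] + 1):(b[1] - 1)
          if (any(phase[seg] == "run")) {
            phase[seg] <- "trap"
            changed <- TRUE
            break
          }
        }
      }
    }
    if (!changed) break
  }
  phase
}
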