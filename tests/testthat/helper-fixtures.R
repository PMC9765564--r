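# trajectory fixtures built in code

# straight constant-velocity trajectory
make_const_track <- function(v, duration = 5, dt = 0.05, id = 1L,
                             angle = 0, x0 = 0, y0 = 0) {
  t <- seq(0, duration, by = dt)
  data.frame(track_id = id, frame = seq_along(t) - 1L, t_s = t,
             x_um = x0 + v * t * cos(angle),
             y_um = y0 + v * t * sin(angle))
}

# random wiggly trajectory mixing slow and fast stretches, n points
make_random_track <- function(n, dt = 0.05, id = 1L) {
  n_seg <- max(1, rpois(1, 3))
  lens <- diff(round(seq(0, n - 1, length.out = n_seg + 1)))
  lens[length(lens)] <- (n - 1) - sum(lens[-length(lens)])
  vx <- vy <- numeric(0)
  for (l in lens) {
    if (l <= 0) next
    speed <- sample(c(runif(1, 0, 4), runif(1, 10, 40)), 1)
    ang <- runif(1, 0, 2 * pi)
    vx <- c(vx, rep(speed * cos(ang), l) + rnorm(l, 0, 0.5))
    vy <- c(vy, rep(speed * sin(ang), l) + rnorm(l, 0, 0.5))
  }
  data.frame(track_id = id, frame = 0:(n - 1), t_s = (0:(n - 1)) * dt,
             x_um = cumsum(c(0, vx * dt)), y_um = cumsum(c(0, vy * dt)))
}

# random multi-particle detection instance: k particles, nf frames,
# small per-frame displacements so crossings occur
make_random_instance <- function(k, nf, max_step = 2, box = 20) {
  x <- runif(k, 0, box)
  y <- runif(k, 0, box)
  out <- list()
  for (f in seq_len(nf)) {
    out[[f]] <- data.frame(frame = f - 1L, x_um = x, y_um = y)
    ang <- runif(k, 0, 2 * pi)
    st <- runif(k, 0, max_step)
    x <- x + st * cos(ang)
    y <- y + st * sin(ang)
  }
  do.call(rbind, out)
}
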