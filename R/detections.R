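#' Render per-frame detections from ground-truth paths
#'
#' Emulates centroid detection in phase-contrast movies: at every frame each
#' swimmer inside the field of view is detected with probability
#' \code{p_detect} at its true position plus isotropic Gaussian localisation
#' noise, and a Poisson number of false-positive detections (mean
#' \code{fp_per_frame}) is placed uniformly in the field of view.
#'
#' @param paths A \code{swimmer_population} (or list of
#'   \code{swimmer_path}) on a common frame grid.
#' @param sigma_loc Localisation noise, um (standard deviation per axis).
#' @param p_detect Per-frame detection probability in [0, 1].
#' @param fp_per_frame Expected false positives per frame.
#' @param fov Field of view as \code{c(xmin, xmax, ymin, ymax)} in um.
#' @param seed Optional integer seed.
#' @param offsets Optional n x 2 matrix of per-path spatial offsets (um)
#'   applied before rendering, e.g. to lay swimmers out on a grid.
#' @return A \code{data.frame} with columns \code{frame}, \code{x_um},
#'   \code{y_um}, ordered by frame.
#' @export
render_detections <- function(paths, sigma_loc = 0, p_detect = 1,
                              fp_per_frame = 0,
                              fov = c(-500, 500, -500, 500), seed = NULL,
                              offsets = NULL) {
  if (sigma_loc < 0) stop("sigma_loc must be >= 0")
  if (p_detect < 0 || p_detect > 1) stop("p_detect must be in [0, 1]")
  fov <- as.numeric(fov)
  if (length(fov) != 4 || fov[1] >= fov[2] || fov[3] >= fov[4])
    stop("fov must be c(xmin, xmax, ymin, ymax) with positive extent")
  if (!is.null(seed)) set.seed(seed)
  paths <- unclass(paths)
  if (length(paths) == 0) {
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0)))
  }
  nf <- length(paths[[1]]$times)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    xs <- vapply(paths, function(p) p$x[f], numeric(1))
    ys <- vapply(paths, function(p) p$y[f], numeric(1))
    if (!is.null(offsets)) {
      xs <- xs + offsets[, 1]
      ys <- ys + offsets[, 2]
    }
    inview <- xs >= fov[1] & xs <= fov[2] & ys >= fov[3] & ys <= fov[4]
    seen <- inview & stats::runif(length(xs)) < p_detect
    dx <- xs[seen] + stats::rnorm(sum(seen), 0, sigma_loc)
    dy <- ys[seen] + stats::rnorm(sum(seen), 0, sigma_loc)
    nfp <- stats::rpois(1, fp_per_frame)
    if (nfp > 0) {
      dx <- c(dx, stats::runif(nfp, fov[1], fov[2]))
      dy <- c(dy, stats::runif(nfp, fov[3], fov[4]))
    }
    if (length(dx) > 0)
      out[[f]] <- data.frame(frame = f - 1L, x_um = dx, y_um = dy)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0))
  rownames(res) <- NULL
  res
}
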