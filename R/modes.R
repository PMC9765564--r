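#' Tabulate swimming-mode frequencies
#'
#' Counts and fractions of the three run modes (push, pull, wrapped) from a
#' vector of per-run mode labels, the CW fraction (pull + wrapped, i.e.
#' runs with clockwise flagellar rotation), and exact Clopper-Pearson
#' binomial confidence intervals for each fraction.
#'
#' @param run_labels Character vector of labels in
#'   \{\code{push}, \code{pull}, \code{wrapped}\}; nonempty.
#' @param conf_level Confidence level for the intervals.
#' @return Object of class \code{mode_table}: list with \code{counts},
#'   \code{fractions}, \code{ci} (matrix mode x (lower, upper)),
#'   \code{cw_fraction}, \code{n}.
#' @export
tabulate_modes <- function(run_labels, conf_level = 0.95) {
  if (length(run_labels) == 0) stop("no run labels")
  run_labels <- as.character(run_labels)
  bad <- setdiff(unique(run_labels), c("push", "pull", "wrapped"))
  if (length(bad))
    stop("unknown mode label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(run_labels, levels = c("push", "pull", "wrapped")))
  n <- sum(counts)
  fractions <- as.numeric(counts) / n
  names(fractions) <- names(counts)
  ci <- t(vapply(as.numeric(counts), function(k)
    stats::binom.test(k, n, conf.level = conf_level)$conf.int,
    numeric(2)))
  dimnames(ci) <- list(names(counts), c("lower", "upper"))
  structure(list(counts = as.numeric(counts) |>
                   stats::setNames(names(counts)),
                 fractions = fractions, ci = ci,
                 cw_fraction = unname(fractions["pull"] +
                                      fractions["wrapped"]),
                 n = as.integer(n)),
            class = "mode_table")
}

#' @export
print.mode_table <- function(x, ...) {
  cat(sprintf("<mode_table> n = %d runs: push %.1f%%, pull %.1f%%, wrapped %.1f%% (CW %.1f%%)\n",
              x$n, 100 * x$fractions["push"], 100 * x$fractions["pull"],
              100 * x$fractions["wrapped"], 100 * x$cw_fraction))
  invisible(x)
}

#' Split of CW runs into pull and wrapped
#'
#' Conditional fractions of the two CW modes among CW runs.
#'
#' @param table A \code{\link{mode_table}}.
#' @return Named numeric \code{c(pull = , wrapped = )} summing to 1.
#' @export
cw_mode_split <- function(table) {
  stopifnot(inherits(table, "mode_table"))
  cw <- table$counts["pull"] + table$counts["wrapped"]
  if (cw == 0) stop("no CW runs; pull/wrapped split is undefined")
  c(pull = unname(table$counts["pull"] / cw),
    wrapped = unname(table$counts["wrapped"] / cw))
}

#' Ground-truth run-mode labels of a simulated population
#'
#' Extracts one mode label per run episode from the generator's
#' ground-truth annotations (a run episode is a maximal block of
#' consecutive non-stop, non-trap timepoints in one mode).
#'
#' @param pop A \code{swimmer_population}.
#' @return Character vector of labels in \{push, pull, wrapped\}.
#' @export
true_run_modes <- function(pop) {
  unlist(lapply(unclass(pop), function(p) {
    m <- p$mode
    m[p$phase == "trap"] <- "trap"
    r <- rle(m)
    r$values[r$values %in% c("push", "pull", "wrapped")]
  }))
}
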