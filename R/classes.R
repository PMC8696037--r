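#' @keywords internal
"_PACKAGE"

## Core S3 containers shared across modules. All coordinates are in
## micrometers (retina frame, y up), times in seconds, densities in
## cells/mm^2, IPL depth in percent (0% = GCL border, 100% = INL border).

#' Construct a planar point pattern
#'
#' A `point_pattern` holds cell coordinates (micrometers) inside an
#' axis-aligned observation window, the basis of all mosaic statistics.
#'
#' @param x,y Numeric vectors of equal length, coordinates in um.
#' @param window Numeric vector `c(x0, y0, x1, y1)` in um.
#' @param label Free-text label for the cell class.
#' @param ground_truth Optional `ground_truth` record of generator
#'   parameters (attached automatically by the synthetic generators).
#' @return An object of class `point_pattern` with fields `x`, `y`,
#'   `window`, `label`.
#' @examples
#' p <- point_pattern(c(0, 10), c(0, 0), window = c(-5, -5, 15, 5))
#' npoints(p)
#' @export
point_pattern <- function(x, y, window, label = "", ground_truth = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  window <- as.numeric(window)
  if (length(window) != 4L) stop("window must be c(x0, y0, x1, y1)")
  if (window[3] <= window[1] || window[4] <= window[2])
    stop("window must have positive area")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  if (length(x) > 0L) {
    inside <- x >= window[1] & x <= window[3] & y >= window[2] & y <= window[4]
    if (!all(inside))
      stop(sprintf("%d point(s) fall outside the window", sum(!inside)))
    if (anyDuplicated(round(cbind(x, y), 6L)))
      stop("duplicate coordinates (tolerance 1e-6 um)")
  }
  structure(list(x = x, y = y, window = window, label = label,
                 ground_truth = ground_truth),
            class = "point_pattern")
}

#' Number of points in a pattern
#' @param p A `point_pattern`.
#' @return Integer point count.
#' @export
npoints <- function(p) length(p$x)

#' Window area in square millimeters
#' @param p A `point_pattern`.
#' @return Area in mm^2.
#' @export
window_area_mm2 <- function(p) {
  w <- p$window
  (w[3] - w[1]) * (w[4] - w[2]) / 1e6
}

#' @export
print.point_pattern <- function(x, ...) {
  w <- x$window
  cat(sprintf("point_pattern: %d points%s\n", npoints(x),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  window: [%g, %g] x [%g, %g] um (%.3f mm^2)\n",
              w[1], w[3], w[2], w[4], window_area_mm2(x)))
  invisible(x)
}

#' Construct a spike train
#'
#' Timestamped action potentials within a recording window.
#'
#' @param spikes Numeric vector of spike times (s), strictly increasing.
#' @param t0,t1 Recording window bounds (s).
#' @param ground_truth Optional generator record.
#' @return Object of class `spike_train` with fields `spikes`, `t0`, `t1`.
#' @export
spike_train <- function(spikes, t0 = 0, t1 = NULL, ground_truth = NULL) {
  spikes <- as.numeric(spikes)
  if (is.null(t1)) t1 <- if (length(spikes)) max(spikes) else t0
  if (length(spikes)) {
    if (any(diff(spikes) <= 0)) stop("spike times must be strictly increasing")
    if (spikes[1] < t0 || spikes[length(spikes)] > t1)
      stop("spike times must lie within [t0, t1]")
  }
  structure(list(spikes = spikes, t0 = t0, t1 = t1,
                 ground_truth = ground_truth),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes in [%g, %g] s\n",
              length(x$spikes), x$t0, x$t1))
  invisible(x)
}

#' Construct a stimulus trial
#'
#' A spike train aligned to a stimulus epoch description.
#'
#' @param train A `spike_train`.
#' @param condition Named list describing the stimulus, e.g.
#'   `list(kind = "flash", diameter_um = 300)`,
#'   `list(kind = "grating", direction_deg = 90)`, or
#'   `list(kind = "current_step", current_pA = 100)`.
#' @param epochs Named list of `c(start, end)` intervals (s); flashes use
#'   `baseline`, `stim_on`, `stim_off`.
#' @return Object of class `stimulus_trial`.
#' @export
stimulus_trial <- function(train, condition, epochs) {
  stopifnot(inherits(train, "spike_train"), is.list(condition), is.list(epochs))
  for (e in epochs) {
    if (length(e) != 2L || e[2] < e[1]) stop("each epoch must be c(start, end)")
    if (e[1] < train$t0 - 1e-9 || e[2] > train$t1 + 1e-9)
      stop("epochs must lie within the recording window")
  }
  structure(list(train = train, condition = condition, epochs = epochs),
            class = "stimulus_trial")
}

#' Count spikes in a time window
#' @param train A `spike_train`.
#' @param window `c(start, end)` in seconds; half-open `[start, end)`.
#' @return Integer count.
#' @export
count_spikes <- function(train, window) {
  sum(train$spikes >= window[1] & train$spikes < window[2])
}

#' Generator ground-truth record
#'
#' Every synthetic artifact carries the parameters and seed that made it,
#' so downstream recovery tests can compare against known truth.
#'
#' @param kind One of `"mosaic"`, `"train"`, `"morphology"`, `"section"`.
#' @param params Named list of generator parameters.
#' @param seed Integer seed used.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(kind, params, seed) {
  kind <- match.arg(kind, c("mosaic", "train", "morphology", "section"))
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "ground_truth")
}

## internal: run expr under a local RNG seed without touching global state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
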