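## Mosaic spatial statistics: nearest-neighbor distances, the
## regularity index, the density recovery profile (DRP) and its
## polynomial summary fit, and coarse density maps.

#' Nearest-neighbor distance statistics
#'
#' For each cell, the Euclidean distance to its closest neighbor, with
#' the summary fields the regularity index is built from.
#'
#' @param pattern A [point_pattern] with at least two points.
#' @return Object of class `nnd_stats`: `nnd` (um, one per point),
#'   `mean_nnd`, `sd_nnd`, `sem_nnd` (= sd/sqrt(n)), `n`.
#' @examples
#' p <- point_pattern(c(0, 10), c(0, 0), c(-5, -5, 15, 5))
#' compute_nnd(p)$mean_nnd  # 10
#' @export
compute_nnd <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- npoints(pattern)
  if (n < 2L) stop("nearest-neighbor distances undefined for n < 2")
  d <- as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
  diag(d) <- Inf
  nnd <- apply(d, 1L, min)
  structure(list(nnd = as.numeric(nnd),
                 mean_nnd = mean(nnd),
                 sd_nnd = stats::sd(nnd),
                 sem_nnd = stats::sd(nnd) / sqrt(n),
                 n = n),
            class = "nnd_stats")
}

#' Mosaic regularity index
#'
#' Mean nearest-neighbor distance divided by its dispersion. The
#' default denominator is the standard error of the mean (`"sem"`); the
#' conventional mosaic-literature variant divides by the standard
#' deviation (`"sd"`). The two differ by a factor sqrt(n), so SEM-based
#' values are not comparable across sample sizes -- the mode is always
#' recorded in the result.
#'
#' @param stats An `nnd_stats` from [compute_nnd] (or a [point_pattern],
#'   which is reduced first).
#' @param denominator_mode `"sem"` (default) or `"sd"`.
#' @return Object of class `regularity_result`: `ri`,
#'   `denominator_mode`, `mean_nnd`, `n`, and logical `infinite` set
#'   when the pattern has zero NND dispersion (perfect lattice).
#' @export
regularity_index <- function(stats, denominator_mode = c("sem", "sd")) {
  denominator_mode <- match.arg(denominator_mode)
  if (inherits(stats, "point_pattern")) stats <- compute_nnd(stats)
  stopifnot(inherits(stats, "nnd_stats"))
  if (stats$n < 2L) stop("regularity index undefined for n < 2")
  denom <- switch(denominator_mode, sem = stats$sem_nnd, sd = stats$sd_nnd)
  # dispersion at the float-rounding level (perfect lattice) is zero
  inf <- !is.finite(denom) || denom <= 1e-12 * stats$mean_nnd
  structure(list(ri = if (inf) Inf else stats$mean_nnd / denom,
                 denominator_mode = denominator_mode,
                 mean_nnd = stats$mean_nnd, n = stats$n,
                 infinite = inf),
            class = "regularity_result")
}

#' @export
print.regularity_result <- function(x, ...) {
  cat(sprintf("regularity index (%s mode): %s  [mean NND %.2f um, n = %d]\n",
              x$denominator_mode,
              if (x$infinite) "infinite (zero dispersion)" else sprintf("%.3f", x$ri),
              x$mean_nnd, x$n))
  invisible(x)
}

#' Density recovery profile
#'
#' Around each reference cell, neighbors are counted in concentric
#' annuli `[r, r + dr)` and divided by the annulus area, then averaged
#' over reference cells: `p(r) = N(r + dr) / A(r + dr)`, in cells/mm^2.
#' A flat profile at the global density indicates spatial randomness; a
#' depression near r = 0 (an exclusion zone) indicates a regular mosaic.
#'
#' @param pattern A [point_pattern].
#' @param dr Annulus width in um (default 10).
#' @param r_max Outer radius in um (default 300).
#' @param edge_policy `"buffer"` (default: only cells at least `r_max`
#'   from every window edge serve as reference points, so annuli are
#'   never clipped) or `"none"` (all cells are reference points; outer
#'   annuli are underestimated near edges).
#' @return Object of class `drp`: `radii` (inner edges, um), `dr`,
#'   `r_mid`, `density` (cells/mm^2 per annulus), `per_point_counts`
#'   (reference x annulus count matrix), `global_density`, `n_ref`.
#' @export
density_recovery_profile <- function(pattern, dr = 10, r_max = 300,
                                     edge_policy = c("buffer", "none")) {
  stopifnot(inherits(pattern, "point_pattern"))
  edge_policy <- match.arg(edge_policy)
  if (dr <= 0) stop("dr must be > 0")
  if (r_max < dr) stop("r_max must be >= dr")
  n <- npoints(pattern)
  if (n < 2L) stop("DRP undefined for n < 2")
  w <- pattern$window
  if (edge_policy == "buffer") {
    short <- min(w[3] - w[1], w[4] - w[2])
    if (r_max > short / 2)
      stop(sprintf("r_max = %g um exceeds half the window's short side; usable r_max <= %g um",
                   r_max, short / 2))
    ref <- which(pattern$x >= w[1] + r_max & pattern$x <= w[3] - r_max &
                 pattern$y >= w[2] + r_max & pattern$y <= w[4] - r_max)
    if (!length(ref))
      stop("buffer edge policy leaves no reference points; reduce r_max")
  } else {
    ref <- seq_len(n)
  }
  radii <- seq(0, r_max - dr, by = dr)
  n_ann <- length(radii)
  counts <- matrix(0L, nrow = length(ref), ncol = n_ann)
  for (i in seq_along(ref)) {
    dx <- pattern$x - pattern$x[ref[i]]
    dy <- pattern$y - pattern$y[ref[i]]
    d <- sqrt(dx * dx + dy * dy)
    d <- d[-ref[i]]
    idx <- floor(d / dr) + 1L
    keep <- idx >= 1L & idx <= n_ann
    counts[i, ] <- tabulate(idx[keep], nbins = n_ann)
  }
  ann_area_mm2 <- pi * ((radii + dr)^2 - radii^2) / 1e6
  density <- colMeans(counts) / ann_area_mm2
  structure(list(radii = radii, dr = dr, r_mid = radii + dr / 2,
                 density = density, per_point_counts = counts,
                 global_density = n / window_area_mm2(pattern),
                 n_ref = length(ref), edge_policy = edge_policy,
                 fit_coeffs = NULL, ci99 = NULL, fit = NULL),
            class = "drp")
}

#' Polynomial summary fit and bootstrap confidence band for a DRP
#'
#' Least-squares polynomial (7th order by default) of mean density on
#' annulus midpoint, plus a per-annulus 99% confidence interval from
#' bootstrap resampling of the reference cells.
#'
#' @param drp A `drp` from [density_recovery_profile].
#' @param order Polynomial order (default 7).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return The `drp` with `fit_coeffs` (intercept first), `fit` (fitted
#'   density at each midpoint), and `ci99` (2 x annuli matrix) filled.
#' @export
fit_drp_curve <- function(drp, order = 7L, n_boot = 1000L, seed) {
  stopifnot(inherits(drp, "drp"))
  n_ann <- length(drp$radii)
  if (n_ann < order + 2L)
    stop(sprintf("need at least %d annuli for an order-%d fit; have %d (use a lower order)",
                 order + 2L, order, n_ann))
  X <- outer(drp$r_mid, 0:order, `^`)
  qr_X <- qr(X)
  drp$fit_coeffs <- as.numeric(qr.coef(qr_X, drp$density))
  drp$fit <- as.numeric(X %*% drp$fit_coeffs)
  ann_area_mm2 <- pi * ((drp$radii + drp$dr)^2 - drp$radii^2) / 1e6
  n_ref <- nrow(drp$per_point_counts)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_ref, n_ref, replace = TRUE)
      colMeans(drp$per_point_counts[idx, , drop = FALSE]) / ann_area_mm2
    }, numeric(n_ann))
  })
  drp$ci99 <- apply(boot, 1L, stats::quantile, probs = c(0.005, 0.995))
  drp
}

#' @export
print.drp <- function(x, ...) {
  cat(sprintf("density recovery profile: %d annuli of %g um up to %g um\n",
              length(x$radii), x$dr, max(x$radii) + x$dr))
  cat(sprintf("  %d reference points (%s edge policy); global density %.1f cells/mm^2\n",
              x$n_ref, x$edge_policy, x$global_density))
  if (!is.null(x$fit_coeffs))
    cat(sprintf("  order-%d polynomial fit and 99%% bootstrap CI attached\n",
                length(x$fit_coeffs) - 1L))
  invisible(x)
}

#' Coarse normalized density map
#'
#' 2-D histogram of cell counts on a square grid, normalized so the
#' densest bin reads 100%.
#'
#' @param pattern A non-empty [point_pattern].
#' @param bin Bin side length in um.
#' @return List with `counts` (matrix, rows = y bins), `percent`
#'   (counts / max * 100), `x_breaks`, `y_breaks`.
#' @export
density_map <- function(pattern, bin) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (bin <= 0) stop("bin must be > 0")
  if (npoints(pattern) == 0L) stop("cannot map an empty pattern")
  w <- pattern$window
  xb <- seq(w[1], w[3] + bin, by = bin)
  yb <- seq(w[2], w[4] + bin, by = bin)
  ix <- findInterval(pattern$x, xb, rightmost.closed = FALSE)
  iy <- findInterval(pattern$y, yb, rightmost.closed = FALSE)
  counts <- matrix(0L, nrow = length(yb) - 1L, ncol = length(xb) - 1L)
  for (k in seq_along(ix)) counts[iy[k], ix[k]] <- counts[iy[k], ix[k]] + 1L
  list(counts = counts, percent = counts / max(counts) * 100,
       x_breaks = xb, y_breaks = yb)
}
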