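## Straightening of curved retinal cross-sections into a rectangular
## IPL frame via a bilinearly blended Coons patch, and extraction of
## normalized depth profiles.

#' Construct a multi-channel section image
#'
#' @param channels Named list of numeric matrices (rows = image y,
#'   increasing toward the INL side; columns = position along the
#'   layer). All channels must share one shape.
#' @param pixel_size Pixel size in um/px (> 0).
#' @param channel_roles Named character vector mapping channel name to
#'   `"nuclear"`, `"marker"`, or `"cell_fill"`.
#' @return Object of class `section_image`.
#' @export
section_image <- function(channels, pixel_size = 1, channel_roles = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a named list of matrices")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) stop("all channels must share one shape")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.null(channel_roles)) {
    bad <- setdiff(channel_roles, c("nuclear", "marker", "cell_fill"))
    if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 channel_roles = channel_roles),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("section_image: %d channel(s) [%s], %d x %d px at %g um/px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Construct IPL boundary curves
#'
#' Single-valued curves (row position as a function of column) for the
#' GCL/IPL border (`top`) and the IPL/INL border (`bottom`), sampled at
#' every column of a shared domain. Crossing curves are rejected.
#'
#' @param top,bottom Numeric vectors of equal length (row positions, px).
#' @param domain `c(first, last)` column indices the curves cover.
#' @return Object of class `boundary_curves`.
#' @export
boundary_curves <- function(top, bottom, domain = c(1L, length(top))) {
  top <- as.numeric(top); bottom <- as.numeric(bottom)
  if (length(top) != length(bottom)) stop("top and bottom must share a domain")
  sgn <- sign(bottom - top)
  if (any(sgn == 0) || length(unique(sgn)) != 1L)
    stop("boundary curves must not cross or touch")
  structure(list(top = top, bottom = bottom, domain = as.integer(domain)),
            class = "boundary_curves")
}

## internal: Otsu threshold on a 256-bin histogram
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(floor((v - rng[1]) / diff(rng) * 256) + 1L, 1L), 256L),
                nbins = 256L)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(256L) - 0.5) / 256 * diff(rng)
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

## internal: 1-D Gaussian smoothing with renormalized edges
gauss_smooth <- function(v, sigma) {
  if (sigma <= 0) return(v)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    kk <- k[j - i + half + 1L]
    out[i] <- sum(v[j] * kk) / sum(kk)
  }
  out
}

#' Detect IPL boundaries from the nuclear channel
#'
#' Uses the nuclear stain of the ganglion cell layer and inner nuclear
#' layer to delimit the IPL: the image is thresholded (Otsu by default),
#' each column is walked for its first (GCL) and last (INL) nuclear
#' band, and the band edges facing the IPL become the two boundary
#' curves, which are then Gaussian-smoothed. Columns where either band
#' is missing are linearly interpolated if they are no more than 20% of
#' the domain; otherwise the section is rejected as unstraightenable
#' (such sections are discarded, not guessed at).
#'
#' @param section A [section_image].
#' @param nuclear_channel Channel name (default: the channel whose role
#'   is `"nuclear"`).
#' @param smooth_sigma Gaussian SD (px) applied to the detected curves
#'   (default 5).
#' @param threshold_mode `"otsu"` (default) or a numeric threshold.
#' @param min_run Minimum band thickness in px to count as a nuclear
#'   band (default 3).
#' @return A [boundary_curves].
#' @export
detect_boundaries <- function(section, nuclear_channel = NULL,
                              smooth_sigma = 5, threshold_mode = "otsu",
                              min_run = 3L) {
  stopifnot(inherits(section, "section_image"))
  if (is.null(nuclear_channel)) {
    nuclear_channel <- names(section$channel_roles)[
      section$channel_roles == "nuclear"][1]
    if (is.na(nuclear_channel) || is.null(nuclear_channel))
      stop("no channel with role 'nuclear'; name one explicitly")
  }
  img <- section$channels[[nuclear_channel]]
  if (is.null(img)) stop("nuclear channel '", nuclear_channel, "' not found")
  if (all(img == 0)) stop("nuclear channel is blank; cannot detect boundaries")
  thr <- if (identical(threshold_mode, "otsu")) otsu_threshold(as.numeric(img))
         else as.numeric(threshold_mode)
  mask <- img > thr
  width <- ncol(img)
  top <- bottom <- rep(NA_real_, width)
  for (j in seq_len(width)) {
    r <- rle(mask[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_run)
    if (length(runs) >= 2L) {
      top[j] <- ends[runs[1]] + 0.5          # inner (IPL-facing) edge of GCL band
      bottom[j] <- starts[runs[length(runs)]] - 0.5  # inner edge of INL band
    }
  }
  bad <- is.na(top) | is.na(bottom) | (bottom - top <= 0)
  if (mean(bad) > 0.2)
    stop(sprintf("boundary detection failed in %.0f%% of columns (> 20%%); section discarded",
                 100 * mean(bad)))
  if (any(bad)) {
    ok <- which(!bad)
    top <- stats::approx(ok, top[ok], xout = seq_len(width), rule = 2)$y
    bottom <- stats::approx(ok, bottom[ok], xout = seq_len(width), rule = 2)$y
  }
  boundary_curves(gauss_smooth(top, smooth_sigma),
                  gauss_smooth(bottom, smooth_sigma))
}

#' Straighten a section with a bilinearly blended Coons patch
#'
#' Maps the curved IPL strip onto a rectangular grid (s = position along
#' the layer, t = normalized depth). The Coons patch interpolates the
#' two detected boundary curves and the straight lateral segments
#' joining their endpoints:
#' `S(s,t) = (1-t) c0(s) + t c1(s) + (1-s) d0(t) + s d1(t) - B(s,t)`,
#' where `B` is the bilinear interpolant of the four corners. Every
#' channel is resampled identically by bilinear interpolation; samples
#' falling outside the raster are zero-filled and counted.
#'
#' @param section A [section_image].
#' @param curves A [boundary_curves] on the section's column domain.
#' @param out_rows Number of depth rows in the output (default 100,
#'   i.e. 1% of IPL depth per row).
#' @return Object of class `straightened_section`: `channels` on the
#'   rectangular grid (row 1 = 0% depth at the GCL border, last row =
#'   100% at the INL border), `depth_resolution` (% per row), and
#'   attribute `oob_count` (zero-filled samples).
#' @export
coons_straighten <- function(section, curves, out_rows = 100L) {
  stopifnot(inherits(section, "section_image"),
            inherits(curves, "boundary_curves"))
  width <- ncol(section$channels[[1]])
  if (length(curves$top) != width)
    stop("curves must be sampled at every column of the section")
  out_cols <- width
  s <- (seq_len(out_cols) - 1) / (out_cols - 1)
  t <- (seq_len(out_rows) - 0.5) / out_rows      # bin centers in [0,1]
  xs <- seq_len(width)
  # boundary curves as (x, y); lateral edges straight => their Coons
  # term cancels the corner bilinear exactly, but keep the full form
  c0x <- xs; c0y <- curves$top
  c1x <- xs; c1y <- curves$bottom
  P00 <- c(c0x[1], c0y[1]); P10 <- c(c0x[width], c0y[width])
  P01 <- c(c1x[1], c1y[1]); P11 <- c(c1x[width], c1y[width])
  src_x <- matrix(0, out_rows, out_cols)
  src_y <- matrix(0, out_rows, out_cols)
  for (i in seq_len(out_rows)) {
    ti <- t[i]
    d0 <- (1 - ti) * P00 + ti * P01
    d1 <- (1 - ti) * P10 + ti * P11
    src_x[i, ] <- (1 - ti) * c0x + ti * c1x + (1 - s) * d0[1] + s * d1[1] -
      ((1 - s) * (1 - ti) * P00[1] + s * (1 - ti) * P10[1] +
       (1 - s) * ti * P01[1] + s * ti * P11[1])
    src_y[i, ] <- (1 - ti) * c0y + ti * c1y + (1 - s) * d0[2] + s * d1[2] -
      ((1 - s) * (1 - ti) * P00[2] + s * (1 - ti) * P10[2] +
       (1 - s) * ti * P01[2] + s * ti * P11[2])
  }
  oob <- 0L
  out_channels <- lapply(section$channels, function(ch) {
    res <- bilinear_sample(ch, src_y, src_x)
    oob <<- oob + attr(res, "oob")
    res
  })
  structure(list(channels = out_channels,
                 depth_resolution = 100 / out_rows,
                 pixel_size = section$pixel_size),
            class = "straightened_section", oob_count = oob)
}

## internal: bilinear interpolation of matrix `img` at real (row, col)
## positions; out-of-bounds -> 0, with the count attached
bilinear_sample <- function(img, rr, cc) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  get_px <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    list(v = v, ok = ok)
  }
  p00 <- get_px(r0, c0);     p01 <- get_px(r0, c0 + 1)
  p10 <- get_px(r0 + 1, c0); p11 <- get_px(r0 + 1, c0 + 1)
  v <- (1 - fr) * (1 - fc) * p00$v + (1 - fr) * fc * p01$v +
       fr * (1 - fc) * p10$v + fr * fc * p11$v
  fully_oob <- !(p00$ok | p01$ok | p10$ok | p11$ok)
  out <- matrix(v, nrow(rr), ncol(rr))
  attr(out, "oob") <- sum(fully_oob)
  out
}

#' Construct a stratification profile
#'
#' Normalized signal (intensity or dendritic length) as a function of
#' IPL depth, with the S1-S5 stratum scheme attached. On this depth
#' axis 0% is the GCL border and 100% the INL border, so the ON strata
#' S5 and S4 occupy [0,20) and [20,40)%, S3 [40,60)%, and the OFF
#' strata S2 and S1 occupy [60,80) and [80,100]%.
#'
#' @param depth_bins Bin centers in percent depth, covering (0, 100).
#' @param signal Non-negative signal per bin; normalized to peak 1.
#' @param mass Optional unnormalized per-bin mass (e.g. dendritic
#'   length in um) retained for conservation checks.
#' @return Object of class `stratification_profile` with `depth_bins`,
#'   `signal`, `layer_scheme` (data.frame layer/lo/hi), and `mass`.
#' @export
stratification_profile <- function(depth_bins, signal, mass = NULL) {
  signal <- as.numeric(signal)
  if (any(signal < 0)) stop("signal must be non-negative")
  if (all(signal == 0)) stop("signal is identically zero")
  structure(list(depth_bins = as.numeric(depth_bins),
                 signal = signal / max(signal),
                 layer_scheme = default_layer_scheme(),
                 mass = mass),
            class = "stratification_profile")
}

#' Default S1-S5 stratum edges
#'
#' Equal quintiles of IPL depth. With 0% at the GCL border, S5 (ON,
#' innermost) comes first and S1 (OFF, next to the INL) last.
#' @return data.frame with columns `layer`, `lo`, `hi` (percent).
#' @export
default_layer_scheme <- function() {
  data.frame(layer = c("S5", "S4", "S3", "S2", "S1"),
             lo = c(0, 20, 40, 60, 80),
             hi = c(20, 40, 60, 80, 100))
}

#' Depth profile of a straightened channel
#'
#' Mean intensity per depth row, normalized to peak 1.
#'
#' @param straight A `straightened_section` from [coons_straighten].
#' @param channel Channel name.
#' @return A [stratification_profile].
#' @export
depth_profile <- function(straight, channel) {
  stopifnot(inherits(straight, "straightened_section"))
  ch <- straight$channels[[channel]]
  if (is.null(ch)) stop("channel '", channel, "' not found")
  if (all(ch == 0)) stop("channel '", channel, "' is all zero")
  m <- rowMeans(ch)
  nr <- nrow(ch)
  stratification_profile(depth_bins = (seq_len(nr) - 0.5) / nr * 100,
                         signal = m, mass = m)
}

#' @export
print.stratification_profile <- function(x, ...) {
  pk <- x$depth_bins[which.max(x$signal)]
  cat(sprintf("stratification_profile: %d bins, peak at %.1f%% IPL depth\n",
              length(x$depth_bins), pk))
  invisible(x)
}
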