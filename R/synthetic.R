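## Synthetic-data generators. Each is a pure function of its parameters
## and a mandatory seed (no hidden global RNG state), and every artifact
## carries a ground_truth record for parameter-recovery tests.

#' Generate a homogeneous Poisson (random) cell mosaic
#'
#' The null model against which mosaic regularity is judged: complete
#' spatial randomness at a given intensity.
#'
#' @param density Intensity in cells/mm^2 (> 0).
#' @param window Observation window `c(x0, y0, x1, y1)` in um.
#' @param seed Integer seed.
#' @param label Pattern label.
#' @return A [point_pattern] whose count is Poisson(density x area) and
#'   whose coordinates are uniform in the window.
#' @examples
#' p <- gen_poisson_pattern(100, c(0, 0, 2000, 2000), seed = 1)
#' @export
gen_poisson_pattern <- function(density, window, seed, label = "poisson") {
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  window <- as.numeric(window)
  area_mm2 <- (window[3] - window[1]) * (window[4] - window[2]) / 1e6
  if (!is.finite(area_mm2) || area_mm2 <= 0) stop("window area must be > 0")
  with_seed(seed, {
    n <- stats::rpois(1L, density * area_mm2)
    x <- stats::runif(n, window[1], window[3])
    y <- stats::runif(n, window[2], window[4])
    point_pattern(x, y, window, label = label,
                  ground_truth = ground_truth("mosaic",
                    list(model = "poisson", density = density), seed))
  })
}

#' Generate a hard-core (regular) cell mosaic by dart throwing
#'
#' Rejection sampling that guarantees every pairwise distance is at least
#' `dmin`, the idealization of a regular retinal mosaic with an exclusion
#' zone. Infeasible packings fail explicitly rather than silently
#' returning fewer cells.
#'
#' @param density Target intensity in cells/mm^2.
#' @param dmin Minimum pairwise distance in um (>= 0).
#' @param window Window `c(x0, y0, x1, y1)` in um.
#' @param seed Integer seed.
#' @param max_attempts Total proposal budget (default `5000 * n`).
#' @param label Pattern label.
#' @return A [point_pattern] with exactly `round(density x area)` points.
#' @export
gen_hardcore_pattern <- function(density, dmin, window, seed,
                                 max_attempts = NULL, label = "hardcore") {
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (!is.numeric(dmin) || dmin < 0) stop("dmin must be >= 0")
  window <- as.numeric(window)
  area_mm2 <- (window[3] - window[1]) * (window[4] - window[2]) / 1e6
  if (area_mm2 <= 0) stop("window area must be > 0")
  n <- max(1L, as.integer(round(density * area_mm2)))
  if (dmin > 0) {
    # hexagonal packing bound: 2/(sqrt(3) dmin^2) points per um^2
    max_density_mm2 <- 2 / (sqrt(3) * dmin^2) * 1e6
    if (density > max_density_mm2)
      stop(sprintf(
        "density %.1f/mm^2 exceeds the hexagonal packing bound %.1f/mm^2 for dmin = %g um",
        density, max_density_mm2, dmin))
  }
  if (is.null(max_attempts)) max_attempts <- 5000L * n
  with_seed(seed, {
    px <- numeric(n); py <- numeric(n); k <- 0L; attempts <- 0L
    while (k < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      cx <- stats::runif(1, window[1], window[3])
      cy <- stats::runif(1, window[2], window[4])
      if (k == 0L || all((px[seq_len(k)] - cx)^2 + (py[seq_len(k)] - cy)^2 >= dmin^2)) {
        k <- k + 1L; px[k] <- cx; py[k] <- cy
      }
    }
    if (k < n)
      stop(sprintf(
        "hard-core packing infeasible: placed %d/%d points (achieved density %.1f/mm^2) after %d attempts",
        k, n, k / area_mm2, attempts))
    point_pattern(px, py, window, label = label,
                  ground_truth = ground_truth("mosaic",
                    list(model = "hardcore", density = density, dmin = dmin), seed))
  })
}

#' Generate a jittered hexagonal lattice mosaic
#'
#' High-regularity reference pattern: hexagonal lattice points plus
#' isotropic Gaussian jitter, clipped to the window. Used to order
#' regularity indices against the Poisson null.
#'
#' @param spacing Lattice constant in um (> 0).
#' @param jitter_sd Isotropic Gaussian jitter SD in um (>= 0).
#' @param window Window `c(x0, y0, x1, y1)` in um.
#' @param seed Integer seed.
#' @param label Pattern label.
#' @return A [point_pattern].
#' @export
gen_jittered_lattice <- function(spacing, jitter_sd, window, seed,
                                 label = "lattice") {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (!is.numeric(jitter_sd) || jitter_sd < 0) stop("jitter_sd must be >= 0")
  window <- as.numeric(window)
  dy <- spacing * sqrt(3) / 2
  rows <- seq(window[2], window[4], by = dy)
  with_seed(seed, {
    xs <- ys <- list()
    for (i in seq_along(rows)) {
      off <- if (i %% 2L == 0L) spacing / 2 else 0
      cx <- seq(window[1] + off, window[3], by = spacing)
      xs[[i]] <- cx
      ys[[i]] <- rep(rows[i], length(cx))
    }
    x <- unlist(xs); y <- unlist(ys)
    if (jitter_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, jitter_sd)
      y <- y + stats::rnorm(length(y), 0, jitter_sd)
    }
    keep <- x >= window[1] & x <= window[3] & y >= window[2] & y <= window[4]
    point_pattern(x[keep], y[keep], window, label = label,
                  ground_truth = ground_truth("mosaic",
                    list(model = "jittered_lattice", spacing = spacing,
                         jitter_sd = jitter_sd), seed))
  })
}

#' Generate a spike train with geometrically progressing intervals
#'
#' Inter-spike intervals follow a geometric progression chosen so that
#' the ratio of the last interval to the first equals `isi_ratio`
#' exactly. This pins the ground truth of the firing adaptation index:
#' the literal index is `1 - isi_ratio` by construction.
#'
#' @param n_spikes Number of spikes (>= 3; the adaptation index needs
#'   first and last intervals).
#' @param first_isi First inter-spike interval in seconds (> 0).
#' @param isi_ratio Target `T_last / T_initial` (> 0); 1 gives a
#'   perfectly regular train.
#' @param seed Integer seed (used only when `jitter_sd > 0`).
#' @param jitter_sd Optional Gaussian jitter SD (s) on interior spike
#'   times; 0 (default) keeps the ratio exact.
#' @return A [spike_train] starting at t = 0.
#' @export
gen_spike_train <- function(n_spikes, first_isi, isi_ratio, seed,
                            jitter_sd = 0) {
  if (n_spikes < 3L) stop("n_spikes must be >= 3 (adaptation index undefined)")
  if (first_isi <= 0) stop("first_isi must be > 0")
  if (isi_ratio <= 0) stop("isi_ratio must be > 0")
  n_isi <- n_spikes - 1L
  r <- isi_ratio^(1 / (n_isi - 1L))
  isis <- first_isi * r^(seq_len(n_isi) - 1L)
  times <- c(0, cumsum(isis))
  if (jitter_sd > 0) {
    times <- with_seed(seed, {
      interior <- seq(2L, n_spikes - 1L)
      times[interior] <- times[interior] + stats::rnorm(length(interior), 0, jitter_sd)
      sort(times)
    })
  }
  spike_train(times, t0 = 0, t1 = max(times),
              ground_truth = ground_truth("train",
                list(model = "geometric_isi", n_spikes = n_spikes,
                     first_isi = first_isi, isi_ratio = isi_ratio,
                     jitter_sd = jitter_sd), seed))
}

## internal: sample a piecewise-constant-rate Poisson process
## segments: data.frame(start, end, rate); returns sorted times
sample_piecewise_poisson <- function(segments) {
  times <- numeric(0)
  for (i in seq_len(nrow(segments))) {
    dur <- segments$end[i] - segments$start[i]
    lam <- segments$rate[i] * dur
    if (lam <= 0) next
    k <- stats::rpois(1L, lam)
    if (k > 0) times <- c(times, stats::runif(k, segments$start[i], segments$end[i]))
  }
  times <- sort(times)
  while (any(diff(times) <= 0)) {            # break exact ties (measure zero)
    times[c(FALSE, diff(times) <= 0)] <- times[c(FALSE, diff(times) <= 0)] + 1e-9
    times <- sort(times)
  }
  times
}

#' Generate direction-tuned moving-grating trials
#'
#' Per-trial spike counts are Poisson with mean
#' `base_count * exp(kappa * (cos(theta - pref_dir) - 1))` -- a von Mises
#' tuning profile normalized to peak 1 at the preferred direction.
#' Spike times are uniform within the 2 s sweep.
#'
#' @param pref_dir Preferred direction in degrees.
#' @param kappa von Mises concentration (>= 0; 0 means untuned).
#' @param base_count Expected spike count at the preferred direction.
#' @param n_trials Trials per direction.
#' @param directions Stimulus directions in degrees (default 8 cardinal
#'   and oblique directions, 45 degrees apart).
#' @param seed Integer seed.
#' @param sweep_s Sweep duration (s); the protocol default is 2 s.
#' @return List of [stimulus_trial] objects (directions vary fastest).
#' @export
gen_direction_trials <- function(pref_dir, kappa, base_count, n_trials,
                                 directions = seq(0, 315, by = 45), seed,
                                 sweep_s = 2) {
  if (!length(directions)) stop("directions must be non-empty")
  if (base_count <= 0) stop("base_count must be > 0")
  if (kappa < 0) stop("kappa must be >= 0")
  gt <- ground_truth("train",
    list(model = "von_mises_direction", pref_dir = pref_dir, kappa = kappa,
         base_count = base_count, n_trials = n_trials,
         directions = directions), seed)
  with_seed(seed, {
    trials <- list()
    for (tr in seq_len(n_trials)) {
      for (d in directions) {
        mu <- base_count * exp(kappa * (cos((d - pref_dir) * pi / 180) - 1))
        k <- stats::rpois(1L, mu)
        times <- sort(stats::runif(k, 0, sweep_s))
        while (any(diff(times) <= 0)) {
          times[c(FALSE, diff(times) <= 0)] <-
            times[c(FALSE, diff(times) <= 0)] + 1e-9
          times <- sort(times)
        }
        st <- spike_train(times, 0, sweep_s, ground_truth = gt)
        trials[[length(trials) + 1L]] <- stimulus_trial(
          st, list(kind = "grating", direction_deg = d, trial = tr),
          list(stim_on = c(0, sweep_s)))
      }
    }
    trials
  })
}

## internal: center-size modulation of the evoked rate, recorded in
## ground truth. Gaussian in log2 diameter around d_peak with a floor.
size_profile <- function(diameter_um, d_peak = 300, log2_sigma = 1,
                         floor = 0.25) {
  floor + (1 - floor) * exp(-(log2(diameter_um / d_peak))^2 / (2 * log2_sigma^2))
}

#' Generate flashing-spot trials for a given response class
#'
#' Poisson spiking at `on_rate` during the class-appropriate window(s)
#' (ON: the whole stimulus-on epoch; OFF: the whole stimulus-off epoch;
#' ON-OFF: 300 ms transients after each luminance edge) and at
#' `baseline_rate` elsewhere. Spot diameter scales the evoked rate by a
#' center-size profile recorded in the ground truth.
#'
#' @param cell_class `"ON"`, `"OFF"`, or `"ON-OFF"`.
#' @param diameters Spot diameters in um (protocol: 50-1200 um).
#' @param on_rate Evoked rate in spikes/s (must exceed `baseline_rate`).
#' @param baseline_rate Spontaneous rate in spikes/s (>= 0).
#' @param epoch Stimulus-on duration (s); protocol default 2 s.
#' @param n_trials Trials per diameter.
#' @param seed Integer seed.
#' @param edge_window Transient window for ON-OFF cells (s).
#' @return List of [stimulus_trial]s with epochs `baseline`
#'   (1 s pre-stimulus), `stim_on`, and `stim_off` (2 s post-offset).
#' @export
gen_flash_trials <- function(cell_class = c("ON", "OFF", "ON-OFF"),
                             diameters = c(50, 100, 200, 300, 600, 1200),
                             on_rate, baseline_rate, epoch = 2, n_trials = 5,
                             seed, edge_window = 0.3) {
  cell_class <- match.arg(cell_class)
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  if (on_rate < baseline_rate) stop("on_rate must be >= baseline_rate")
  if (epoch <= 0) stop("epoch must be > 0")
  if (on_rate == baseline_rate)
    warning("on_rate equals baseline_rate: cell class is unrecoverable")
  t_base <- 1; t_on <- t_base + epoch; t_end <- t_on + 2
  epochs <- list(baseline = c(0, t_base), stim_on = c(t_base, t_on),
                 stim_off = c(t_on, t_end))
  gt <- ground_truth("train",
    list(model = "flash", cell_class = cell_class, on_rate = on_rate,
         baseline_rate = baseline_rate, epoch = epoch,
         size_profile = list(d_peak = 300, log2_sigma = 1, floor = 0.25)),
    seed)
  with_seed(seed, {
    trials <- list()
    for (d in diameters) {
      evoked <- baseline_rate + (on_rate - baseline_rate) * size_profile(d)
      seg <- switch(cell_class,
        "ON" = data.frame(
          start = c(0, t_base, t_on),
          end   = c(t_base, t_on, t_end),
          rate  = c(baseline_rate, evoked, baseline_rate)),
        "OFF" = data.frame(
          start = c(0, t_base, t_on),
          end   = c(t_base, t_on, t_end),
          rate  = c(baseline_rate, baseline_rate, evoked)),
        "ON-OFF" = data.frame(
          start = c(0, t_base, t_base + edge_window, t_on, t_on + edge_window),
          end   = c(t_base, t_base + edge_window, t_on, t_on + edge_window, t_end),
          rate  = c(baseline_rate, evoked, baseline_rate, evoked, baseline_rate)))
      for (tr in seq_len(n_trials)) {
        st <- spike_train(sample_piecewise_poisson(seg), 0, t_end,
                          ground_truth = gt)
        trials[[length(trials) + 1L]] <- stimulus_trial(
          st, list(kind = "flash", diameter_um = d, trial = tr), epochs)
      }
    }
    trials
  })
}

#' Generate a mono- or bistratified neuron morphology
#'
#' Builds a rooted binary-branching tree whose dendritic length is
#' concentrated in Gaussian slabs at the requested IPL depths. The soma
#' sits in the ganglion cell layer below the 0% border; one primary
#' dendrite per stratification plane climbs to its slab and arborizes
#' radially. The result is valid SWC on write.
#'
#' @param soma_depth Soma z in um (negative = inside the GCL, below the
#'   0% IPL border at z = 0).
#' @param strat_depths One or two stratification depths in percent of
#'   IPL depth (0 = GCL border, 100 = INL border).
#' @param arbor_radius Approximate dendritic-field radius in um.
#' @param branch_order Number of successive bifurcations per plane.
#' @param seed Integer seed.
#' @param ipl_thickness_um Physical IPL thickness (default 50 um).
#' @param slab_sigma_pct Gaussian slab SD in percent depth (default 5).
#' @return A `morphology` (see [read_swc]) with attribute `ipl_frame`
#'   (the [ipl_frame] used) and a `ground_truth` record.
#' @export
gen_morphology <- function(soma_depth = -10, strat_depths, arbor_radius = 120,
                           branch_order = 5L, seed, ipl_thickness_um = 50,
                           slab_sigma_pct = 5) {
  strat_depths <- as.numeric(strat_depths)
  if (length(strat_depths) < 1L || length(strat_depths) > 2L)
    stop("strat_depths must contain 1 or 2 planes (mono/bistratified scheme)")
  if (any(strat_depths < 0 | strat_depths > 100))
    stop("strat_depths must lie in [0, 100]")
  frame <- ipl_frame(gcl_border_z = 0, inl_border_z = ipl_thickness_um)
  sigma_um <- slab_sigma_pct / 100 * ipl_thickness_um
  with_seed(seed, {
    cap <- 4L * (2L^(branch_order + 1L)) * length(strat_depths) + 8L
    nd <- list(type = integer(cap), x = numeric(cap), y = numeric(cap),
               z = numeric(cap), radius = numeric(cap), parent = integer(cap))
    n_nodes <- 1L
    nd$type[1] <- 1L; nd$x[1] <- 0; nd$y[1] <- 0; nd$z[1] <- soma_depth
    nd$radius[1] <- 6; nd$parent[1] <- -1L
    add_node <- function(type, x, y, z, radius, parent) {
      id <- n_nodes + 1L
      n_nodes <<- id
      nd$type[id] <<- type; nd$x[id] <<- x; nd$y[id] <<- y; nd$z[id] <<- z
      nd$radius[id] <<- radius; nd$parent[id] <<- parent
      id
    }
    for (depth in strat_depths) {
      z_plane <- depth / 100 * ipl_thickness_um
      entry <- add_node(3L, 0, 0, z_plane, 1.2, 1L)
      # queue of (node id, x, y, heading, remaining orders)
      grow <- function(parent_id, px, py, heading, order) {
        if (order == 0L) return(invisible(NULL))
        seg_len <- arbor_radius / branch_order
        for (dth in c(-1, 1) * stats::runif(1, 20, 45) * pi / 180) {
          h <- heading + dth
          nx <- px + seg_len * cos(h)
          ny <- py + seg_len * sin(h)
          nz <- stats::rnorm(1, z_plane, sigma_um)
          nz <- min(max(nz, 0), ipl_thickness_um)
          id <- add_node(3L, nx, ny, nz, 0.8, parent_id)
          grow(id, nx, ny, h, order - 1L)
        }
      }
      for (h0 in stats::runif(2, 0, 2 * pi)) grow(entry, 0, 0, h0, branch_order)
    }
    m <- morphology(data.frame(id = seq_len(n_nodes),
                               type = nd$type[seq_len(n_nodes)],
                               x = nd$x[seq_len(n_nodes)],
                               y = nd$y[seq_len(n_nodes)],
                               z = nd$z[seq_len(n_nodes)],
                               radius = nd$radius[seq_len(n_nodes)],
                               parent = nd$parent[seq_len(n_nodes)]))
    attr(m, "ipl_frame") <- frame
    attr(m, "ground_truth") <- ground_truth("morphology",
      list(soma_depth = soma_depth, strat_depths = strat_depths,
           arbor_radius = arbor_radius, branch_order = branch_order,
           ipl_thickness_um = ipl_thickness_um,
           slab_sigma_pct = slab_sigma_pct), seed)
    m
  })
}

#' Generate a curved retinal cross-section with known boundaries
#'
#' Emulates a vibratome cross-section: a nuclear-stain channel marking
#' the ganglion cell layer (GCL) and inner nuclear layer (INL) slabs on
#' either side of a curved IPL, plus one marker channel per requested
#' band depth. Boundaries are sinusoidal with the given amplitude; the
#' true curves are returned alongside the image so straightening can be
#' tested by round trip.
#'
#' @param width,height Raster size in px.
#' @param boundary_amplitude Sinusoid amplitude in px (0 = already
#'   straight).
#' @param band_depths Marker band depths in percent IPL depth.
#' @param band_sigma Band Gaussian SD in px.
#' @param noise_sd Additive Gaussian noise SD (intensity units on a
#'   0-255 scale).
#' @param seed Integer seed (noise and phase).
#' @param ipl_frac Fraction of image height occupied by the IPL.
#' @return List with `section` (a [section_image]) and `truth_curves`
#'   (a [boundary_curves]).
#' @export
gen_curved_section <- function(width = 200, height = 160,
                               boundary_amplitude = 10, band_depths = c(40),
                               band_sigma = 4, noise_sd = 2, seed,
                               ipl_frac = 0.4) {
  if (any(band_depths < 0 | band_depths > 100))
    stop("band_depths must lie in [0, 100]")
  thick <- ipl_frac * height
  nuc_thick <- 0.15 * height
  y_mid <- height / 2 - thick / 2
  if (y_mid - nuc_thick - boundary_amplitude < 1 ||
      y_mid + thick + nuc_thick + boundary_amplitude > height)
    stop("boundary_amplitude too large: layers would leave the raster")
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    xs <- seq_len(width)
    y_top <- y_mid + boundary_amplitude * sin(2 * pi * xs / width + phase)
    y_bot <- y_top + thick                       # constant thickness: no crossing
    rows <- seq_len(height)
    mk_channel <- function(fun) {
      ch <- matrix(0, nrow = height, ncol = width)
      for (j in xs) ch[, j] <- fun(rows, y_top[j], y_bot[j])
      if (noise_sd > 0)
        ch <- ch + matrix(stats::rnorm(height * width, 0, noise_sd),
                          height, width)
      pmax(ch, 0)
    }
    nuclear <- mk_channel(function(r, yt, yb)
      ifelse((r >= yt - nuc_thick & r < yt) | (r >= yb & r < yb + nuc_thick),
             200, 5))
    channels <- list(nuclear = nuclear)
    for (i in seq_along(band_depths)) {
      d <- band_depths[i]
      channels[[paste0("marker", i)]] <- mk_channel(function(r, yt, yb)
        200 * exp(-(r - (yt + d / 100 * (yb - yt)))^2 / (2 * band_sigma^2)))
    }
    roles <- c("nuclear", rep("marker", length(band_depths)))
    names(roles) <- names(channels)
    sec <- section_image(channels, pixel_size = 1, channel_roles = roles)
    attr(sec, "ground_truth") <- ground_truth("section",
      list(width = width, height = height,
           boundary_amplitude = boundary_amplitude, band_depths = band_depths,
           band_sigma = band_sigma, noise_sd = noise_sd,
           ipl_frac = ipl_frac), seed)
    list(section = sec,
         truth_curves = boundary_curves(top = y_top, bottom = y_bot,
                                        domain = c(1L, width)))
  })
}
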