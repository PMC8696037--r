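## Spike-train physiology metrics: firing adaptation, F-I curves,
## flash-response classification, spot-size tuning, and direction
## tuning with a direction-selectivity index.

#' Firing adaptation index
#'
#' Compares the first and last inter-spike intervals of a train. The
#' `"literal"` variant is `1 - T_last / T_initial` (0 for a perfectly
#' regular train; negative when firing decays, since the last interval
#' is then longer). The `"decay_positive"` variant is
#' `1 - T_initial / T_last`, which is positive for decaying firing.
#' Both agree (at 0) for a regular train; the variant is recorded on
#' the result. Algebraically
#' `literal = 1 - 1 / (1 - decay_positive)`.
#'
#' @param train A [spike_train] with at least 3 spikes.
#' @param variant `"literal"` (default) or `"decay_positive"`.
#' @return Numeric index with attribute `variant`.
#' @examples
#' tr <- gen_spike_train(10, first_isi = 0.1, isi_ratio = 1, seed = 1)
#' adaptation_index(tr)  # 0
#' @export
adaptation_index <- function(train, variant = c("literal", "decay_positive")) {
  variant <- match.arg(variant)
  stopifnot(inherits(train, "spike_train"))
  s <- train$spikes
  if (length(s) < 3L)
    stop("adaptation index undefined for fewer than 3 spikes")
  t_initial <- s[2] - s[1]
  t_last <- s[length(s)] - s[length(s) - 1L]
  val <- switch(variant,
                literal = 1 - t_last / t_initial,
                decay_positive = 1 - t_initial / t_last)
  structure(val, variant = variant)
}

#' Firing rate versus injected current (F-I curve)
#'
#' Mean firing rate (spike count / step duration) per current step.
#'
#' @param trials List of [stimulus_trial]s with
#'   `condition$kind == "current_step"` and a `step` epoch.
#' @return data.frame `current_pA`, `rate_hz`, `n_trials`, sorted by
#'   current.
#' @export
fi_curve <- function(trials) {
  stopifnot(length(trials) > 0)
  rows <- lapply(trials, function(tr) {
    stopifnot(inherits(tr, "stimulus_trial"))
    if (!identical(tr$condition$kind, "current_step"))
      stop("fi_curve expects current_step trials")
    w <- tr$epochs$step
    if (is.null(w)) stop("trial lacks a 'step' epoch")
    dur <- w[2] - w[1]
    data.frame(current_pA = tr$condition$current_pA,
               rate_hz = if (dur > 0) count_spikes(tr$train, w) / dur else 0)
  })
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(rate_hz ~ current_pA, d, mean)
  agg$n_trials <- stats::aggregate(rate_hz ~ current_pA, d, length)$rate_hz
  agg[order(agg$current_pA), ]
}

## internal: per-trial rate in a window
window_rate <- function(trial, window) {
  count_spikes(trial$train, window) / (window[2] - window[1])
}

#' Classify a cell's flash response as ON, OFF, ON-OFF, or unresponsive
#'
#' From trials sharing a `baseline` / `stim_on` / `stim_off` epoch
#' structure, computes a z-scored rate elevation in the 300 ms windows
#' after the light-ON and light-OFF edges relative to the baseline rate
#' distribution across trials:
#' `on_index = (mean post-ON rate - mean baseline rate) / SD(baseline rates)`.
#' The call is ON if only `on_index` exceeds `z_thresh`, OFF if only
#' `off_index` does, ON-OFF if both, and unresponsive if neither (such
#' cells are typically discarded from analysis).
#'
#' @param trials List of flash [stimulus_trial]s.
#' @param z_thresh z-score threshold (default 3).
#' @param edge_window Post-edge response window in seconds (default 0.3).
#' @return Object of class `flash_classification`: `call`, `on_index`,
#'   `off_index`, `baseline_rate`, and `fallback` (TRUE when a silent
#'   baseline forced the Poisson-SD fallback).
#' @export
classify_flash_response <- function(trials, z_thresh = 3, edge_window = 0.3) {
  stopifnot(length(trials) > 0)
  ep <- trials[[1]]$epochs
  if (is.null(ep$baseline) || is.null(ep$stim_on) || is.null(ep$stim_off))
    stop("trials need baseline, stim_on and stim_off epochs")
  base <- vapply(trials, window_rate, numeric(1), window = ep$baseline)
  on_w <- c(ep$stim_on[1], min(ep$stim_on[1] + edge_window, ep$stim_on[2]))
  off_w <- c(ep$stim_off[1], min(ep$stim_off[1] + edge_window, ep$stim_off[2]))
  on_r <- vapply(trials, window_rate, numeric(1), window = on_w)
  off_r <- vapply(trials, window_rate, numeric(1), window = off_w)
  sd_base <- stats::sd(base)
  fallback <- FALSE
  if (!is.finite(sd_base) || sd_base == 0) {
    # silent baseline: use the Poisson SD of the baseline rate estimate,
    # with a half-spike floor over the pooled baseline time
    fallback <- TRUE
    t_base <- (ep$baseline[2] - ep$baseline[1]) * length(trials)
    lam <- max(mean(base), 0.5 / t_base)
    sd_base <- sqrt(lam / (ep$baseline[2] - ep$baseline[1]))
  }
  on_index <- (mean(on_r) - mean(base)) / sd_base
  off_index <- (mean(off_r) - mean(base)) / sd_base
  call <- if (on_index > z_thresh && off_index > z_thresh) "ON-OFF"
          else if (on_index > z_thresh) "ON"
          else if (off_index > z_thresh) "OFF"
          else "unresponsive"
  structure(list(call = call, on_index = on_index, off_index = off_index,
                 baseline_rate = mean(base), fallback = fallback),
            class = "flash_classification")
}

#' @export
print.flash_classification <- function(x, ...) {
  cat(sprintf("flash response: %s (on z = %.1f, off z = %.1f)\n",
              x$call, x$on_index, x$off_index))
  invisible(x)
}

#' Spot-size tuning
#'
#' Mean stimulus-on firing rate per spot diameter, plus the same row
#' normalized to its maximum for population heatmaps.
#'
#' @param trials List of flash [stimulus_trial]s with
#'   `condition$diameter_um` and a `stim_on` epoch.
#' @return data.frame `diameter_um`, `rate_hz`, `norm_rate`, `n_trials`.
#' @export
spot_size_tuning <- function(trials) {
  stopifnot(length(trials) > 0)
  d <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(diameter_um = tr$condition$diameter_um,
               rate_hz = window_rate(tr, tr$epochs$stim_on))
  }))
  agg <- stats::aggregate(rate_hz ~ diameter_um, d, mean)
  agg$norm_rate <- if (max(agg$rate_hz) > 0) agg$rate_hz / max(agg$rate_hz)
                   else agg$rate_hz
  agg$n_trials <- stats::aggregate(rate_hz ~ diameter_um, d, length)$rate_hz
  agg[order(agg$diameter_um), ]
}

#' Direction tuning and direction-selectivity index
#'
#' Mean spike count per stimulus direction and the vector-sum
#' direction-selectivity index
#' `DSI = |sum_d n_d e^{i theta_d}| / sum_d n_d`, with the preferred
#' direction given by the argument of the vector sum. DSI is 0 for
#' uniform responses and 1 when all spikes fall in one direction. The
#' `"pref_null"` variant instead reports
#' `(pref - null) / (pref + null)` using the direction opposite the
#' preferred one as null.
#'
#' @param trials List of [stimulus_trial]s with
#'   `condition$direction_deg`; default protocol is 8 directions 45
#'   degrees apart, 2 s sweeps.
#' @param stim_window Counting window `c(start, end)` in s (default:
#'   each trial's `stim_on` epoch).
#' @param dsi_mode `"vector_sum"` (default) or `"pref_null"`.
#' @return Object of class `direction_tuning`: `directions`,
#'   `mean_counts`, `dsi`, `pref_dir` (deg in [0, 360)), `dsi_mode`,
#'   and `undefined` (TRUE when all counts are zero).
#' @export
direction_tuning <- function(trials, stim_window = NULL,
                             dsi_mode = c("vector_sum", "pref_null")) {
  dsi_mode <- match.arg(dsi_mode)
  stopifnot(length(trials) > 0)
  d <- do.call(rbind, lapply(trials, function(tr) {
    w <- if (is.null(stim_window)) tr$epochs$stim_on else stim_window
    data.frame(direction = tr$condition$direction_deg,
               count = count_spikes(tr$train, w))
  }))
  agg <- stats::aggregate(count ~ direction, d, mean)
  agg <- agg[order(agg$direction), ]
  dirs <- agg$direction
  if (length(dirs) > 1L) {
    steps <- diff(sort(dirs %% 360))
    if (max(steps) - min(steps) > 1e-6)
      warning("stimulus directions are not evenly spaced over 360 degrees")
  }
  counts <- agg$count
  if (all(counts == 0))
    return(structure(list(directions = dirs, mean_counts = counts,
                          dsi = NA_real_, pref_dir = NA_real_,
                          dsi_mode = dsi_mode, undefined = TRUE),
                     class = "direction_tuning"))
  theta <- dirs * pi / 180
  vec <- sum(counts * exp(1i * theta))
  pref_dir <- (Arg(vec) * 180 / pi) %% 360
  dsi <- if (dsi_mode == "vector_sum") {
    Mod(vec) / sum(counts)
  } else {
    ipref <- which.min(pmin(abs(dirs - pref_dir), 360 - abs(dirs - pref_dir)))
    null_dir <- (dirs[ipref] + 180) %% 360
    inull <- which.min(pmin(abs(dirs - null_dir), 360 - abs(dirs - null_dir)))
    (counts[ipref] - counts[inull]) / (counts[ipref] + counts[inull])
  }
  structure(list(directions = dirs, mean_counts = counts, dsi = dsi,
                 pref_dir = pref_dir, dsi_mode = dsi_mode, undefined = FALSE),
            class = "direction_tuning")
}

#' @export
print.direction_tuning <- function(x, ...) {
  if (x$undefined) {
    cat("direction_tuning: no spikes; DSI undefined\n")
  } else {
    cat(sprintf("direction_tuning (%s): DSI = %.3f, preferred %.0f deg\n",
                x$dsi_mode, x$dsi, x$pref_dir))
  }
  invisible(x)
}
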