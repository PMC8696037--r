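## Run configuration, the end-to-end synthetic demo pipeline, and the
## command-line entry point.

#' Default run configuration
#'
#' Nested parameter blocks, one per module, every default equal to the
#' module function defaults. Unknown keys are rejected by
#' [validate_config].
#'
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @param output_dir Output directory.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, output_dir = "rgckit-out") {
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    mosaic = list(density = 100, window = c(0, 0, 2000, 2000),
                  dmin = 50, dr = 10, r_max = 200,
                  edge_policy = "buffer", ri_mode = "sem",
                  fit_order = 7L, n_boot = 1000L, map_bin = 200),
    synth = list(n_spikes = 10L, first_isi = 0.05, isi_ratio = 2,
                 flash_on_rate = 40, flash_baseline = 2, flash_trials = 10L,
                 pref_dir = 90, kappa = 8, base_count = 50,
                 direction_trials = 10L),
    straighten = list(width = 200L, height = 160L, amplitude = 10,
                      band_depths = c(30, 70), band_sigma = 4,
                      noise_sd = 2, out_rows = 100L, smooth_sigma = 5),
    morphology = list(strat_depths = list(mono = 30, bi = c(30, 70)),
                      arbor_radius = 120, branch_order = 5L, bin = 2,
                      prominence = 0.2, min_peak_fraction = 0.15),
    ephys = list(z_thresh = 3, dsi_mode = "vector_sum",
                 adaptation_variant = "literal", edge_window = 0.3)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Rejects unknown keys at the top level and inside each module block,
#' so typos fail before any stage executes.
#'
#' @param config A list shaped like [default_config].
#' @return The config, invisibly, or an error naming the unknown key.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (block in intersect(names(config), c("mosaic", "synth", "straighten",
                                           "morphology", "ephys"))) {
    bad <- setdiff(names(config[[block]]), names(ref[[block]]))
    if (length(bad))
      stop(sprintf("unknown key(s) in config block '%s': %s", block,
                   paste(bad, collapse = ", ")))
  }
  invisible(config)
}

## internal: merge a partial config over the defaults
merge_config <- function(config) {
  validate_config(config)
  out <- default_config()
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && nm %in% c("mosaic", "synth", "straighten",
                                           "morphology", "ephys")) {
      for (k in names(config[[nm]])) out[[nm]][[k]] <- config[[nm]][[k]]
    } else out[[nm]] <- config[[nm]]
  }
  out
}

#' Run the end-to-end synthetic demo pipeline
#'
#' Generates every input class with the configured parameters, runs all
#' analysis stages, and writes per-stage CSVs, a JSON summary, and a
#' log (versions, seeds, discarded items). Deterministic for a fixed
#' config and seed.
#'
#' @param config Full or partial [default_config]-shaped list.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- merge_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("rgckit %s | R %s | seed %d",
                         as.character(utils::packageVersion("rgckit")),
                         paste(R.version$major, R.version$minor, sep = "."),
                         cfg$seed))
  logf <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  summary <- list(seed = cfg$seed)
  seed <- cfg$seed

  ## --- mosaic stage -------------------------------------------------
  mc <- cfg$mosaic
  pats <- list(
    poisson = gen_poisson_pattern(mc$density, mc$window, seed = seed + 1L),
    hardcore = gen_hardcore_pattern(mc$density, mc$dmin, mc$window,
                                    seed = seed + 2L))
  mosaic_rows <- list()
  for (nm in names(pats)) {
    p <- pats[[nm]]
    st <- compute_nnd(p)
    ri_sem <- regularity_index(st, "sem"); ri_sd <- regularity_index(st, "sd")
    drp <- density_recovery_profile(p, dr = mc$dr, r_max = mc$r_max,
                                    edge_policy = mc$edge_policy)
    drp <- fit_drp_curve(drp, order = mc$fit_order, n_boot = mc$n_boot,
                         seed = seed + 3L)
    write_point_table(p, file.path(cfg$output_dir, paste0(nm, "_points.csv")))
    write_drp(drp, file.path(cfg$output_dir, paste0(nm, "_drp.csv")))
    mosaic_rows[[nm]] <- data.frame(
      pattern = nm, n = st$n, mean_nnd_um = st$mean_nnd,
      ri_sem = ri_sem$ri, ri_sd = ri_sd$ri,
      global_density_mm2 = drp$global_density)
    logf("mosaic %s: n = %d, RI(sem) = %.2f, RI(sd) = %.2f", nm, st$n,
         ri_sem$ri, ri_sd$ri)
  }
  mosaic_tab <- do.call(rbind, mosaic_rows)
  utils::write.csv(mosaic_tab, file.path(cfg$output_dir, "mosaic_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  summary$mosaic <- mosaic_tab

  ## --- ephys stage --------------------------------------------------
  sy <- cfg$synth; ec <- cfg$ephys
  train <- gen_spike_train(sy$n_spikes, sy$first_isi, sy$isi_ratio,
                           seed = seed + 4L)
  adapt <- adaptation_index(train, ec$adaptation_variant)
  flash_calls <- list(); discarded <- 0L
  for (cls in c("ON", "OFF", "ON-OFF")) {
    trials <- gen_flash_trials(cls, on_rate = sy$flash_on_rate,
                               baseline_rate = sy$flash_baseline,
                               n_trials = sy$flash_trials,
                               seed = seed + 5L + match(cls, c("ON", "OFF", "ON-OFF")))
    fc <- classify_flash_response(trials, z_thresh = ec$z_thresh,
                                  edge_window = ec$edge_window)
    if (fc$call == "unresponsive") {
      discarded <- discarded + 1L
      logf("flash cell (%s truth) unresponsive: discarded", cls)
    }
    flash_calls[[cls]] <- fc$call
    tune <- spot_size_tuning(trials)
    utils::write.csv(tune, file.path(cfg$output_dir,
                                     paste0("spot_tuning_", gsub("-", "", cls), ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  dir_trials <- gen_direction_trials(sy$pref_dir, sy$kappa, sy$base_count,
                                     sy$direction_trials, seed = seed + 9L)
  dt <- direction_tuning(dir_trials, dsi_mode = ec$dsi_mode)
  utils::write.csv(data.frame(direction_deg = dt$directions,
                              mean_count = dt$mean_counts),
                   file.path(cfg$output_dir, "direction_tuning.csv"),
                   row.names = FALSE, quote = FALSE)
  summary$ephys <- list(adaptation_index = as.numeric(adapt),
                        adaptation_variant = ec$adaptation_variant,
                        flash_calls = flash_calls,
                        dsi = dt$dsi, pref_dir = dt$pref_dir,
                        discarded_cells = discarded)
  logf("ephys: adaptation = %.3f (%s), DSI = %.3f, pref %.0f deg",
       as.numeric(adapt), ec$adaptation_variant, dt$dsi, dt$pref_dir)

  ## --- morphology stage ---------------------------------------------
  mo <- cfg$morphology
  morph_rows <- list()
  for (nm in names(mo$strat_depths)) {
    m <- gen_morphology(strat_depths = mo$strat_depths[[nm]],
                        arbor_radius = mo$arbor_radius,
                        branch_order = mo$branch_order, seed = seed + 10L)
    prof <- stratification_distribution(m, bin = mo$bin)
    call <- classify_subtype(prof, prominence = mo$prominence,
                             min_peak_fraction = mo$min_peak_fraction)
    write_swc(m, file.path(cfg$output_dir, paste0("morph_", nm, ".swc")))
    morph_rows[[nm]] <- data.frame(
      cell_id = nm, total_length_um = total_neurite_length(m),
      n_branch_points = branch_points(m),
      peak_depths_pct = paste(sprintf("%.0f", call$peak_depths), collapse = ";"),
      subtype = call$call)
    logf("morphology %s: subtype %s", nm, call$call)
  }
  morph_tab <- do.call(rbind, morph_rows)
  utils::write.csv(morph_tab, file.path(cfg$output_dir, "morphology_features.csv"),
                   row.names = FALSE, quote = FALSE)
  summary$morphology <- morph_tab

  ## --- straighten stage ---------------------------------------------
  st <- cfg$straighten
  gen <- gen_curved_section(width = st$width, height = st$height,
                            boundary_amplitude = st$amplitude,
                            band_depths = st$band_depths,
                            band_sigma = st$band_sigma,
                            noise_sd = st$noise_sd, seed = seed + 11L)
  curves <- detect_boundaries(gen$section, smooth_sigma = st$smooth_sigma)
  straight <- coons_straighten(gen$section, curves, out_rows = st$out_rows)
  prof <- depth_profile(straight, "marker1")
  write_profile(prof, file.path(cfg$output_dir, "stratification_profile.csv"))
  peak_depth <- prof$depth_bins[which.max(prof$signal)]
  summary$straighten <- list(planted_depth = st$band_depths[1],
                             recovered_depth = peak_depth,
                             oob_samples = attr(straight, "oob_count"))
  logf("straighten: band planted at %.0f%%, recovered at %.1f%%",
       st$band_depths[1], peak_depth)

  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
  invisible(summary)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `inst/exec/rgckit` wrapper:
#' `simulate`, `drp`, `regularity`, `straighten`, `stratify`, `morph`,
#' `ephys`, `report`. Flags are `--key value` pairs; common flags are
#' `--seed`, `--out`, and per-command knobs (`--dr`, `--rmax`, `--edge`,
#' `--ri-mode`, `--rows`, `--sigma`, `--nuclear-channel`, `--dsi-mode`,
#' `--adaptation-variant`, `--z-thresh`).
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status 0 on success (invisibly); errors propagate.
#' @export
rgc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: rgckit <simulate|drp|regularity|straighten|stratify|morph|ephys|report> [--flag value ...]")
  cmd <- args[1]
  flags <- parse_flags(args[-1])
  get <- function(key, default = NULL) flags[[key]] %||% default
  num <- function(key, default) as.numeric(get(key, default))
  switch(cmd,
    simulate = {
      p <- gen_poisson_pattern(num("density", 100),
                               window = c(0, 0, num("size", 2000),
                                          num("size", 2000)),
                               seed = as.integer(num("seed", 1)))
      write_point_table(p, get("out", "pattern.csv"))
      message("wrote ", get("out", "pattern.csv"))
    },
    drp = {
      p <- read_point_table(get("in", stop("drp needs --in points.csv")))
      d <- density_recovery_profile(p, dr = num("dr", 10),
                                    r_max = num("rmax", 300),
                                    edge_policy = get("edge", "buffer"))
      d <- fit_drp_curve(d, order = as.integer(num("order", 7)),
                         n_boot = as.integer(num("nboot", 1000)),
                         seed = as.integer(num("seed", 1)))
      write_drp(d, get("out", "drp.csv"))
      message("wrote ", get("out", "drp.csv"))
    },
    regularity = {
      p <- read_point_table(get("in", stop("regularity needs --in points.csv")))
      ri <- regularity_index(compute_nnd(p), get("ri-mode", "sem"))
      cat(sprintf("n,%d\nmean_nnd_um,%.6g\nri,%.6g\nmode,%s\n",
                  ri$n, ri$mean_nnd, ri$ri, ri$denominator_mode))
    },
    straighten = {
      sec <- read_section(get("in", stop("straighten needs --in manifest.json")))
      curves <- detect_boundaries(sec, nuclear_channel = get("nuclear-channel"),
                                  smooth_sigma = num("sigma", 5))
      straight <- coons_straighten(sec, curves,
                                   out_rows = as.integer(num("rows", 100)))
      out <- get("out", "straightened")
      write_section(section_image(straight$channels,
                                  pixel_size = straight$pixel_size,
                                  channel_roles = sec$channel_roles), out)
      message("wrote ", out, ".json")
    },
    stratify = {
      sec <- read_section(get("in", stop("stratify needs --in manifest.json")))
      curves <- detect_boundaries(sec, nuclear_channel = get("nuclear-channel"),
                                  smooth_sigma = num("sigma", 5))
      straight <- coons_straighten(sec, curves,
                                   out_rows = as.integer(num("rows", 100)))
      ch <- get("channel", setdiff(names(sec$channels), "nuclear")[1])
      write_profile(depth_profile(straight, ch), get("out", "profile.csv"))
      message("wrote ", get("out", "profile.csv"))
    },
    morph = {
      m <- read_swc(get("in", stop("morph needs --in cell.swc")))
      frame <- ipl_frame(num("gcl-z", 0), num("inl-z", 50))
      prof <- stratification_distribution(m, frame, bin = num("bin", 2))
      call <- classify_subtype(prof)
      cat(sprintf("total_length_um,%.6g\nn_branch_points,%d\npeak_depths_pct,%s\nsubtype,%s\n",
                  total_neurite_length(m), branch_points(m),
                  paste(sprintf("%.1f", call$peak_depths), collapse = ";"),
                  call$call))
    },
    ephys = {
      df <- read_spike_table(get("in", stop("ephys needs --in spikes.csv")))
      for (cell in unique(df$cell_id)) {
        sub <- df[df$cell_id == cell, ]
        kind <- sub$condition_kind[1]
        if (kind == "grating") {
          trials <- trials_from_table(sub, list(stim_on = c(0, 2)))
          dt <- direction_tuning(trials, dsi_mode = get("dsi-mode", "vector_sum"))
          cat(sprintf("%s,dsi,%.6g\n%s,pref_dir_deg,%.6g\n",
                      cell, dt$dsi, cell, dt$pref_dir))
        } else if (kind == "flash") {
          epoch <- num("epoch", 2)
          trials <- trials_from_table(sub, list(baseline = c(0, 1),
                                                stim_on = c(1, 1 + epoch),
                                                stim_off = c(1 + epoch, 3 + epoch)))
          fc <- classify_flash_response(trials, z_thresh = num("z-thresh", 3))
          cat(sprintf("%s,flash_call,%s\n", cell, fc$call))
        }
      }
    },
    report = {
      cfg <- default_config(seed = as.integer(num("seed", 1)),
                            output_dir = get("out", "rgckit-out"))
      run_pipeline(cfg)
      message("report written to ", cfg$output_dir)
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}

## internal: parse --key value pairs (and bare --flag as TRUE)
parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      flags[[key]] <- args[i + 1L]; i <- i + 2L
    } else {
      flags[[key]] <- TRUE; i <- i + 1L
    }
  }
  flags
}
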