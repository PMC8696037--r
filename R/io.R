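## File formats. One convention throughout: CSV with explicit headers,
## coordinates in um, times in seconds. Section rasters use a
## plain-text format (whitespace-delimited matrix per channel plus a
## JSON manifest) since the toolchain carries no TIFF codec; the
## in-memory contract is identical.

## internal: require named columns, with a helpful error
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")))
  invisible(df)
}

#' Read / write cell point tables
#'
#' CSV with columns `x_um`, `y_um`, `label`. Coordinates round-trip to
#' within 1e-6 um.
#'
#' @param pattern A [point_pattern].
#' @param path CSV path.
#' @param window Observation window for reading; defaults to the
#'   bounding box of the points.
#' @return `read_point_table`: a [point_pattern]. `write_point_table`:
#'   `path`, invisibly.
#' @export
write_point_table <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  df <- data.frame(x_um = sprintf("%.9g", pattern$x),
                   y_um = sprintf("%.9g", pattern$y),
                   label = rep(pattern$label, npoints(pattern)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_point_table
#' @export
read_point_table <- function(path, window = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("x_um", "y_um"), basename(path))
  if (is.null(window))
    window <- c(min(df$x_um), min(df$y_um), max(df$x_um), max(df$y_um))
  label <- if ("label" %in% names(df) && nrow(df)) as.character(df$label[1]) else ""
  point_pattern(df$x_um, df$y_um, window, label = label)
}

#' Read / write spike tables
#'
#' Long-format CSV with columns `cell_id`, `trial`, `condition_kind`,
#' `condition_value`, `t_s` (one row per spike). A trial with no spikes
#' leaves no rows, so rebuilding from the table recovers only the
#' trials that spiked.
#'
#' @param trials Named list: `cell_id` -> list of [stimulus_trial]s.
#' @param path CSV path.
#' @return `read_spike_table`: the data.frame. `write_spike_table`:
#'   `path`, invisibly.
#' @export
write_spike_table <- function(trials, path) {
  rows <- list()
  for (cell_id in names(trials)) {
    for (tr in trials[[cell_id]]) {
      cond <- tr$condition
      value <- cond$diameter_um %||% cond$direction_deg %||%
        cond$current_pA %||% NA_real_
      n <- length(tr$train$spikes)
      if (n == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell_id, trial = cond$trial %||% 1L,
        condition_kind = cond$kind, condition_value = value,
        t_s = tr$train$spikes)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), trial = integer(0),
               condition_kind = character(0), condition_value = numeric(0),
               t_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("cell_id", "trial", "condition_kind",
                      "condition_value", "t_s"), basename(path))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild stimulus trials from a spike table
#'
#' Groups rows of a long-format spike table (one cell) by trial and
#' condition value and attaches a shared epoch structure.
#'
#' @param df data.frame as returned by [read_spike_table], one cell.
#' @param epochs Named list of `c(start, end)` epochs (s).
#' @param t0,t1 Recording window (s).
#' @return List of [stimulus_trial]s.
#' @export
trials_from_table <- function(df, epochs, t0 = 0, t1 = NULL) {
  check_columns(df, c("trial", "condition_kind", "condition_value", "t_s"),
                "spike table")
  if (is.null(t1)) t1 <- max(c(df$t_s, vapply(epochs, max, numeric(1))))
  keys <- unique(df[, c("trial", "condition_kind", "condition_value")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$trial == keys$trial[i] &
      df$condition_value == keys$condition_value[i]
    kind <- keys$condition_kind[i]
    cond <- switch(kind,
      flash = list(kind = "flash", diameter_um = keys$condition_value[i]),
      grating = list(kind = "grating", direction_deg = keys$condition_value[i]),
      current_step = list(kind = "current_step",
                          current_pA = keys$condition_value[i]),
      stop("unknown condition_kind: ", kind))
    cond$trial <- keys$trial[i]
    stimulus_trial(spike_train(sort(df$t_s[sel]), t0, t1), cond, epochs)
  })
}

#' Read / write multi-channel section rasters
#'
#' Plain-text raster bundle: `<stem>.json` manifest (pixel size and
#' per-channel role/file) plus one whitespace-delimited matrix file per
#' channel. Round-trips a [section_image] exactly at the written
#' precision.
#'
#' @param section A [section_image].
#' @param stem Output path stem (files `<stem>.json`,
#'   `<stem>_<channel>.txt`).
#' @return `read_section`: a [section_image]. `write_section`: the
#'   manifest path, invisibly.
#' @export
write_section <- function(section, stem) {
  stopifnot(inherits(section, "section_image"))
  files <- list()
  for (nm in names(section$channels)) {
    f <- paste0(stem, "_", nm, ".txt")
    utils::write.table(format(section$channels[[nm]], digits = 9,
                              scientific = FALSE, trim = TRUE),
                       f, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    files[[nm]] <- basename(f)
  }
  manifest <- list(pixel_size = section$pixel_size,
                   channels = lapply(names(section$channels), function(nm)
                     list(name = nm,
                          role = unname(section$channel_roles[nm]),
                          file = files[[nm]])))
  jsonlite::write_json(manifest, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, ".json"))
}

#' @rdname write_section
#' @param manifest_path Path to the `.json` manifest.
#' @export
read_section <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  channels <- list(); roles <- character(0)
  for (ch in man$channels) {
    f <- file.path(dir, ch$file)
    if (!file.exists(f))
      stop("manifest channel '", ch$name, "' refers to missing file ", ch$file)
    channels[[ch$name]] <- as.matrix(utils::read.table(f))
    dimnames(channels[[ch$name]]) <- NULL
    roles[ch$name] <- ch$role %||% NA_character_
  }
  section_image(channels, pixel_size = man$pixel_size,
                channel_roles = roles[!is.na(roles)])
}

#' Write a stratification profile as CSV
#' @param profile A [stratification_profile].
#' @param path CSV path (columns `depth_pct`, `signal`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(depth_pct = profile$depth_bins,
                              signal = profile$signal),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a density recovery profile as CSV
#' @param drp A `drp` (fitted or not).
#' @param path CSV path (columns `r_mid_um`, `density_per_mm2`, and when
#'   fitted `fit`, `ci_lo`, `ci_hi`).
#' @return `path`, invisibly.
#' @export
write_drp <- function(drp, path) {
  df <- data.frame(r_mid_um = drp$r_mid, density_per_mm2 = drp$density)
  if (!is.null(drp$fit)) df$fit <- drp$fit
  if (!is.null(drp$ci99)) { df$ci_lo <- drp$ci99[1, ]; df$ci_hi <- drp$ci99[2, ] }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
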