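## Morphometry of traced neurons (SWC trees): total neurite length,
## branch points, dendritic stratification in the IPL, and the
## four-way stratification subtype classification.

#' Construct a neuron morphology
#'
#' A rooted tree of 3-D neurite points with radii (SWC semantics:
#' type 1 = soma, 2 = axon, 3 = basal dendrite, 4 = apical dendrite).
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`
#'   (um), `radius` (um), `parent` (-1 for the root). Exactly one root;
#'   every node must be reachable from it.
#' @return Object of class `morphology` (the validated node table).
#' @export
morphology <- function(nodes) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes)))
    stop("nodes must have columns: ", paste(req, collapse = ", "))
  nodes <- nodes[, req]
  nodes$id <- as.integer(nodes$id); nodes$parent <- as.integer(nodes$parent)
  nodes$type <- as.integer(nodes$type)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (any(!is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L)
    stop(sprintf("expected exactly one root (parent = -1), found %d",
                 length(roots)))
  missing_parent <- setdiff(nodes$parent, c(-1L, nodes$id))
  if (length(missing_parent))
    stop("missing parent id(s): ", paste(missing_parent, collapse = ", "))
  # reachability from the root proves the graph is one acyclic tree
  kids <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  reached <- integer(0); frontier <- nodes$id[roots]
  while (length(frontier)) {
    reached <- c(reached, frontier)
    frontier <- unlist(kids[as.character(frontier)], use.names = FALSE)
  }
  orphans <- setdiff(nodes$id, reached)
  if (length(orphans))
    stop("disconnected or cyclic nodes (unreachable from root): ",
         paste(sort(orphans), collapse = ", "))
  class(nodes) <- c("morphology", "data.frame")
  nodes
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("morphology: %d nodes (%d soma, %d axon, %d dendrite)\n",
              nrow(x), sum(x$type == 1L), sum(x$type == 2L),
              sum(x$type >= 3L)))
  invisible(x)
}

#' Read / write SWC morphology files
#'
#' Standard 7-column whitespace-delimited SWC
#' (`id type x y z radius parent`), `#` comments allowed. Reading
#' validates the tree (unique ids, one root, no cycles, no missing
#' parents); `write_swc(read_swc(f))` is the identity on valid files.
#'
#' @param path File path.
#' @return `read_swc`: a [morphology]. `write_swc`: `path`, invisibly.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no SWC records in ", path)
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop(sprintf("malformed SWC record (7 columns expected) at data line %d",
                 bad[1]))
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (any(!is.finite(m))) stop("non-numeric field in SWC file ", path)
  morphology(data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                        z = m[, 5], radius = m[, 6], parent = m[, 7]))
}

#' @rdname read_swc
#' @param m A [morphology].
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   m$id, m$type, m$x, m$y, m$z, m$radius, m$parent)
  writeLines(c("# SWC export (id type x y z radius parent; um)", lines), path)
  invisible(path)
}

## internal: child/parent segment table with 3-D lengths; child node
## type decides whether the segment is soma/axon/dendrite
segment_table <- function(m) {
  idx <- match(m$parent, m$id)
  has_parent <- !is.na(idx)
  child <- which(has_parent)
  parent <- idx[has_parent]
  data.frame(child = child, parent = parent, type = m$type[child],
             length = sqrt((m$x[child] - m$x[parent])^2 +
                           (m$y[child] - m$y[parent])^2 +
                           (m$z[child] - m$z[parent])^2))
}

#' Total neurite length
#'
#' Sum of Euclidean lengths of all parent-child segments whose child is
#' a neurite node. Soma segments are always excluded; axon (type 2)
#' segments are excluded by default because stratification analysis
#' concerns dendrites.
#'
#' @param m A [morphology].
#' @param include_axon Include SWC type-2 segments (default `FALSE`).
#' @return Total length in um.
#' @export
total_neurite_length <- function(m, include_axon = FALSE) {
  stopifnot(inherits(m, "morphology"))
  seg <- segment_table(m)
  keep <- seg$type != 1L & (include_axon | seg$type != 2L)
  sum(seg$length[keep])
}

#' Number of branch points
#'
#' Non-soma nodes with two or more children.
#'
#' @param m A [morphology].
#' @return Integer count.
#' @export
branch_points <- function(m) {
  stopifnot(inherits(m, "morphology"))
  n_children <- table(factor(m$parent, levels = m$id))
  sum(n_children >= 2L & m$type != 1L)
}

#' Construct an IPL depth frame
#'
#' Maps z (um) to percent IPL depth:
#' `depth = 100 (z - gcl_border_z) / (inl_border_z - gcl_border_z)`,
#' so the GCL border reads 0% and the INL border 100%.
#'
#' @param gcl_border_z,inl_border_z Border z positions in um (distinct).
#' @return Object of class `ipl_frame`.
#' @export
ipl_frame <- function(gcl_border_z, inl_border_z) {
  if (gcl_border_z == inl_border_z) stop("IPL borders must be distinct")
  structure(list(gcl_border_z = gcl_border_z, inl_border_z = inl_border_z),
            class = "ipl_frame")
}

#' Convert z to percent IPL depth
#' @param frame An [ipl_frame].
#' @param z z coordinates in um.
#' @return Depth in percent.
#' @export
ipl_depth <- function(frame, z) {
  100 * (z - frame$gcl_border_z) / (frame$inl_border_z - frame$gcl_border_z)
}

#' Dendritic stratification distribution
#'
#' Dendritic length per IPL-depth bin: each dendritic segment's length
#' is apportioned across the depth bins it traverses by linear
#' interpolation, then normalized to peak 1. The unnormalized mass is
#' retained (its total equals [total_neurite_length] of the dendrites).
#' Nodes slightly outside the IPL (within [-10, 110]% depth) are
#' tolerated with a warning and clamped; nodes beyond that are an error.
#'
#' @param m A [morphology].
#' @param frame An [ipl_frame] (default: the frame attached by
#'   [gen_morphology], if any).
#' @param bin Bin width in percent depth (default 2).
#' @param include_axon Include SWC type-2 segments (default `FALSE`).
#' @return A [stratification_profile].
#' @export
stratification_distribution <- function(m, frame = attr(m, "ipl_frame"),
                                        bin = 2, include_axon = FALSE) {
  stopifnot(inherits(m, "morphology"))
  if (is.null(frame)) stop("an ipl_frame is required")
  if (bin <= 0 || bin > 100) stop("bin must be in (0, 100]")
  seg <- segment_table(m)
  seg <- seg[seg$type != 1L & (include_axon | seg$type != 2L), ]
  if (!nrow(seg)) stop("no dendritic segments")
  d_child <- ipl_depth(frame, m$z[seg$child])
  d_parent <- ipl_depth(frame, m$z[seg$parent])
  # tolerance applies to dendritic nodes; a soma parent endpoint (the
  # primary-dendrite attachment) legitimately sits outside the IPL
  out_of_ipl <- c(d_child, d_parent[m$type[seg$parent] != 1L])
  if (any(out_of_ipl < -10 | out_of_ipl > 110))
    stop(sprintf("%d segment endpoint(s) beyond [-10, 110]%% IPL depth",
                 sum(out_of_ipl < -10 | out_of_ipl > 110)))
  n_tol <- sum(out_of_ipl < 0 | out_of_ipl > 100)
  if (n_tol > 0)
    warning(sprintf("%d dendritic endpoint(s) outside [0, 100]%% depth clamped",
                    n_tol))
  d_child <- pmin(pmax(d_child, 0), 100)
  d_parent <- pmin(pmax(d_parent, 0), 100)
  edges <- seq(0, 100, by = bin)
  if (edges[length(edges)] < 100) edges <- c(edges, 100)
  n_bins <- length(edges) - 1L
  mass <- numeric(n_bins)
  lo <- pmin(d_child, d_parent); hi <- pmax(d_child, d_parent)
  for (k in seq_len(nrow(seg))) {
    if (hi[k] == lo[k]) {
      i <- min(max(findInterval(lo[k], edges, rightmost.closed = TRUE), 1L),
               n_bins)
      mass[i] <- mass[i] + seg$length[k]
    } else {
      ov <- pmin(edges[-1], hi[k]) - pmax(edges[-(n_bins + 1L)], lo[k])
      ov[ov < 0] <- 0
      mass <- mass + seg$length[k] * ov / (hi[k] - lo[k])
    }
  }
  stratification_profile(depth_bins = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                         signal = if (max(mass) > 0) mass else
                           stop("all dendritic mass outside the IPL"),
                         mass = mass)
}

## internal: local maxima with topographic prominence on a signal in
## [0, 1]; returns indices sorted by height (plateaus collapse to their
## first index)
find_peaks <- function(sig, min_prominence) {
  n <- length(sig)
  if (n < 3L) return(integer(0))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (sig[i] > sig[i - 1L]) {
      j <- i
      while (j < n && sig[j + 1L] == sig[j]) j <- j + 1L
      if (j <= n - 1L && sig[j + 1L] < sig[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  keep <- vapply(cand, function(p) {
    left <- sig[seq_len(p)]
    higher_l <- which(left > sig[p])
    base_l <- if (length(higher_l)) min(left[max(higher_l):p]) else min(left)
    right <- sig[p:n]
    higher_r <- which(right > sig[p])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    (sig[p] - max(base_l, base_r)) >= min_prominence
  }, logical(1))
  cand[keep][order(sig[cand[keep]], decreasing = TRUE)]
}

#' Classify a cell's stratification subtype
#'
#' Detects profile peaks above a prominence threshold, keeps those
#' carrying at least `min_peak_fraction` of the dendritic mass, maps
#' their depths to the S1-S5 strata, and emits one of the four
#' stratification subtypes (`bistratified_S2S4`, `mono_ON_S4`,
#' `mono_ON_S5`, `mono_OFF_S1`) or `unclassified`.
#'
#' @param profile A [stratification_profile].
#' @param prominence Minimum peak prominence on the peak-normalized
#'   profile (default 0.2).
#' @param min_peak_fraction Minimum share of dendritic mass per peak
#'   (default 0.15); mass is partitioned at the minima between peaks.
#' @return Object of class `subtype_call`: `call`, `peak_depths`
#'   (percent, sorted), `peak_fractions`, `strata`.
#' @export
classify_subtype <- function(profile, prominence = 0.2,
                             min_peak_fraction = 0.15) {
  stopifnot(inherits(profile, "stratification_profile"))
  sig <- profile$signal
  mass <- if (!is.null(profile$mass)) profile$mass else sig
  peaks <- find_peaks(sig, prominence)
  if (!length(peaks))
    return(structure(list(call = "unclassified", peak_depths = numeric(0),
                          peak_fractions = numeric(0), strata = character(0)),
                     class = "subtype_call"))
  peaks <- sort(peaks)
  # partition mass at the minima between consecutive peaks
  cuts <- c(0L, vapply(seq_len(length(peaks) - 1L), function(k) {
    span <- peaks[k]:peaks[k + 1L]
    span[which.min(sig[span])]
  }, integer(1)), length(sig))
  frac <- vapply(seq_along(peaks), function(k)
    sum(mass[(cuts[k] + 1L):cuts[k + 1L]]) / sum(mass), numeric(1))
  keep <- frac >= min_peak_fraction
  peaks <- peaks[keep]; frac <- frac[keep]
  depths <- profile$depth_bins[peaks]
  scheme <- profile$layer_scheme
  stratum_of <- function(d) {
    hit <- which(d >= scheme$lo & (d < scheme$hi | (scheme$hi == 100 & d <= 100)))
    scheme$layer[hit[1]]
  }
  strata <- vapply(depths, stratum_of, character(1))
  uniq <- sort(unique(strata))
  call <- if (identical(uniq, c("S2", "S4"))) "bistratified_S2S4"
          else if (identical(uniq, "S4")) "mono_ON_S4"
          else if (identical(uniq, "S5")) "mono_ON_S5"
          else if (identical(uniq, "S1")) "mono_OFF_S1"
          else "unclassified"
  ord <- order(depths)
  structure(list(call = call, peak_depths = depths[ord],
                 peak_fractions = frac[ord], strata = strata[ord]),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("subtype: %s", x$call))
  if (length(x$peak_depths))
    cat(sprintf("  (peaks at %s%% depth)",
                paste(sprintf("%.0f", x$peak_depths), collapse = ", ")))
  cat("\n")
  invisible(x)
}
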