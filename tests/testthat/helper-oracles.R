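# Independent oracles and hand-built fixtures. These stay deliberately
# naive (double loops, explicit sums) so they never share code with the
# implementation they check.

brute_force_nnd <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

brute_force_min_pairdist <- function(x, y) {
  best <- Inf
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (j <= i) next
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d < best) best <- d
  }
  best
}

brute_force_edge_sum <- function(m, types = c(3L, 4L)) {
  total <- 0
  for (k in seq_len(nrow(m))) {
    if (m$parent[k] == -1L) next
    if (!(m$type[k] %in% types)) next
    p <- which(m$id == m$parent[k])
    total <- total + sqrt((m$x[k] - m$x[p])^2 + (m$y[k] - m$y[p])^2 +
                          (m$z[k] - m$z[p])^2)
  }
  total
}

brute_force_branch_points <- function(m) {
  n <- 0L
  for (k in seq_len(nrow(m))) {
    if (m$type[k] == 1L) next
    if (sum(m$parent == m$id[k]) >= 2L) n <- n + 1L
  }
  n
}

# perfect binary dendritic tree of the given depth (root is a dendrite)
perfect_binary_morphology <- function(depth) {
  nodes <- data.frame(id = 1L, type = 3L, x = 0, y = 0, z = 0,
                      radius = 1, parent = -1L)
  frontier <- 1L
  for (lev in seq_len(depth)) {
    new_frontier <- integer(0)
    for (p in frontier) {
      for (side in c(-1, 1)) {
        id <- nrow(nodes) + 1L
        nodes[id, ] <- list(id, 3L, nodes$x[p] + side * 2^(depth - lev),
                            nodes$y[p] + 1, 0, 1, p)
        new_frontier <- c(new_frontier, id)
      }
    }
    frontier <- new_frontier
  }
  morphology(nodes)
}

# binomial (conditionally uniform) pattern with exactly n points, for
# equal-n comparisons against lattice patterns
with_fixed_uniform <- function(n, seed, window = c(0, 0, 1000, 1000)) {
  set.seed(seed + 10000L)
  point_pattern(runif(n, window[1], window[3]),
                runif(n, window[2], window[4]), window, label = "uniform")
}

# trial with exactly k evenly spaced spikes in a 2 s sweep
direction_trial_with_count <- function(direction, k, sweep = 2) {
  spikes <- if (k > 0) seq(0.01, sweep - 0.01, length.out = k) else numeric(0)
  stimulus_trial(spike_train(spikes, 0, sweep),
                 list(kind = "grating", direction_deg = direction, trial = 1L),
                 list(stim_on = c(0, sweep)))
}

# flat section with analytically known content: intensity r + c is
# linear, so bilinear resampling reproduces it exactly
flat_linear_section <- function(width = 60, height = 80) {
  ch <- outer(seq_len(height), seq_len(width), `+`)
  section_image(list(signal = ch), pixel_size = 1,
                channel_roles = c(signal = "marker"))
}
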