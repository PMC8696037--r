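test_that("generators reject degenerate inputs", {
  expect_error(gen_poisson_pattern(0, c(0, 0, 100, 100), seed = 1),
               "density")
  expect_error(gen_poisson_pattern(100, c(0, 0, 0, 100), seed = 1), "area")
  expect_error(gen_hardcore_pattern(100, -1, c(0, 0, 100, 100), seed = 1),
               "dmin")
  expect_error(gen_spike_train(2, 0.1, 1, seed = 1), "n_spikes")
  expect_error(gen_morphology(strat_depths = c(10, 50, 90), seed = 1),
               "1 or 2 planes")
  expect_error(gen_curved_section(band_depths = 130, seed = 1), "band_depths")
})

test_that("generators are pure functions of parameters and seed", {
  for (gen in list(
    function(s) gen_poisson_pattern(80, c(0, 0, 1000, 1000), seed = s),
    function(s) gen_hardcore_pattern(80, 40, c(0, 0, 1000, 1000), seed = s),
    function(s) gen_jittered_lattice(100, 5, c(0, 0, 1000, 1000), seed = s))) {
    a <- gen(42L); b <- gen(42L); c <- gen(43L)
    expect_identical(a$x, b$x)
    expect_identical(a$y, b$y)
    expect_false(identical(a$x, c$x))
  }
  a <- gen_direction_trials(90, 4, 20, 2, seed = 7)
  b <- gen_direction_trials(90, 4, 20, 2, seed = 7)
  expect_identical(lapply(a, function(t) t$train$spikes),
                   lapply(b, function(t) t$train$spikes))
  g1 <- gen_curved_section(noise_sd = 0, seed = 3)
  g2 <- gen_curved_section(noise_sd = 0, seed = 3)
  expect_identical(g1$section$channels, g2$section$channels)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  gen_poisson_pattern(50, c(0, 0, 500, 500), seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("Poisson pattern counts follow the Poisson law", {
  counts <- vapply(1:200, function(s)
    npoints(gen_poisson_pattern(100, c(0, 0, 2000, 2000), seed = s)),
    numeric(1))
  # expected count 400; each seed within 3 sd in >= 99% of seeds
  expect_gte(mean(abs(counts - 400) <= 3 * sqrt(400)), 0.99)
  expect_lt(abs(mean(counts) - 400), 3 * sqrt(400 / 200))
})

test_that("hard-core pattern honors dmin exhaustively", {
  p <- gen_hardcore_pattern(100, 50, c(0, 0, 1500, 1500), seed = 5)
  expect_equal(npoints(p), 225)
  expect_gte(brute_force_min_pairdist(p$x, p$y), 50)
  expect_identical(p$ground_truth$params$dmin, 50)
})

test_that("infeasible hard-core packing fails explicitly", {
  # hexagonal bound for dmin = 100 um is ~115/mm^2
  expect_error(
    gen_hardcore_pattern(200, 100, c(0, 0, 1000, 1000), seed = 1),
    "packing bound")
  # feasible by the bound but unreachable by dart throwing
  expect_error(
    gen_hardcore_pattern(110, 100, c(0, 0, 1000, 1000), seed = 1,
                         max_attempts = 2000L),
    "achieved density")
})

test_that("jittered lattice reduces NND dispersion relative to Poisson", {
  # jitter-free lattice: interior points sit exactly one spacing apart
  lat0 <- gen_jittered_lattice(100, 0, c(0, 0, 1000, 1000), seed = 1)
  st0 <- compute_nnd(lat0)
  expect_true(all(abs(st0$nnd - 100) < 1e-9))
  cv <- function(p) { s <- compute_nnd(p); s$sd_nnd / s$mean_nnd }
  wins <- vapply(1:20, function(s) {
    lat <- gen_jittered_lattice(100, 5, c(0, 0, 1000, 1000), seed = s)
    n <- npoints(lat)
    unif <- with_fixed_uniform(n, s)
    cv(lat) < cv(unif)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("spike train realizes the configured ISI ratio exactly", {
  tr <- gen_spike_train(10, first_isi = 0.05, isi_ratio = 2, seed = 1)
  isi <- diff(tr$spikes)
  expect_equal(isi[1], 0.05)
  expect_equal(isi[length(isi)], 0.1)
  expect_equal(isi[length(isi)] / isi[1], 2)
  reg <- gen_spike_train(5, 0.1, 1, seed = 1)
  expect_true(all(abs(diff(reg$spikes) - 0.1) < 1e-12))
})

test_that("direction trials realize the von Mises count profile", {
  # kappa = 0: all directions share one expected count
  trials <- gen_direction_trials(0, 0, 30, 50, seed = 11)
  counts <- vapply(trials, function(t) length(t$train$spikes), numeric(1))
  dirs <- vapply(trials, function(t) t$condition$direction_deg, numeric(1))
  per_dir <- tapply(counts, dirs, mean)
  expect_true(all(abs(per_dir - 30) < 3 * sqrt(30 / 50)))
  # total expected count equals the integral of the rate profile (2 MC SE)
  kappa <- 2; base <- 30; dirs8 <- seq(0, 315, by = 45)
  trials <- gen_direction_trials(90, kappa, base, 25, directions = dirs8,
                                 seed = 12)
  expected <- 25 * sum(base * exp(kappa * (cos((dirs8 - 90) * pi / 180) - 1)))
  total <- sum(vapply(trials, function(t) length(t$train$spikes), numeric(1)))
  expect_lt(abs(total - expected), 2 * sqrt(expected))
})

test_that("flash trials place spikes in the class-appropriate windows", {
  expect_warning(
    gen_flash_trials("ON", diameters = 300, on_rate = 5, baseline_rate = 5,
                     n_trials = 1, seed = 1),
    "unrecoverable")
  trials <- gen_flash_trials("ON", diameters = 300, on_rate = 40,
                             baseline_rate = 2, n_trials = 60, seed = 2)
  frac_on_heavier <- mean(vapply(trials, function(t) {
    count_spikes(t$train, t$epochs$stim_on) >
      count_spikes(t$train, t$epochs$stim_off)
  }, logical(1)))
  expect_gte(frac_on_heavier, 0.95)
  # ON-OFF: both 300 ms edge windows elevated above baseline rate
  oo <- gen_flash_trials("ON-OFF", diameters = 300, on_rate = 40,
                         baseline_rate = 2, n_trials = 60, seed = 3)
  edge_on <- mean(vapply(oo, function(t)
    count_spikes(t$train, t$epochs$stim_on[1] + c(0, 0.3)), numeric(1)))
  edge_off <- mean(vapply(oo, function(t)
    count_spikes(t$train, t$epochs$stim_off[1] + c(0, 0.3)), numeric(1)))
  expect_gt(edge_on / 0.3, 20)
  expect_gt(edge_off / 0.3, 20)
  # total expected count equals the rate-profile integral (2 MC SE)
  on <- gen_flash_trials("ON", diameters = 300, on_rate = 40,
                         baseline_rate = 2, n_trials = 200, seed = 4)
  expected <- 200 * (2 * 1 + 40 * 2 + 2 * 2)   # size profile peaks at 300 um
  total <- sum(vapply(on, function(t) length(t$train$spikes), numeric(1)))
  expect_lt(abs(total - expected), 2 * sqrt(expected))
})

test_that("generated morphology round-trips through SWC", {
  m <- gen_morphology(strat_depths = c(30, 70), seed = 8)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(m2$x, m$x)
  expect_equal(m2$z, m$z)
  expect_identical(m2$parent, m$parent)
  expect_identical(m2$type, m$type)
})

test_that("curved section fixture carries consistent truth", {
  g <- gen_curved_section(boundary_amplitude = 0, noise_sd = 0, seed = 9)
  expect_true(all(diff(g$truth_curves$top) == 0))      # already straight
  expect_true(all(g$truth_curves$bottom > g$truth_curves$top))
  g2 <- gen_curved_section(boundary_amplitude = 12, band_depths = c(30, 70),
                           seed = 10)
  expect_length(g2$section$channels, 3L)
  expect_error(gen_curved_section(boundary_amplitude = 80, seed = 1),
               "amplitude")
})
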