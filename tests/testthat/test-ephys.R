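test_that("adaptation index follows both stated formulas", {
  # regular train: exactly 0 under both variants (a binary-representable
  # interval keeps all spike times exact; a decimal one is exact only to
  # the accumulation rounding)
  reg <- gen_spike_train(10, 0.125, 1, seed = 1)
  expect_identical(as.numeric(adaptation_index(reg, "literal")), 0)
  expect_identical(as.numeric(adaptation_index(reg, "decay_positive")), 0)
  reg100ms <- gen_spike_train(10, 0.1, 1, seed = 1)
  expect_equal(as.numeric(adaptation_index(reg100ms, "literal")), 0,
               tolerance = 1e-12)
  # direct evaluation: spikes at 0, .1, .2, .3, .5 s
  tr <- spike_train(c(0, 0.1, 0.2, 0.3, 0.5))
  expect_equal(as.numeric(adaptation_index(tr, "literal")), -1)
  expect_equal(as.numeric(adaptation_index(tr, "decay_positive")), 0.5)
  # generator round trip: literal = 1 - isi_ratio, exactly
  for (rho in c(0.25, 0.5, 1, 2, 4)) {
    g <- gen_spike_train(12, 0.02, rho, seed = 1)
    expect_equal(as.numeric(adaptation_index(g, "literal")), 1 - rho,
                 tolerance = 1e-12)
  }
  # algebraic relation between the variants
  for (s in 1:10) {
    g <- gen_spike_train(8, 0.05, 0.3 + s / 4, seed = s)
    lit <- as.numeric(adaptation_index(g, "literal"))
    dec <- as.numeric(adaptation_index(g, "decay_positive"))
    expect_equal(lit, 1 - 1 / (1 - dec), tolerance = 1e-10)
  }
  expect_error(adaptation_index(spike_train(c(0, 0.1))), "3 spikes")
})

test_that("fi_curve is count over duration, averaged over trials", {
  mk <- function(spikes, pA) stimulus_trial(
    spike_train(spikes, 0, 1), list(kind = "current_step", current_pA = pA),
    list(step = c(0.25, 0.75)))
  trials <- list(mk(seq(0.3, 0.7, length.out = 10), 100),
                 mk(numeric(0), 50))
  fi <- fi_curve(trials)
  expect_equal(fi$rate_hz[fi$current_pA == 100], 20)
  expect_equal(fi$rate_hz[fi$current_pA == 50], 0)
  # additive over trial concatenation (weighted mean)
  t1 <- list(mk(c(0.3, 0.4), 100)); t2 <- list(mk(c(0.3, 0.4, 0.5, 0.6), 100))
  both <- fi_curve(c(t1, t2))
  expect_equal(both$rate_hz,
               (fi_curve(t1)$rate_hz + fi_curve(t2)$rate_hz) / 2)
  # Poisson generator recovery at rate lambda
  lam <- 30
  set.seed(1)
  ptrials <- lapply(1:100, function(i) {
    k <- rpois(1, lam * 0.5)
    mk(sort(runif(k, 0.25, 0.75)), 80)
  })
  fi <- fi_curve(ptrials)
  expect_lt(abs(fi$rate_hz - lam), 3 * sqrt(lam / (0.5 * 100)))
})

test_that("flash classification recovers generated classes", {
  for (cls in c("ON", "OFF", "ON-OFF")) {
    trials <- gen_flash_trials(cls, on_rate = 40, baseline_rate = 2,
                               n_trials = 10, seed = 21 + nchar(cls))
    expect_identical(classify_flash_response(trials)$call, cls)
  }
  # baseline-only activity: unresponsive
  base_only <- gen_flash_trials("ON", on_rate = 40, baseline_rate = 2,
                                n_trials = 10, seed = 30)
  flat <- lapply(base_only, function(t) {
    keep <- t$train$spikes < 1                       # baseline epoch only
    stimulus_trial(spike_train(t$train$spikes[keep], 0, t$train$t1),
                   t$condition, t$epochs)
  })
  expect_identical(classify_flash_response(flat)$call, "unresponsive")
  # silent baseline triggers the logged Poisson fallback, not a crash
  silent <- gen_flash_trials("ON", on_rate = 40, baseline_rate = 0,
                             n_trials = 5, seed = 31)
  fc <- classify_flash_response(silent)
  expect_true(fc$fallback)
  expect_identical(fc$call, "ON")
})

test_that("spot-size tuning summarizes and normalizes per cell", {
  trials <- gen_flash_trials("ON", on_rate = 40, baseline_rate = 2,
                             n_trials = 20, seed = 32)
  tune <- spot_size_tuning(trials)
  expect_equal(max(tune$norm_rate), 1)
  expect_equal(tune$diameter_um, sort(unique(c(50, 100, 200, 300, 600, 1200))))
  # generator rate profile peaks at 300 um
  expect_equal(tune$diameter_um[which.max(tune$rate_hz)], 300)
  # identical responses at all sizes -> flat tuning
  mk <- function(d) stimulus_trial(
    spike_train(c(1.1, 1.5, 1.9), 0, 5),
    list(kind = "flash", diameter_um = d),
    list(baseline = c(0, 1), stim_on = c(1, 3), stim_off = c(3, 5)))
  flat <- spot_size_tuning(lapply(c(50, 200, 800), mk))
  expect_true(all(flat$norm_rate == 1))
})

test_that("DSI satisfies its vector-sum properties", {
  dirs <- seq(0, 315, by = 45)
  # equal counts cancel
  eq <- direction_tuning(lapply(dirs, direction_trial_with_count, k = 7))
  expect_lte(eq$dsi, 1e-12)
  # all spikes in one direction: DSI = 1 at that direction
  one <- direction_tuning(lapply(dirs, function(d)
    direction_trial_with_count(d, if (d == 135) 12 else 0)))
  expect_equal(one$dsi, 1)
  expect_equal(one$pref_dir, 135)
  # all-zero counts: undefined, flagged
  zero <- direction_tuning(lapply(dirs, direction_trial_with_count, k = 0))
  expect_true(zero$undefined)
  expect_true(is.na(zero$dsi))
  # DSI in [0, 1] for arbitrary non-negative counts; invariant to order
  set.seed(5)
  for (i in 1:20) {
    counts <- rpois(8, 6)
    if (all(counts == 0)) counts[1] <- 1
    trials <- mapply(direction_trial_with_count, dirs, counts,
                     SIMPLIFY = FALSE)
    dt <- direction_tuning(trials)
    expect_gte(dt$dsi, 0); expect_lte(dt$dsi, 1)
    dt_shuf <- direction_tuning(sample(trials))
    expect_equal(dt_shuf$dsi, dt$dsi)
    expect_equal(dt_shuf$pref_dir, dt$pref_dir)
    # rotating the stimulus frame rotates the preferred direction
    rot <- mapply(direction_trial_with_count, (dirs + 90) %% 360, counts,
                  SIMPLIFY = FALSE)
    dr <- direction_tuning(rot)
    expect_equal(dr$dsi, dt$dsi, tolerance = 1e-9)
    expect_equal(dr$pref_dir %% 360, (dt$pref_dir + 90) %% 360,
                 tolerance = 1e-6)
  }
})

test_that("preferred direction is recovered from tuned generators", {
  hits <- vapply(1:20, function(s) {
    trials <- gen_direction_trials(90, kappa = 8, base_count = 50,
                                   n_trials = 10, seed = 600 + s)
    dt <- direction_tuning(trials)
    diff <- abs(dt$pref_dir - 90) %% 360
    min(diff, 360 - diff) <= 45
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # pref/null variant stays in [-1, 1] and agrees on the winner
  trials <- gen_direction_trials(180, 8, 50, 10, seed = 700)
  pn <- direction_tuning(trials, dsi_mode = "pref_null")
  expect_gte(pn$dsi, 0); expect_lte(pn$dsi, 1)
})
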