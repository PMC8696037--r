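test_that("compute_nnd matches the brute-force oracle exactly", {
  p <- point_pattern(c(0, 10), c(0, 0), c(-5, -5, 15, 5))
  st <- compute_nnd(p)
  expect_equal(st$nnd, c(10, 10))
  expect_equal(st$mean_nnd, 10)
  expect_equal(st$sem_nnd, st$sd_nnd / sqrt(2))
  for (s in 1:5) {
    pat <- gen_poisson_pattern(120, c(0, 0, 1200, 1200), seed = s)
    expect_identical(compute_nnd(pat)$nnd, brute_force_nnd(pat$x, pat$y))
  }
  expect_error(compute_nnd(point_pattern(1, 1, c(0, 0, 2, 2))), "n < 2")
})

test_that("regularity index follows its formula in both modes", {
  # arithmetic check of the stated formula: mean / SEM
  st <- structure(list(nnd = NULL, mean_nnd = 54.04, sd_nnd = 31.79 * sqrt(10),
                       sem_nnd = 31.79, n = 10L), class = "nnd_stats")
  expect_equal(regularity_index(st, "sem")$ri, 54.04 / 31.79, tolerance = 1e-12)
  expect_equal(round(regularity_index(st, "sem")$ri, 1), 1.7)
  # mode relation ri_sem = ri_sd * sqrt(n) to 1e-10 relative
  for (s in 1:10) {
    pat <- gen_poisson_pattern(100, c(0, 0, 1000, 1000), seed = s)
    stats <- compute_nnd(pat)
    r_sem <- regularity_index(stats, "sem")$ri
    r_sd <- regularity_index(stats, "sd")$ri
    expect_equal(r_sem, r_sd * sqrt(stats$n), tolerance = 1e-10)
  }
  # zero dispersion -> explicit infinite flag, not a crash
  lat <- gen_jittered_lattice(100, 0, c(0, 0, 600, 600), seed = 1)
  ri <- regularity_index(compute_nnd(lat))
  expect_true(ri$infinite)
  expect_identical(ri$ri, Inf)
})

test_that("regular mosaics score higher RI than random ones", {
  wins_sem <- logical(20); wins_sd <- logical(20)
  for (s in 1:20) {
    lat <- gen_jittered_lattice(100, 5, c(0, 0, 1000, 1000), seed = s)
    unif <- with_fixed_uniform(npoints(lat), s)
    ri_l <- compute_nnd(lat); ri_u <- compute_nnd(unif)
    wins_sem[s] <- regularity_index(ri_l, "sem")$ri >
      regularity_index(ri_u, "sem")$ri
    wins_sd[s] <- regularity_index(ri_l, "sd")$ri >
      regularity_index(ri_u, "sd")$ri
  }
  expect_gte(mean(wins_sem), 0.95)
  expect_gte(mean(wins_sd), 0.95)
})

test_that("RI(sd) does not decrease with the exclusion radius", {
  wins <- vapply(1:20, function(s) {
    lo <- gen_hardcore_pattern(80, 20, c(0, 0, 1200, 1200), seed = s)
    hi <- gen_hardcore_pattern(80, 60, c(0, 0, 1200, 1200), seed = s)
    regularity_index(compute_nnd(hi), "sd")$ri >=
      regularity_index(compute_nnd(lo), "sd")$ri
  }, logical(1))
  expect_gte(mean(wins), 0.90)
})

test_that("DRP reproduces a hand-counted configuration", {
  # three collinear points 10 um apart; one annulus [0, 15) catches only
  # the 10 um neighbors: counts 1, 2, 1 -> mean 4/3
  p <- point_pattern(c(0, 10, 20), c(0, 0, 0), c(-1, -1, 21, 1))
  drp <- density_recovery_profile(p, dr = 15, r_max = 15, edge_policy = "none")
  expect_equal(unname(colMeans(drp$per_point_counts)), 4 / 3)
  expect_equal(drp$density, (4 / 3) / (pi * 15^2 / 1e6))
})

test_that("DRP conserves neighbor counts and respects the hard core", {
  pat <- gen_hardcore_pattern(100, 50, c(0, 0, 1500, 1500), seed = 3)
  drp <- density_recovery_profile(pat, dr = 10, r_max = 200)
  # annuli wholly below dmin are exactly empty
  below <- drp$radii + drp$dr <= 50
  expect_true(all(drp$density[below] == 0))
  expect_gt(sum(drp$density[!below]), 0)
  # row sums equal each reference point's neighbors within r_max, exactly
  ref_in_core <- which(pat$x >= 200 & pat$x <= 1300 &
                       pat$y >= 200 & pat$y <= 1300)
  for (k in seq_len(min(10, length(ref_in_core)))) {
    i <- ref_in_core[k]
    d <- sqrt((pat$x - pat$x[i])^2 + (pat$y - pat$y[i])^2)
    expect_identical(sum(drp$per_point_counts[k, ]),
                     sum(d > 0 & d < 200))
  }
})

test_that("DRP edge policy guards r_max", {
  pat <- gen_poisson_pattern(100, c(0, 0, 1000, 1000), seed = 1)
  expect_error(density_recovery_profile(pat, dr = 10, r_max = 600),
               "usable r_max")
  expect_silent(density_recovery_profile(pat, dr = 10, r_max = 600,
                                         edge_policy = "none"))
})

test_that("polynomial DRP fit behaves like nested least squares", {
  pat <- gen_poisson_pattern(150, c(0, 0, 2000, 2000), seed = 2)
  drp <- density_recovery_profile(pat, dr = 10, r_max = 200)
  # constant profile -> constant fit
  flat <- drp
  flat$density <- rep(123, length(drp$density))
  flat_fit <- fit_drp_curve(flat, order = 7, n_boot = 50, seed = 1)
  expect_lt(max(abs(flat_fit$fit_coeffs[-1])), 1e-6 * 123)
  expect_equal(flat_fit$fit, rep(123, length(drp$density)), tolerance = 1e-8)
  # higher order never fits worse at the midpoints
  rss <- vapply(c(2, 4, 7), function(k) {
    f <- fit_drp_curve(drp, order = k, n_boot = 10, seed = 1)
    sum((f$fit - drp$density)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-6 * rss[1]))
  expect_error(fit_drp_curve(drp, order = 25, n_boot = 10, seed = 1),
               "lower order")
  fitted <- fit_drp_curve(drp, order = 7, n_boot = 200, seed = 9)
  expect_equal(dim(fitted$ci99), c(2L, length(drp$radii)))
  expect_true(all(fitted$ci99[1, ] <= fitted$ci99[2, ]))
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  width_at <- function(win, seed) {
    pat <- gen_poisson_pattern(100, win, seed = seed)
    drp <- density_recovery_profile(pat, dr = 20, r_max = 200)
    f <- fit_drp_curve(drp, order = 3, n_boot = 400, seed = seed)
    mean(f$ci99[2, ] - f$ci99[1, ])
  }
  ratios <- vapply(1:3, function(s)
    width_at(c(0, 0, 4400, 4400), s) / width_at(c(0, 0, 2400, 2400), s),
    numeric(1))
  # 4x the area -> ~4x the reference points -> half the width
  expect_lt(abs(mean(ratios) - 0.5), 0.15)
})

test_that("density map normalizes to its modal bin", {
  p <- point_pattern(c(10, 11, 12, 500), c(10, 11, 12, 500),
                     c(0, 0, 1000, 1000))
  dm <- density_map(p, bin = 100)
  expect_equal(max(dm$percent), 100)
  expect_equal(sum(dm$counts), 4L)
  expect_equal(sort(unique(as.numeric(dm$percent))), c(0, 100 / 3, 100))
  expect_error(density_map(point_pattern(numeric(0), numeric(0),
                                         c(0, 0, 1, 1)), 10),
               "empty")
  pat <- gen_poisson_pattern(200, c(0, 0, 2000, 2000), seed = 4)
  expect_equal(sum(density_map(pat, 200)$counts), npoints(pat))
})
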