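# Synthetic generators: Markov rasters against their closed forms, the
# surrogate landscape's shape constraints, slice-like subsampling.

test_that("Markov rasters honour their closed-form statistics", {
  all_on <- synth_raster(markov_raster_spec(5, 20, q = 1, r = 1, seed = 1))
  expect_equal(feature_vector(all_on), c(activity = 1, interval = 0, cv = 0))

  spec <- markov_raster_spec(200, 2400, q = 0.5, r = 0.1, seed = 3)
  expect_equal(spec$stationary, 1 / 6)
  ra <- synth_raster(spec)
  expect_equal(mean(ra$mat), 1 / 6, tolerance = 0.03)

  no_adjacent <- synth_raster(markov_raster_spec(30, 200, q = 0, r = 0.5,
                                                 seed = 5))
  ivs <- unlist(apply(no_adjacent$mat, 1, activation_intervals))
  expect_true(all(ivs >= 1))
  expect_error(markov_raster_spec(5, 5, q = 1.2, r = 0, seed = 1), "q and r")
})

test_that("the surrogate map satisfies its three shape constraints on a 50x50 grid", {
  spec <- surrogate_spec(noise_sd = 0)
  gi <- seq(0.002, 0.02, length.out = 50)
  ge <- seq(0, 2e-5, length.out = 50)
  gr <- expand.grid(g_i = gi, g_e = ge)
  fx <- surrogate_features(gr$g_i, gr$g_e, spec)
  act <- matrix(fx$activity, 50); itv <- matrix(fx$interval, 50)
  cvm <- matrix(fx$cv, 50)
  # activity strictly decreasing in G_I at every G_E; interval increasing
  expect_true(all(apply(act, 2, function(col) all(diff(col) < 0))))
  expect_true(all(apply(itv, 2, function(col) all(diff(col) > 0))))
  # CV: single collapse below g_c at high G_E, none at low G_E
  hi <- cvm[, 50]
  expect_gt(gi[which.max(hi)], 0.006)
  expect_true(all(hi[gi < 0.005] < 0.5 * max(hi)))
  lo <- cvm[, 5]
  expect_gt(min(lo[gi < 0.005]), 0.5)
})

test_that("surrogate point examples and determinism hold", {
  spec <- surrogate_spec(noise_sd = 0)
  f <- function(gi, ge) surrogate_features(gi, ge, spec)
  expect_lt(f(0.018, 1e-5)$activity, f(0.004, 1e-5)$activity)
  expect_lt(f(0.004, 1.8e-5)$cv, f(0.008, 1.8e-5)$cv)
  expect_identical(f(0.01, 1e-5), f(0.01, 1e-5))
  noisy <- surrogate_spec(noise_sd = 0.05)
  expect_identical(surrogate_features(0.01, 1e-5, noisy, seed = 4),
                   surrogate_features(0.01, 1e-5, noisy, seed = 4))
  expect_error(surrogate_features(0.001, 1e-5, spec), "prior box")
  expect_error(surrogate_features(0.01, 3e-5, spec), "prior box")
})

test_that("subsampling keeps cell-averaged features honest", {
  spec <- markov_raster_spec(150, 1000, q = 0.55, r = 0.08, seed = 11)
  ra <- synth_raster(spec)
  full <- slice_like_subsample(ra, nrow(ra$mat), seed = 2)
  expect_identical(feature_vector(full), feature_vector(ra))
  sub <- slice_like_subsample(ra, 30, seed = 2)
  expect_equal(feature_vector(sub)[["activity"]],
               feature_vector(ra)[["activity"]], tolerance = 0.1)
  # the QC metric, by contrast, depends on the number of recorded cells
  f_full <- total_fluctuation(ra, transient_bins = 100)$value
  f_sub <- total_fluctuation(sub, transient_bins = 100)$value
  expect_false(isTRUE(all.equal(f_full, f_sub, tolerance = 1e-6)))
  expect_error(slice_like_subsample(ra, 0, seed = 1), "positive")
  expect_error(slice_like_subsample(ra, 1e4, seed = 1), "exceeds")
})
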