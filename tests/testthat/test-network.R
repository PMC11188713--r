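# Network construction and integration: degree statistics, draw ranges,
# reproducibility, reduction to the isolated cell, monotone suppression.

test_that("connectivity statistics match the construction", {
  np <- network_params(n_cells = 200, p = 0.4, g_i = 0.01, g_e = 1e-5,
                       duration = 10, compensate = FALSE)
  net <- build_network(np, seed = 7)
  expect_false(any(net$edges$src == net$edges$dst))
  expect_equal(nrow(net$edges) / 200, 199 * 0.4, tolerance = 0.05)
  w <- net$edges$weight
  expect_true(all(w >= 0.3125 * 0.01 & w <= 0.9375 * 0.01))
  expect_true(all(net$edges$delay >= 1 & net$edges$delay <= 3))
  expect_true(all(net$drives >= 0.001305 & net$drives <= 0.001305 + 1e-5))

  expect_identical(build_network(np, seed = 7)$edges, net$edges)
  np0 <- network_params(n_cells = 50, p = 0, g_i = 0.01, g_e = 0,
                        duration = 10)
  expect_equal(nrow(build_network(np0, seed = 1)$edges), 0)
})

test_that("parameter validation enforces the stated ranges", {
  expect_error(network_params(g_i = 0.03), "g_i")
  expect_error(network_params(g_e = 3e-5), "g_e")
  expect_error(network_params(p = 1.2), "probability")
  expect_error(network_params(duration = -1), "duration")
  expect_error(build_network(network_params()), "seed")
})

test_that("a one-cell edgeless network reproduces the isolated cell exactly", {
  np <- network_params(n_cells = 1, p = 0, g_i = 0.01, g_e = 0, duration = 5)
  net <- build_network(np, seed = 3)
  sp <- run_network(net)
  iso <- simulate_cell(drive = 0.001305, duration = 5)
  expect_identical(sp$time, iso$spikes)
})

test_that("raster invariants hold and inhibition suppresses spiking", {
  np_lo <- network_params(n_cells = 40, p = 0.4, g_i = 0.002, g_e = 1.5e-5,
                          duration = 20)
  np_hi <- network_params(n_cells = 40, p = 0.4, g_i = 0.02, g_e = 1.5e-5,
                          duration = 20)
  sp_lo <- run_network(build_network(np_lo, seed = 5))
  sp_hi <- run_network(build_network(np_hi, seed = 5))
  # per-cell sorted times within the recording window
  expect_true(all(sp_lo$time >= 0 & sp_lo$time <= 20000))
  expect_true(all(unlist(tapply(sp_lo$time, sp_lo$cell, function(x)
    diff(x) > 0))))
  # same topology and drives, stronger inhibition -> fewer spikes
  expect_gt(nrow(sp_lo), nrow(sp_hi))
  # with inhibition absent every cell fires near its isolated rate
  np0 <- network_params(n_cells = 5, p = 0.4, g_i = 0, g_e = 1.5e-5,
                        duration = 20)
  net0 <- build_network(np0, seed = 9)
  sp0 <- run_network(net0)
  rates <- tabulate(sp0$cell, 5) / 20
  iso <- vapply(net0$drives, function(d)
    simulate_cell(drive = d, duration = 20)$rate, numeric(1))
  expect_true(all(abs(rates - iso) / iso <= 0.02))
})

test_that("sweep sampling covers the prior box reproducibly", {
  sw <- sample_sweep(200, seed = 21)
  expect_equal(nrow(sw), 200)
  expect_true(all(sw$g_i >= 0.002 & sw$g_i <= 0.02))
  expect_true(all(sw$g_e >= 0 & sw$g_e <= 2e-5))
  expect_equal(mean(sw$g_i), 0.011, tolerance = 0.1)
  expect_equal(mean(sw$g_e), 1e-5, tolerance = 0.15)
  expect_identical(sample_sweep(200, seed = 21), sw)
  expect_error(sample_sweep(0, seed = 1), "n must")
})
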