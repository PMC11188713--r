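# Single-cell model: determinism, threshold behaviour, f-I calibration
# surface, first-spike delay.

test_that("simulation is deterministic and silent below rheobase", {
  a <- simulate_cell(drive = 0.001325, duration = 4)
  b <- simulate_cell(drive = 0.001325, duration = 4)
  expect_identical(a$spikes, b$spikes)
  expect_gt(length(a$spikes), 0)

  silent <- simulate_cell(drive = 0.0008, duration = 2)
  expect_length(silent$spikes, 0)
  expect_true(is.na(silent$latency))
})

test_that("spike times are strictly increasing and drive must be valid", {
  tr <- simulate_cell(drive = 0.001325, duration = 3)
  expect_true(all(diff(tr$spikes) > 0))
  expect_error(simulate_cell(drive = 0.001325, dt = 0.2), "dt")
  expect_error(drive_spec(increment = 3e-5), "increment")
  expect_error(drive_spec(increment = -1e-6), "increment")
})

test_that("first-spike latency decreases with drive", {
  lo <- simulate_cell(drive = 0.001305 + 1e-6, duration = 6)
  hi <- simulate_cell(drive = 0.001305 + 2e-5, duration = 6)
  expect_false(is.na(lo$latency))
  expect_false(is.na(hi$latency))
  expect_gt(lo$latency, hi$latency)
})

test_that("f-I curve is non-decreasing over the network drive range", {
  drives <- seq(0.001305, 0.001325, length.out = 10)
  fi <- fI_curve(drives = drives, duration = 10)
  expect_true(all(fi$rate >= 0))
  expect_true(all(diff(fi$rate) >= 0))
  expect_error(fI_curve(drives = numeric(0)), "empty")
  expect_error(fI_curve(drives = rev(drives)), "sorted")
})

test_that("rheobase brackets threshold behaviour", {
  rb <- rheobase(duration = 10)
  expect_lt(rb, 0.001305)
  expect_gte(length(simulate_cell(drive = 1.01 * rb, duration = 10)$spikes), 1)
  expect_length(simulate_cell(drive = 0.99 * rb, duration = 10)$spikes, 0)
})

test_that("halving dt changes the 10 s spike count by at most one spike", {
  n1 <- length(simulate_cell(drive = 0.001325, duration = 10, dt = 0.05)$spikes)
  n2 <- length(simulate_cell(drive = 0.001325, duration = 10, dt = 0.025)$spikes)
  expect_lte(abs(n1 - n2), 1)
})
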