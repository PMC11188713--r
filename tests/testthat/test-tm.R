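# Tsodyks-Markram synapse: closed-form relaxation, spike updates, the
# periodic-train fixed point against direct simulation, and the IPSP
# characterization protocol.

test_that("relaxation follows the closed forms", {
  expect_equal(tm_relax(tm_state(r = 1, s = 0), 500),
               tm_state(r = 1, s = 0, t = 500), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tm_relax(tm_state(r = 0), 222)$r, 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(tm_relax(tm_state(s = 0.5), 1859)$s, 0.5 * exp(-1),
               tolerance = 1e-12)
  expect_error(tm_relax(tm_state(), -1), "dt")
})

test_that("relaxation is a semigroup", {
  set.seed(11)
  for (i in 1:20) {
    st <- tm_state(r = runif(1), s = runif(1), g = runif(1))
    d1 <- runif(1, 0, 500); d2 <- runif(1, 0, 500)
    a <- tm_relax(tm_relax(st, d1), d2)
    b <- tm_relax(st, d1 + d2)
    expect_equal(a$r, b$r, tolerance = 1e-12)
    expect_equal(a$s, b$s, tolerance = 1e-12)
    expect_equal(a$g, b$g, tolerance = 1e-12)
  }
})

test_that("spike update matches hand evaluation with U = 0.41", {
  st <- tm_spike(tm_state(), weight = 1)
  expect_equal(st$s, 0.41)
  expect_equal(st$r, 0.59)
  expect_equal(st$increment, 0.41)
  st2 <- tm_spike(st, weight = 1)       # immediate second spike
  expect_equal(st2$s, 0.41 + 0.41 * 0.59, tolerance = 1e-12)
  expect_equal(st2$r, 0.59 * (1 - st2$s), tolerance = 1e-12)
  u0 <- tm_spike(tm_state(s = 0.3, r = 0.7), weight = 2,
                 params = tm_params(u = 0))
  expect_equal(u0$s, 0.3)
  expect_equal(u0$r, 0.7 * (1 - 0.3))
  expect_equal(tm_spike(tm_state(), 2, tm_params(u = 0))$increment, 0)
})

test_that("R and S stay in [0, 1] on random spike trains", {
  set.seed(42)
  for (rep in 1:20) {
    st <- tm_state()
    for (ev in 1:100) {
      st <- tm_relax(st, rexp(1, rate = 1 / 50))
      st <- tm_spike(st, runif(1, 0, 0.02))
      expect_true(st$r >= 0 && st$r <= 1)
      expect_true(st$s >= 0 && st$s <= 1)
    }
  }
})

test_that("periodic-train fixed point agrees with 100-spike simulation", {
  for (rate in c(1, 5, 20)) {
    analytic <- steady_state_efficacy(rate)
    st <- tm_state()
    period <- 1000 / rate
    eff <- NA
    for (i in 1:100) {
      st <- tm_relax(st, period)
      s_post <- st$s + 0.41 * (1 - st$s)
      eff <- st$r * s_post
      st <- tm_spike(st, 1)
      st$g <- 0
    }
    expect_lt(abs(analytic - eff), 1e-6)
  }
  expect_equal(steady_state_efficacy(1e-4), 0.41, tolerance = 1e-6)
  expect_lt(steady_state_efficacy(20), steady_state_efficacy(1))
  expect_error(steady_state_efficacy(0), "rate")
})

test_that("IPSP peak is zero without inhibition and monotone in G_I", {
  peaks <- vapply(c(0, 0.002, 0.008, 0.02), ipsp_peak, numeric(1))
  expect_lt(peaks[1], 1e-6)
  expect_true(all(diff(peaks) > 0))
})
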