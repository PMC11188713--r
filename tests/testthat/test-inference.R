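# Weighted-MSE identities, density-estimator training, posterior
# summaries, winner selection, best-fit lookup.

test_that("weighted MSE behaves as a squared metric with factor 900", {
  expect_equal(weighted_mse(c(0.01, 1e-5), c(0.01, 1e-5)), 0)
  expect_equal(weighted_mse(c(0.01, 1e-5), c(0.011, 1e-5)), 1e-6)
  expect_equal(weighted_mse(c(0.01, 1e-5), c(0.01, 2e-5)), (900 * 1e-5)^2)
  set.seed(1)
  for (i in 1:20) {
    a <- c(runif(1, 0.002, 0.02), runif(1, 0, 2e-5))
    b <- c(runif(1, 0.002, 0.02), runif(1, 0, 2e-5))
    expect_gte(weighted_mse(a, b), 0)
    expect_equal(weighted_mse(a, b), weighted_mse(b, a))
  }
})

test_that("a single-atom training set concentrates the posterior at the atom", {
  set.seed(2)
  rec <- data.frame(sim_id = 1:60, g_i = 0.012, g_e = 8e-6,
                    activity = runif(60, 0.2, 0.8),
                    interval = runif(60, 1, 10), cv = runif(60, 0.5, 3))
  cfg <- inference_config(epochs = 300, posterior_samples = 0, seed = 5)
  est <- train_estimator(rec, cfg)
  ps <- posterior_map(est, c(activity = 0.5, interval = 5, cv = 1.5), cfg)
  expect_equal(ps$map[["g_i"]], 0.012, tolerance = 0.03)
  expect_equal(ps$map[["g_e"]], 8e-6, tolerance = 0.05)
})

test_that("posterior grids normalize and MAPs stay inside the prior box", {
  rec <- surrogate_records(120, seed = 31)
  cfg <- inference_config(epochs = 250, posterior_samples = 2e4, seed = 9)
  est <- train_estimator(rec, cfg)
  for (i in c(1, 50, 111)) {
    ps <- posterior_map(est, unlist(rec[i, c("activity", "interval", "cv")]),
                        cfg)
    cell <- diff(ps$gi[1:2]) * diff(ps$ge[1:2])
    expect_equal(sum(ps$joint) * cell, 1, tolerance = 0.01)
    expect_true(ps$map[["g_i"]] >= 0.002 && ps$map[["g_i"]] <= 0.02)
    expect_true(ps$map[["g_e"]] >= 0 && ps$map[["g_e"]] <= 2e-5)
    expect_true(all(ps$samples$g_i >= 0.002 & ps$samples$g_i <= 0.02))
    expect_true(all(ps$samples$g_e >= 0 & ps$samples$g_e <= 2e-5))
    # marginals integrate to one as well
    expect_equal(sum(ps$marginal_gi$density) * diff(ps$gi[1:2]), 1,
                 tolerance = 0.01)
  }
  expect_error(train_estimator(rec[1:10, ], cfg), "at least")
})

test_that("winner selection returns the minimum held-out error", {
  fake <- structure(lapply(c(0.3, 0.05, 0.4), function(m)
    list(estimator = paste0("est", m), holdout = 1:3, mse = m)),
    class = "npe_restarts")
  w <- select_winner(fake)
  expect_equal(w$index, 2)
  expect_equal(w$mse, 0.05)
  expect_lte(w$mse, median(w$all_mse))
  one <- structure(fake[1], class = "npe_restarts")
  expect_equal(select_winner(one)$index, 1)
  expect_error(select_winner(list()), "no restarts")

  rec <- surrogate_records(90, seed = 77)
  cfg <- inference_config(n_restarts = 3, holdout = 10, epochs = 150,
                          posterior_samples = 0, seed = 13)
  rs <- train_restarts(rec, cfg, map_grid_n = 60)
  w <- select_winner(rs)
  mses <- vapply(rs, `[[`, numeric(1), "mse")
  expect_equal(w$mse, min(mses))
  expect_lte(w$mse, median(mses))
})

test_that("best-fit lookup is an exhaustive argmin with sim_id tie-breaks", {
  rec <- data.frame(sim_id = c(3L, 1L, 2L),
                    g_i = c(0.004, 0.01, 0.016),
                    g_e = c(5e-6, 1e-5, 1.5e-5))
  hit <- best_fit_lookup(c(0.01, 1e-5), rec)
  expect_equal(hit$sim_id, 1L)
  expect_equal(hit$mse, 0)
  target <- c(0.0121, 1.21e-5)
  bf <- best_fit_lookup(target, rec)
  mses <- (rec$g_i - target[1])^2 + 900^2 * (rec$g_e - target[2])^2
  expect_equal(bf$sim_id, rec$sim_id[which.min(mses)])
  expect_true(all(bf$mse <= mses))
  ties <- data.frame(sim_id = c(9L, 4L), g_i = c(0.01, 0.01),
                     g_e = c(1e-5, 1e-5))
  expect_equal(best_fit_lookup(c(0.02, 0), ties)$sim_id, 4L)
  expect_error(best_fit_lookup(c(0.01, 1e-5), rec[0, ]), "empty")
})

test_that("training is reproducible from its seed", {
  rec <- surrogate_records(80, seed = 55)
  cfg <- inference_config(epochs = 120, posterior_samples = 0, seed = 21)
  e1 <- train_estimator(rec, cfg)
  e2 <- train_estimator(rec, cfg)
  expect_identical(e1$net$W1, e2$net$W1)
  f <- unlist(rec[5, c("activity", "interval", "cv")])
  expect_identical(posterior_map(e1, f, cfg)$map, posterior_map(e2, f, cfg)$map)
})
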