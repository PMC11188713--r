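# Raster binarization, interval statistics, the three summary features,
# the total-fluctuation QC metric, and the WTA rejection filter.

test_that("binarization follows the half-open 250 ms convention", {
  sp <- make_raster(list(c(10, 60, 300), numeric(0), 250), n_cells = 3,
                    duration_ms = 1000)
  ca <- binarize(sp)
  expect_equal(ca$cells, c(1, 3))            # silent cell dropped
  expect_equal(ca$mat[1, ], c(1L, 1L, 0L, 0L))
  expect_equal(ca$mat[2, ], c(0L, 1L, 0L, 0L))  # t = 250 ms -> bin 2
  # active (cell, bin) pairs conserved
  pairs <- unique(data.frame(cell = sp$cell, bin = floor(sp$time / 250)))
  expect_equal(sum(ca$mat), nrow(pairs))
  expect_error(binarize(make_raster(list(10), duration_ms = 100)), "bin")
  bad <- make_raster(list(50), duration_ms = 1000)
  bad$time <- -5
  expect_error(binarize(bad), "outside")
})

test_that("interval extraction matches the adjacency rule and a brute-force oracle", {
  expect_equal(activation_intervals(c(1, 1, 0, 1)), c(0L, 1L))
  expect_equal(activation_intervals(c(0, 1, 0, 0)), integer(0))
  expect_equal(activation_intervals(rep(1, 6)), rep(0L, 5))
  expect_error(activation_intervals(integer(0)), "non-empty")
  expect_error(activation_intervals(c(0, 2)), "0/1")
  set.seed(99)
  for (i in 1:1000) {
    row <- rbinom(sample(3:40, 1), 1, runif(1, 0.05, 0.9))
    expect_identical(activation_intervals(row), oracle_intervals(row))
  }
})

test_that("feature vector matches hand-computed toy cases", {
  ones <- ca_raster(matrix(1L, 4, 8))
  expect_equal(feature_vector(ones),
               c(activity = 1, interval = 0, cv = 0))
  toy <- ca_raster(rbind(c(1, 0, 1, 0, 1, 0), c(1, 1, 0, 0, 1, 1)))
  fv <- feature_vector(toy)
  expect_equal(fv[["activity"]], mean(c(3 / 6, 4 / 6)))
  expect_equal(fv[["interval"]], mean(c(1, 2 / 3)))
  expect_equal(fv[["cv"]], mean(c(0, sd(c(0, 2, 0)) / (2 / 3))))
  expect_error(feature_vector(ca_raster(matrix(0L, 3, 4))), "active")
})

test_that("features are invariant under per-cell temporal shifts", {
  # activity confined to the middle third so circular shifts cannot wrap
  set.seed(7)
  n_bins <- 90
  mat <- matrix(0L, 12, n_bins)
  for (i in 1:12) mat[i, 30 + which(rbinom(30, 1, 0.4) == 1)] <- 1L
  mat[rowSums(mat) == 0, 45] <- 1L
  base <- feature_vector(ca_raster(mat))
  shifts <- sample(-25:25, 12, replace = TRUE)
  shifted <- t(vapply(1:12, function(i) {
    s <- shifts[i] %% n_bins
    c(tail(mat[i, ], s), head(mat[i, ], n_bins - s))
  }, integer(n_bins)))
  expect_identical(feature_vector(ca_raster(shifted)), base)
  # an all-zero cell changes nothing
  expect_identical(feature_vector(ca_raster(rbind(mat, 0L))), base)
})

test_that("total fluctuation separates fixed points from fluctuating activity", {
  const <- ca_raster(matrix(1L, 6, 150))
  expect_equal(total_fluctuation(const, transient_bins = 20)$value, 0)
  alt <- ca_raster(matrix(rep(c(1L, 0L), 200), 6, 400, byrow = TRUE))
  expect_equal(total_fluctuation(alt, transient_bins = 20)$value, 1,
               tolerance = 0.01)
  expect_error(total_fluctuation(const, transient_bins = 145), "10 bins")
  dead <- matrix(0L, 4, 200); dead[, 1:10] <- 1L
  expect_warning(qc <- total_fluctuation(ca_raster(dead), transient_bins = 120),
                 "dead")
  expect_equal(qc$value, 0)
  expect_true(qc$dead)
})

test_that("the WTA filter keeps the boundary and splits records", {
  rec <- data.frame(sim_id = 1:4, fluct = c(0.05, 0.5, 0.09, 0.0899))
  out <- wta_filter(rec)
  expect_equal(out$kept$sim_id, c(2L, 3L))     # exactly 0.09 is kept
  expect_equal(out$removed$sim_id, c(1L, 4L))
})
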