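# Assembly clustering, dominant-cluster series, transition graphs.

test_that("a planted two-assembly raster is recovered", {
  ra <- planted_raster(n_per_block = 12, n_bins = 60, period = 10)
  cl <- embed_and_cluster(ra, n_neighbors = 5, seed = 4)
  expect_equal(cl$k, 2)
  expect_length(cl$labels, 24)
  expect_equal(min(cl$labels), 0L)
  # blocks are pure
  expect_length(unique(cl$labels[1:12]), 1)
  expect_length(unique(cl$labels[13:24]), 1)
  expect_false(cl$labels[1] == cl$labels[13])
  # bitwise reproducibility
  cl2 <- embed_and_cluster(ra, n_neighbors = 5, seed = 4)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$embedding, cl2$embedding)
})

test_that("identical rows collapse to a single cluster and errors are raised", {
  ra <- ca_raster(matrix(rep(c(1L, 0L, 1L, 1L, 0L), 12), 12, byrow = TRUE))
  cl <- embed_and_cluster(ra, n_neighbors = 3, seed = 1)
  expect_equal(cl$k, 1)
  tiny <- ca_raster(diag(1L, 4))
  expect_error(embed_and_cluster(tiny), "at least 10")
  expect_error(embed_and_cluster(planted_raster(6, 30), n_neighbors = 50),
               "neighbours")
})

test_that("dominant-cluster series follows the majority rule", {
  ra <- planted_raster(10, n_bins = 40, period = 10)
  labels <- rep(c(0L, 1L), each = 10)
  s <- dominant_cluster_series(ra, labels)
  expect_equal(s[1:10], rep(0L, 10))
  expect_equal(s[11:20], rep(1L, 10))
  # an empty bin has no dominant cluster; a tie yields NA
  m <- rbind(c(1L, 0L, 1L), c(1L, 0L, 0L), c(0L, 0L, 1L), c(0L, 0L, 0L))
  s2 <- dominant_cluster_series(ca_raster(m, drop_silent = FALSE),
                                c(0L, 0L, 1L, 1L))
  expect_true(is.na(s2[2]))   # empty bin
  expect_true(is.na(s2[3]))   # tie 0.5 vs 0.5
  expect_equal(s2[1], 0L)
})

test_that("transition graphs count distinct switches with gaps skipped", {
  expect_equal(nrow(transition_graph(c(0L, 0L, 0L))), 0)
  g <- transition_graph(c(0L, 1L, 0L, 1L))
  expect_equal(g$weight[g$src == 0 & g$dst == 1], 2L)
  expect_equal(g$weight[g$src == 1 & g$dst == 0], 1L)
  s <- c(0L, NA, 0L, 1L, NA, 1L, 2L, 0L, 0L, NA, 2L)
  g2 <- transition_graph(s)
  sr <- s[!is.na(s)]
  switches <- sum(diff(sr) != 0)
  expect_equal(sum(g2$weight), switches)
  expect_false(any(g2$src == g2$dst))
  # relabeling clusters permutes node ids but preserves the weight multiset
  perm <- c(2L, 0L, 1L)
  g3 <- transition_graph(perm[s + 1L])
  expect_equal(sort(g3$weight), sort(g2$weight))
})
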