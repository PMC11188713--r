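# Synthetic inputs with known statistical structure: two-state Markov
# rasters with closed-form expected features, a fast analytic surrogate of
# the network feature landscape for inference-recovery tests, and
# slice-like cell subsampling.

#' Specification of a Markov-chain binary raster
#'
#' Each cell is an independent two-state Markov chain over 250 ms bins with
#' on-to-on probability `q` and off-to-on probability `r`, started from its
#' stationary distribution; the stationary activity is \eqn{r/(1-q+r)}.
#' These rasters emulate the delimited binary format of slice recordings
#' while having closed-form expected features.
#'
#' @param n_cells,n_bins raster dimensions.
#' @param q on-to-on transition probability in `[0, 1]`.
#' @param r off-to-on transition probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A list of class `markov_raster_spec`; element `stationary` holds
#'   the stationary activity.
#' @export
markov_raster_spec <- function(n_cells, n_bins, q, r, seed) {
  if (q < 0 || q > 1 || r < 0 || r > 1) stop("q and r must lie in [0, 1]")
  structure(list(n_cells = n_cells, n_bins = n_bins, q = q, r = r,
                 seed = seed, stationary = r / (1 - q + r)),
            class = "markov_raster_spec")
}

#' Generate a Markov-chain binary raster
#'
#' @param spec a [markov_raster_spec()].
#' @return A `ca_raster` (silent cells dropped, as always).
#' @export
synth_raster <- function(spec) {
  set.seed(derive_seed(spec$seed, "markov"))
  n <- spec$n_cells; b <- spec$n_bins
  mat <- matrix(0L, n, b)
  mat[, 1] <- rbinom(n, 1, spec$stationary)
  for (j in seq_len(b - 1)) {
    p_on <- ifelse(mat[, j] == 1, spec$q, spec$r)
    mat[, j + 1] <- rbinom(n, 1, p_on)
  }
  ca_raster(mat, bin_ms = 250)
}

#' Surrogate feature-landscape specification
#'
#' An explicit analytic stand-in for the mapping from network parameters
#' `(G_I, G_E)` to the three raster features, honouring the qualitative
#' structure of the simulated landscape: mean activity decreases with
#' inhibition (logistic in `G_I`, modulated upward by `G_E`); the mean
#' activation interval increases with inhibition (linear with a weak
#' excitation interaction); the interval CV is a bump that collapses to
#' near zero below the winners-take-all transition `g_c` when excitation is
#' high.  Gaussian observation noise with SD equal to `noise_sd` of each
#' feature's range is added.  This generator is a test double for the
#' biophysical simulator, roughly 10^4 times faster.
#'
#' @param noise_sd observation noise as a fraction of each feature's range.
#' @param g_c transition location in `G_I`.
#' @param seed integer seed consumed when noise is drawn.
#' @return A list of class `surrogate_spec`.
#' @export
surrogate_spec <- function(noise_sd = 0.05, g_c = 0.006, seed = 1) {
  structure(list(noise_sd = noise_sd, g_c = g_c, seed = seed,
                 ranges = c(activity = 0.84, interval = 41, cv = 4.2)),
            class = "surrogate_spec")
}

# noiseless surrogate map (vectorized)
.surrogate_mean <- function(g_i, g_e, spec) {
  u <- (g_i - 0.002) / 0.018
  v <- g_e / 2e-5
  activity <- 0.05 + 0.45 * plogis(6 * (0.35 - u)) + 0.45 * v
  interval <- 1 + 24 * u + 14 * v * (0.2 + u)
  gate <- plogis((v - 0.55) / 0.08) * plogis((spec$g_c - g_i) / 0.0006)
  base <- 0.3 + 3.7 * exp(-(u - 0.22)^2 / (2 * 0.18^2))
  cv <- base * (0.7 + 0.6 * v) * (1 - 0.95 * gate)
  cbind(activity = activity, interval = interval, cv = cv)
}

#' Surrogate features at given network parameters
#'
#' @param g_i,g_e network parameters inside the prior box
#'   `[0.002, 0.02] x [0, 2e-5]` (vectorized).
#' @param spec a [surrogate_spec()].
#' @param seed seed for the observation noise (defaults to the spec seed);
#'   with `noise_sd = 0` repeated calls are identical.
#' @return A data.frame `activity`, `interval`, `cv` with one row per
#'   parameter pair.
#' @export
surrogate_features <- function(g_i, g_e, spec = surrogate_spec(),
                               seed = spec$seed) {
  if (any(g_i < 0.002 - 1e-12) || any(g_i > 0.02 + 1e-12) ||
      any(g_e < -1e-18) || any(g_e > 2e-5 + 1e-18))
    stop("parameters outside the prior box [0.002, 0.02] x [0, 2e-5]")
  mu <- .surrogate_mean(g_i, g_e, spec)
  n <- nrow(mu)
  if (spec$noise_sd > 0) {
    set.seed(derive_seed(seed, "surrogate-noise"))
    noise <- matrix(rnorm(3 * n), n, 3) %*%
      diag(spec$noise_sd * spec$ranges)
    mu <- mu + noise
  }
  out <- as.data.frame(mu)
  out$activity <- pmin(pmax(out$activity, 1e-3), 1)
  out$interval <- pmax(out$interval, 0)
  out$cv <- pmax(out$cv, 0)
  out
}

#' Subsample recorded cells from a raster
#'
#' Emulates the varying number of recorded cells across slice preparations
#' by keeping a uniform random subset of active cells.  The three summary
#' features are unchanged in expectation (they are cell averages), whereas
#' the total fluctuation is not.
#'
#' @param raster a `ca_raster`.
#' @param n_record number of cells to keep (1..active cells).
#' @param seed integer seed.
#' @return A `ca_raster` over the sampled subset.
#' @export
slice_like_subsample <- function(raster, n_record, seed) {
  n <- nrow(raster$mat)
  if (n_record <= 0) stop("n_record must be positive")
  if (n_record > n) stop("n_record exceeds the number of active cells")
  set.seed(derive_seed(seed, "subsample"))
  keep <- sort(sample.int(n, n_record))
  ca_raster(raster$mat[keep, , drop = FALSE], bin_ms = raster$bin_ms,
            cells = raster$cells[keep], drop_silent = FALSE)
}
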