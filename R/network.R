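# Random recurrent inhibitory MSN network: construction, integration,
# parameter sweeps.

#' Network parameters
#'
#' Parameters of the random inhibitory MSN network.  The reference (full
#' scale) network has 400 cells connected with probability 0.4, giving a
#' mean in-degree of about 160; synaptic weights are uniform in
#' `[0.3125 G_I, 0.9375 G_I]`, axonal delays uniform in 1-3 ms, and every
#' cell receives a constant suprathreshold drive uniform in
#' `[0.001305, 0.001305 + G_E]`, fixed for the whole run.
#'
#' When `n_cells` is below 400 and `compensate = TRUE`, weights are scaled
#' by `kappa = (399 * 0.4) / ((n_cells - 1) * p)` so the summed lateral
#' inhibitory conductance per cell matches the full-scale network; see the
#' vignette for why the desk profile also raises `p` to 0.8.
#'
#' @param n_cells number of cells.
#' @param p connection probability in `[0, 1]`.
#' @param g_i lateral inhibition scale, in `[0, 0.02]` (0.002-0.02 is the
#'   inference prior box; 0 is allowed for the no-inhibition control).
#' @param g_e excitatory drive scale, in `[0, 2e-5]`.
#' @param duration simulation duration, seconds.
#' @param dt integration step, ms.
#' @param weight_frac weight range as fractions of `g_i`.
#' @param delay_range synaptic delay range, ms.
#' @param compensate scale weights to preserve full-scale summed inhibition.
#' @param seed default seed used by [build_network()].
#' @return A list of class `network_params`.
#' @export
network_params <- function(n_cells = 400, p = 0.4, g_i = 0.008, g_e = 1e-5,
                           duration = 600, dt = 0.025,
                           weight_frac = c(0.3125, 0.9375),
                           delay_range = c(1, 3), compensate = TRUE,
                           seed = NULL) {
  if (p < 0 || p > 1) stop("connection probability must lie in [0, 1]")
  if (g_i < 0 || g_i > 0.02) stop("g_i must lie in [0, 0.02]")
  if (g_e < 0 || g_e > 2e-5) stop("g_e must lie in [0, 2e-5]")
  if (duration <= 0) stop("duration must be > 0")
  if (n_cells < 1) stop("need at least one cell")
  structure(list(n_cells = as.integer(n_cells), p = p, g_i = g_i, g_e = g_e,
                 duration = duration, dt = dt, weight_frac = weight_frac,
                 delay_range = delay_range, compensate = compensate,
                 seed = seed), class = "network_params")
}

#' Desk-scale network profile
#'
#' Scaled-down study conditions used by the test suite and the transition
#' sweep: 100 cells for 120 s, connection probability 0.8 with weight
#' compensation, which preserves the position of the winners-take-all
#' transition of the 400-cell reference network (see vignette).
#'
#' @param g_i,g_e network parameters.
#' @param seed build seed.
#' @param n_cells,duration overrides of the desk defaults.
#' @return A `network_params` object.
#' @export
desk_profile <- function(g_i, g_e, seed = NULL, n_cells = 100,
                         duration = 120) {
  network_params(n_cells = n_cells, p = 0.8, g_i = g_i, g_e = g_e,
                 duration = duration, compensate = TRUE, seed = seed)
}

#' Build a random MSN network
#'
#' Draws the directed adjacency (each ordered pair `i != j` connected
#' independently with probability `p`), per-edge weights and delays, and
#' per-cell drives.  Four independent RNG streams are derived from the seed
#' (topology, weights, delays, drives) so any one draw class can be held
#' fixed while others vary.
#'
#' @param params a [network_params()].
#' @param seed integer seed (defaults to `params$seed`).
#' @return A list of class `msn_network` with `edges` (data.frame
#'   `src`, `dst`, `weight`, `delay`), `drives`, and `params`.
#' @export
build_network <- function(params, seed = params$seed) {
  if (is.null(seed)) stop("a seed is required to build a network")
  n <- params$n_cells
  set.seed(derive_seed(seed, "topology"))
  a <- matrix(runif(n * n) < params$p, n, n)
  diag(a) <- FALSE
  idx <- which(a, arr.ind = TRUE)
  m <- nrow(idx)
  kappa <- if (params$compensate && n > 1)
    (399 * 0.4) / ((n - 1) * params$p) else 1
  set.seed(derive_seed(seed, "weights"))
  w <- runif(m, params$weight_frac[1], params$weight_frac[2]) * params$g_i * kappa
  set.seed(derive_seed(seed, "delays"))
  d <- runif(m, params$delay_range[1], params$delay_range[2])
  set.seed(derive_seed(seed, "drives"))
  drv <- runif(n, 0.001305, 0.001305 + params$g_e)
  structure(list(
    edges = data.frame(src = idx[, 1], dst = idx[, 2], weight = w, delay = d),
    drives = drv, params = params, seed = seed, kappa = kappa
  ), class = "msn_network")
}

#' @export
print.msn_network <- function(x, ...) {
  cat(sprintf("<msn_network> %d cells, %d edges (mean in-degree %.1f), G_I=%g, G_E=%g, kappa=%.2f\n",
              x$params$n_cells, nrow(x$edges),
              nrow(x$edges) / x$params$n_cells, x$params$g_i, x$params$g_e,
              x$kappa))
  invisible(x)
}

#' Spike raster container
#'
#' @param cell integer cell indices (1-based).
#' @param time spike times, ms.
#' @param n_cells number of cells in the network.
#' @param duration_ms recording duration, ms.
#' @return A data.frame of class `spike_raster` with attributes `n_cells`
#'   and `duration_ms`; rows are ordered by cell then time.
#' @export
spike_raster <- function(cell, time, n_cells, duration_ms) {
  stopifnot(length(cell) == length(time))
  if (length(time) && (min(time) < 0 || max(time) > duration_ms))
    stop("spike times must lie in [0, duration]")
  o <- order(cell, time)
  out <- data.frame(cell = as.integer(cell[o]), time = time[o])
  attr(out, "n_cells") <- as.integer(n_cells)
  attr(out, "duration_ms") <- duration_ms
  class(out) <- c("spike_raster", "data.frame")
  out
}

#' Integrate a built network
#'
#' Runs all cells with event-driven TM synapses and fixed axonal delays
#' (rounded to the integration grid, delivered at `t_spike + delay`).  The
#' integration is deterministic given the built network and `dt`; every
#' emitted spike appears exactly once in the returned raster.
#'
#' @param net an [build_network()] result.
#' @param duration run length in seconds (defaults to the network params).
#' @param dt integration step in ms (<= 0.1).
#' @param syn a [tm_params()] (network GABA reversal -85 mV).
#' @param settle per-cell settling time from rest, seconds.
#' @return A [spike_raster()].
#' @export
run_network <- function(net, duration = net$params$duration,
                        dt = net$params$dt, syn = tm_params(), settle = 2) {
  if (dt > 0.1) stop("dt must be <= 0.1 ms")
  p <- cell_params()
  dsteps <- as.integer(pmax(1, round(net$edges$delay / dt)))
  r <- cpp_engine(unclass(p), net$params$n_cells,
                  as.integer(net$edges$src - 1L),
                  as.integer(net$edges$dst - 1L),
                  net$edges$weight, dsteps, drives = net$drives,
                  duration_ms = duration * 1000, dt = dt,
                  settle_ms = settle * 1000, hold_current = 0,
                  ext_times = numeric(0), ext_weight = 0, ext_target = 0L,
                  e_syn = syn$e_rev, tm_u = syn$u, tm_d = syn$d,
                  tm_f = syn$f, tau_syn = syn$tau, record_trace = FALSE,
                  record_cell = 0L, record_every = 40L)
  spike_raster(r$spike_cell + 1L, r$spike_time, net$params$n_cells,
               duration * 1000)
}

#' Locate the winners-take-all transition in a CV sweep
#'
#' The interval CV rises as inhibition is lowered towards the transition
#' and then collapses to near zero once the network falls into the
#' fixed-point winners-take-all regime.  Given a sweep of `G_I` values and
#' the corresponding cell-averaged interval CVs, this returns the largest
#' `G_I` on the low-inhibition side of the CV peak at which the CV has
#' fallen below half the sweep maximum -- the operational collapse point.
#' (The high-inhibition side also has moderate CVs below half maximum; it
#' is excluded because the transition is defined by the collapse as `G_I`
#' decreases.)
#'
#' @param g_i sweep values of the inhibition scale.
#' @param cv matching cell-averaged interval CVs.
#' @return The transition `G_I` (`NA` if no value qualifies).
#' @export
wta_transition <- function(g_i, cv) {
  stopifnot(length(g_i) == length(cv))
  o <- order(g_i)
  g_i <- g_i[o]; cv <- cv[o]
  peak <- which.max(cv)
  cand <- which(seq_along(g_i) <= peak & cv < 0.5 * max(cv))
  if (!length(cand)) return(NA_real_)
  g_i[max(cand)]
}

#' Sample a parameter sweep over the prior box
#'
#' Draws i.i.d. uniform `(G_I, G_E)` pairs over the inference prior box,
#' as for the training sweep of 200 ten-minute simulations.
#'
#' @param n number of simulations (>= 1).
#' @param gi_range,ge_range prior ranges.
#' @param seed integer seed.
#' @return A data.frame `sim_id`, `g_i`, `g_e`, `seed` (per-simulation
#'   build seed).
#' @export
sample_sweep <- function(n = 200, gi_range = c(0.002, 0.02),
                         ge_range = c(0, 2e-5), seed) {
  if (n < 1) stop("n must be >= 1")
  set.seed(derive_seed(seed, "sweep"))
  data.frame(sim_id = seq_len(n),
             g_i = runif(n, gi_range[1], gi_range[2]),
             g_e = runif(n, ge_range[1], ge_range[2]),
             seed = vapply(seq_len(n), function(i)
               derive_seed(seed, paste0("sim", i)), integer(1)))
}
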