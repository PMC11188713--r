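# Tsodyks-Markram short-term plasticity: deterministic resource/utilization
# dynamics for the depressing, weakly facilitating GABA synapses between
# MSNs, plus the single-spike IPSP characterization protocol.

#' Tsodyks-Markram synapse parameters
#'
#' Deterministic short-term plasticity constants of the MSN-MSN GABA
#' synapse: utilization `U = 0.41`, depression recovery `D = 222` ms,
#' facilitation decay `F = 1859` ms, exponential conductance decay
#' `tau = 20` ms, GABA reversal -85 mV in the network (-40 mV chloride
#' reversal in the IPSP characterization protocol), axonal delays uniform
#' in 1-3 ms.
#'
#' @param u utilization factor in `[0, 1]`.
#' @param d depression time constant, ms (> 0).
#' @param f facilitation time constant, ms (> 0).
#' @param tau conductance decay time constant, ms (> 0).
#' @param e_rev synaptic reversal potential, mV.
#' @param delay_range synaptic delay range, ms.
#' @return A list of class `tm_params`.
#' @export
tm_params <- function(u = 0.41, d = 222, f = 1859, tau = 20, e_rev = -85,
                      delay_range = c(1, 3)) {
  if (u < 0 || u > 1) stop("U must lie in [0, 1]")
  if (d <= 0 || f <= 0 || tau <= 0) stop("D, F and tau must be > 0")
  structure(list(u = u, d = d, f = f, tau = tau, e_rev = e_rev,
                 delay_range = delay_range), class = "tm_params")
}

#' Tsodyks-Markram synapse state
#'
#' @param r fraction of available resources in `[0, 1]`.
#' @param s utilization variable in `[0, 1]`.
#' @param g open conductance (>= 0, raw conductance units).
#' @param t last-update time, ms.
#' @return A list of class `tm_state`.
#' @export
tm_state <- function(r = 1, s = 0, g = 0, t = 0) {
  if (r < 0 || r > 1 || s < 0 || s > 1) stop("R and S must lie in [0, 1]")
  if (g < 0) stop("conductance must be >= 0")
  structure(list(r = r, s = s, g = g, t = t), class = "tm_state")
}

#' Relax a TM synapse between spikes
#'
#' Closed-form exponential relaxation over an interval with no presynaptic
#' events: `R` recovers towards 1 with constant `D`, `S` decays towards 0
#' with constant `F`, and the open conductance decays with constant `tau`.
#'
#' @param state a [tm_state()].
#' @param dt elapsed time in ms (>= 0).
#' @param params a [tm_params()].
#' @return The relaxed `tm_state`.
#' @export
#' @examples
#' st <- tm_state(r = 0, s = 0.5)
#' tm_relax(st, 222)$r  # 1 - exp(-1)
tm_relax <- function(state, dt, params = tm_params()) {
  if (dt < 0) stop("dt must be >= 0")
  tm_state(r = 1 + (state$r - 1) * exp(-dt / params$d),
           s = state$s * exp(-dt / params$f),
           g = state$g * exp(-dt / params$tau),
           t = state$t + dt)
}

#' Apply a presynaptic spike to a TM synapse
#'
#' Event update at a presynaptic spike: the utilization variable
#' facilitates first, `S+ = S + U (1 - S)`; the conductance increment uses
#' the pre-spike resources, `weight * R- * S+`; resources are then consumed,
#' `R+ = R- (1 - S+)`.
#'
#' @param state a [tm_state()].
#' @param weight synaptic weight (conductance units, >= 0).
#' @param params a [tm_params()].
#' @return The updated `tm_state`; the conductance increment that was added
#'   to `g` is attached as element `increment`.
#' @export
#' @examples
#' st <- tm_spike(tm_state(), weight = 1)
#' st$increment  # 0.41 at rest
tm_spike <- function(state, weight, params = tm_params()) {
  if (weight < 0) stop("weight must be >= 0")
  s_post <- state$s + params$u * (1 - state$s)
  inc <- weight * state$r * s_post
  out <- tm_state(r = state$r * (1 - s_post), s = s_post,
                  g = state$g + inc, t = state$t)
  out$increment <- inc
  out
}

#' Steady-state per-spike efficacy of a periodic train
#'
#' Fixed point of the relax-then-spike event map for a periodic presynaptic
#' train: the limiting per-spike conductance increment expressed as a
#' fraction of the synaptic weight (`R- * S+` at the fixed point).  In the
#' low-rate limit resources recover fully and the efficacy tends to `U`.
#'
#' @param rate presynaptic rate in Hz (> 0).
#' @param params a [tm_params()].
#' @param tol convergence tolerance of the fixed-point iteration.
#' @return Steady-state efficacy (dimensionless).
#' @export
steady_state_efficacy <- function(rate, params = tm_params(), tol = 1e-14) {
  if (rate <= 0) stop("rate must be > 0")
  period <- 1000 / rate
  st <- tm_state()
  for (i in seq_len(100000)) {
    st2 <- tm_spike(tm_relax(st, period, params), 1, params)
    st2$g <- 0
    if (abs(st2$r - st$r) + abs(st2$s - st$s) < tol && i > 1) {
      st <- st2
      break
    }
    st <- st2
  }
  rel <- tm_relax(st, period, params)
  rel$r * (rel$s + params$u * (1 - rel$s))
}

#' Single-spike IPSP amplitude at a given inhibition scale
#'
#' The characterization protocol behind the synaptic calibration: the model
#' MSN is current-clamped at -80 mV, the synaptic (chloride) reversal is set
#' to -40 mV so IPSPs are depolarizing, a single presynaptic spike is
#' delivered through a TM synapse with the mean network weight
#' `0.625 * G_I`, and the peak depolarization from hold is returned.  With
#' the calibrated cell, peaks grow supralinearly from about 0.1 mV at
#' `G_I = 0.002` to about 1.5 mV at `G_I = 0.02`.
#'
#' @param g_i inhibition scale (>= 0).
#' @param params `msn_cell_params`.
#' @param syn `tm_params`; the characterization reversal defaults to -40 mV.
#' @param v_hold holding potential, mV.
#' @param weight_frac weight as a fraction of `g_i` (mean of the network
#'   weight range 0.3125-0.9375).
#' @param duration recording window after the spike, ms.
#' @param dt integration step, ms.
#' @return Peak depolarization from hold, mV.
#' @export
#' @examples
#' \donttest{ipsp_peak(0.008)}
ipsp_peak <- function(g_i, params = cell_params(),
                      syn = tm_params(e_rev = -40), v_hold = -80,
                      weight_frac = 0.625, duration = 250, dt = 0.025) {
  if (g_i < 0) stop("g_i must be >= 0")
  i_hold <- cpp_holding_current(unclass(params), v_hold)
  r <- .cell_engine(params, numeric(0), duration, dt, settle_ms = 2500,
                    hold_current = i_hold, ext_times = 10,
                    ext_weight = weight_frac * g_i, e_syn = syn$e_rev,
                    record = TRUE, thin = 1L, tm = syn)
  v0 <- r$v[r$time <= 10]
  if (max(abs(v0 - v_hold)) > 0.5)
    stop(sprintf("protocol error: cell failed to hold at %g mV", v_hold))
  max(r$v) - v_hold
}
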