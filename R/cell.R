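# Single-compartment MSN cell model: parameters, protocols, calibration
# surfaces.  Units follow the conductance-based convention mV / ms /
# mS/cm^2 / uA/cm^2 with a membrane capacitance of 1 uF/cm^2.  Excitatory
# drive is expressed in abstract "model drive units"; `drive_scale` converts
# drive units into injected current and is fixed once by calibration so that
# (i) rheobase lies just below the base drive 0.001305 and (ii) the maximum
# network drive 0.001305 + 2e-5 elicits tonic firing at 10 Hz.

#' MSN cell parameters
#'
#' Returns the calibrated parameter set of the single-compartment MSN model.
#' The channel complement is the canonical striatal projection-neuron set:
#' fast sodium (`I_Na`), delayed-rectifier potassium (`I_K`), inward
#' rectifier (`I_Kir`), fast and slow A-type potassium (`I_Af`, `I_As`),
#' persistent potassium (`I_Krp`), and persistent plus slowly-equilibrating
#' sodium (`I_NaP`, `I_NaS`).  The slow A-current inactivation produces the
#' characteristic long delay to first spike; the sharp subthreshold sodium
#' and inward-rectifier nonlinearities produce the supralinear growth of
#' somatic IPSP amplitude with synaptic strength.
#'
#' Kinetics are Boltzmann steady-state curves `x_inf(V)` with fixed or
#' sigmoid voltage-dependent time constants; gating advances by exponential
#' Euler.  Defaults are calibrated against three behavioural anchors (see
#' the package vignette): rheobase below 0.001305 drive units, 10 Hz tonic
#' firing at drive 0.001325, and single-spike IPSP peaks of about
#' 0.1/0.45/0.7/1.5 mV at inhibition scales 0.002/0.008/0.011/0.02.
#'
#' @param ... named overrides of individual parameters (e.g. `g_kir = 0.1`).
#' @return A named numeric vector of class `msn_cell_params`.
#' @export
#' @examples
#' p <- cell_params()
#' p[["drive_scale"]]
cell_params <- function(...) {
  p <- c(
    g_l = 0.08, e_l = -75, g_na = 35, e_na = 55, g_k = 6, e_k = -90,
    g_kir = 0.081888, g_af = 0.5, g_as = 0.4, g_krp = 0.4, g_nap = 0.02,
    g_nas = 0.000796,
    m_vh = -30, m_k = 6, h_vh = -50, h_k = 6,
    tau_h0 = 0.3, tau_h1 = 6, tau_h_vh = -45, tau_h_k = 8,
    n_vh = -20, n_k = 9, tau_n0 = 1.2, tau_n1 = 12, tau_n_vh = -27,
    tau_n_k = 10,
    kir_vh = -75.448529, kir_k = 11.825271,
    af_vh = -33, af_k = 7.5, bf_vh = -70, bf_k = 7.6, tau_bf = 25,
    as_vh = -26, as_k = 13, tau_as = 10, bs_vh = -58, bs_k = 7,
    bs_min = 0.3, tau_bs = 1200,
    krp_vh = -14, krp_k = 12, tau_krp = 300,
    nap_vh = -48, nap_k = 3.1,
    nas_vh = -79.226791, nas_k = 0.20683, tau_nas = 1,
    drive_scale = 3642.264151, syn_scale = 1.10298
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  gc_names <- grep("^g_", names(p), value = TRUE)
  if (any(p[gc_names] < 0)) stop("all peak conductances must be >= 0")
  if (p[["drive_scale"]] <= 0) stop("drive_scale must be > 0")
  structure(p, class = "msn_cell_params")
}

#' Excitatory drive specification
#'
#' Constant somatic current injection in model drive units, as used for all
#' network cells: a base of 0.001305 plus a cell-specific increment drawn
#' between 0 and `G_E` (at most 2e-5).
#'
#' @param increment drive increment above base, in `[0, 2e-5]`.
#' @param base base drive amplitude (default 0.001305).
#' @param duration protocol duration in seconds.
#' @return A list of class `drive_spec` with elements `base`, `increment`,
#'   `duration` and the total `amplitude`.
#' @export
drive_spec <- function(increment = 0, base = 0.001305, duration = 10) {
  stopifnot(is.numeric(increment), length(increment) == 1L)
  if (increment < 0 || increment > 2e-5)
    stop("drive increment must lie in [0, 2e-5]")
  if (duration <= 0) stop("duration must be positive")
  structure(list(base = base, increment = increment, duration = duration,
                 amplitude = base + increment), class = "drive_spec")
}

# internal: uniform access to the compiled engine for isolated-cell work
.cell_engine <- function(params, drive, duration_ms, dt, settle_ms = 2000,
                         hold_current = 0, ext_times = numeric(0),
                         ext_weight = 0, e_syn = -85, record = FALSE,
                         thin = 40L, tm = tm_params()) {
  cpp_engine(unclass(params), 1L, integer(0), integer(0), numeric(0),
             integer(0), drives = drive, duration_ms = duration_ms, dt = dt,
             settle_ms = settle_ms, hold_current = hold_current,
             ext_times = ext_times, ext_weight = ext_weight, ext_target = 0L,
             e_syn = e_syn, tm_u = tm$u, tm_d = tm$d, tm_f = tm$f,
             tau_syn = tm$tau, record_trace = record, record_cell = 0L,
             record_every = as.integer(thin))
}

#' Simulate an isolated MSN under constant drive
#'
#' Integrates the single-compartment model for `duration` seconds of
#' protocol time after a 2 s drive-free settling period.  Spikes are upward
#' crossings of 0 mV with a 2 ms detection lockout.  The run is fully
#' deterministic: identical inputs give bit-identical spike times.
#'
#' @param params `msn_cell_params` (default [cell_params()]).
#' @param drive drive amplitude in model drive units, or a [drive_spec()].
#' @param duration protocol duration in seconds (ignored when `drive` is a
#'   `drive_spec`, which carries its own duration).
#' @param dt integration step in ms (must be <= 0.1).
#' @param record if `TRUE`, keep the voltage trace (thinned by `thin`).
#' @param thin keep every `thin`-th sample of the voltage trace.
#' @param settle settling time in seconds before the protocol.
#' @return A list of class `voltage_trace` with `spikes` (ms), `latency`
#'   (ms to first spike, `NA` if silent), `rate` (Hz over the protocol
#'   window), and optionally `time`/`v`.
#' @export
#' @examples
#' tr <- simulate_cell(drive = 0.001325, duration = 2)
#' tr$rate
simulate_cell <- function(params = cell_params(), drive, duration = 10,
                          dt = 0.025, record = FALSE, thin = 40L,
                          settle = 2) {
  if (inherits(drive, "drive_spec")) {
    duration <- drive$duration
    drive <- drive$amplitude
  }
  stopifnot(is.numeric(drive), length(drive) == 1L, drive >= 0)
  if (dt > 0.1) stop("dt must be <= 0.1 ms")
  r <- .cell_engine(params, drive, duration * 1000, dt,
                    settle_ms = settle * 1000, record = record, thin = thin)
  out <- list(spikes = r$spike_time,
              latency = if (length(r$spike_time)) r$spike_time[1] else NA_real_,
              rate = length(r$spike_time) / duration,
              drive = drive, dt = dt, duration = duration)
  if (record) { out$time <- r$time; out$v <- r$v }
  structure(out, class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> drive=%g, %g s at dt=%g ms: %d spikes (%.2f Hz), latency %s ms\n",
              x$drive, x$duration, x$dt, length(x$spikes), x$rate,
              if (is.na(x$latency)) "NA" else sprintf("%.1f", x$latency)))
  invisible(x)
}

#' Firing rate versus drive (f-I curve)
#'
#' @param params `msn_cell_params`.
#' @param drives ascending numeric vector of drive amplitudes (drive units).
#' @param duration protocol duration per point, seconds.
#' @param dt integration step, ms.
#' @return A data.frame with columns `drive`, `rate` (Hz), `latency` (ms).
#' @export
fI_curve <- function(params = cell_params(), drives, duration = 10,
                     dt = 0.025) {
  if (length(drives) == 0) stop("empty drive list")
  if (is.unsorted(drives)) stop("drives must be sorted ascending")
  res <- lapply(drives, function(d)
    simulate_cell(params, d, duration = duration, dt = dt))
  data.frame(drive = drives,
             rate = vapply(res, `[[`, numeric(1), "rate"),
             latency = vapply(res, `[[`, numeric(1), "latency"))
}

#' Rheobase of the model cell
#'
#' Minimum constant drive eliciting at least one spike in `duration`
#' seconds, located by bisection to relative tolerance `tol`.  With the
#' calibrated defaults the returned value lies just below the network base
#' drive 0.001305, so every network cell is driven above threshold.
#'
#' @param params `msn_cell_params`.
#' @param lower,upper bisection bracket in drive units; `upper` defaults to
#'   twice the base drive.
#' @param tol relative tolerance of the bisection.
#' @param duration test duration per probe, seconds.
#' @param dt integration step, ms.
#' @return Rheobase drive amplitude (drive units).
#' @export
rheobase <- function(params = cell_params(), lower = 5e-4, upper = 2 * 0.001305,
                     tol = 1e-3, duration = 10, dt = 0.025) {
  n_at <- function(d) length(simulate_cell(params, d, duration, dt)$spikes)
  if (n_at(upper) == 0)
    stop("calibration error: no spiking even at twice the base drive")
  if (n_at(lower) > 0)
    stop("lower bracket already spikes; decrease `lower`")
  while ((upper - lower) / upper > tol) {
    mid <- (lower + upper) / 2
    if (n_at(mid) > 0) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}
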