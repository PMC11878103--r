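# Minimal six-current ionic model: I_Na, I_to, I_CaL, I_Kr, I_Kur, I_K1.
# Membrane capacitance is normalised to 1, so all currents are in mV/ms and
# the monodomain reaction term is simply -I_ion. Gates are first-order with
# sigmoid steady states 1/(1 + exp((vh - V)/k)) and constant time constants
# (k > 0 activation, k < 0 inactivation). The model has no concentration
# dynamics and no pacemaker current: every region is quiescent until driven.

#' Default parameters of the minimal six-current cell model
#'
#' Returns the named parameter vector consumed by [ionic_current()],
#' [step_cell()], [simulate_cell()] and the tissue solver. Conductances
#' (`gNa`, `gto`, `gCaL`, `gKr`, `gKur`, `gK1`) are in ms^-1 (current per mV
#' of driving force with unit capacitance), reversal potentials (`ENa`,
#' `EK`, `ECa`) in mV, gate midpoints `vh_*` in mV, slopes `k_*` in mV and
#' time constants `tau_*` in ms. The defaults give a quiescent rest near
#' -80 mV, a ventricular-type action potential with APD90 close to 300 ms,
#' and (after conduction-velocity calibration) planar conduction at
#' 0.713 m/s for D = 0.3 mm^2/ms on a 0.292 mm grid.
#'
#' @param ... name = value overrides of individual parameters.
#' @return Named numeric vector of model parameters.
#' @export
cell_params <- function(...) {
  p <- c(
    gNa = 4.5, gto = 0.15, gCaL = 0.08, gKr = 0.025, gKur = 0.005,
    gK1 = 0.45,
    ENa = 65, EK = -82, ECa = 50,
    vh_m = -45, k_m = 5.5, tau_m = 0.4,
    vh_h = -68, k_h = -5, tau_h = 10,
    vh_d = -15, k_d = 6, tau_d = 2,
    vh_f = -28, k_f = -7, tau_f = 220,
    vh_r = -10, k_r = 9, tau_r = 3,
    vh_s = -35, k_s = -6, tau_s = 25,
    vh_xr = -18, k_xr = 7, tau_xr = 260,
    vh_xur = -5, k_xur = 8, tau_xur = 40,
    vh_k1 = -65, k_k1 = -8
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(all(p[c("gNa", "gto", "gCaL", "gKr", "gKur", "gK1")] >= 0),
            all(p[grep("^tau_", names(p))] > 0))
  p
}

#' Construct a single-cell state
#'
#' @param v Membrane potential in mV.
#' @param gates Numeric vector of the 8 gate variables
#'   (`m, h, d, f, r, s, xr, xur`), each in `[0, 1]`. Defaults to the
#'   steady-state values at `v`.
#' @param params Cell parameter vector, see [cell_params()].
#' @return A list with elements `v` and `gates` (class `cell_state`).
#' @export
cell_state <- function(v, gates = NULL, params = cell_params()) {
  stopifnot(is.finite(v))
  if (is.null(gates)) gates <- .gate_ss_cpp(v, params)
  gates <- pmin(pmax(as.numeric(gates), 0), 1)
  if (length(gates) != 8L) stop("expected 8 gate variables")
  structure(list(v = v, gates = gates), class = "cell_state")
}

#' Total ionic current and gate rates at a state
#'
#' Evaluates the reaction term of the monodomain model: the summed six
#' currents (outward positive, mV/ms with unit capacitance) and the
#' instantaneous first-order rate of each gate.
#'
#' @inheritParams cell_state
#' @param state A [cell_state()].
#' @param upstroke_scale Multiplier on the sodium conductance (regional
#'   dVm/dt_max control).
#' @param apd_scale Divisor on the transient/delayed repolarising
#'   conductances `gto`, `gKr`, `gKur` (regional APD90 control; the
#'   background rectifier that sets the resting potential is not scaled).
#' @return List with `current` (mV/ms), `gate_rates` (per ms) and `gate_ss`.
#' @export
ionic_current <- function(state, params = cell_params(), upstroke_scale = 1,
                          apd_scale = 1) {
  .cell_rhs_cpp(state$v, state$gates, params, upstroke_scale, apd_scale)
}

#' Advance a single cell by one explicit step
#'
#' Forward Euler on the membrane potential and Rush-Larsen exponential
#' updates on the gates, the same scheme the tissue solver uses.
#'
#' @inheritParams ionic_current
#' @param dt Time step in ms.
#' @param stim Applied depolarising current in mV/ms during this step.
#' @return The updated `cell_state`.
#' @export
step_cell <- function(state, params = cell_params(), dt, stim = 0,
                      upstroke_scale = 1, apd_scale = 1) {
  stopifnot(dt > 0)
  out <- .step_cell_cpp(state$v, state$gates, params, upstroke_scale,
                        apd_scale, dt, stim)
  cell_state(out$v, out$gates, params)
}

#' Quiescent resting state of the cell model
#'
#' Root-finds the membrane potential at which the total ionic current
#' vanishes with every gate at its voltage steady state; this is the exact
#' fixed point of the integrator.
#'
#' @inheritParams ionic_current
#' @param interval Search interval in mV.
#' @return A `cell_state` at rest.
#' @export
rest_state <- function(params = cell_params(), upstroke_scale = 1,
                       apd_scale = 1, interval = c(-95, -55)) {
  f <- function(v) {
    .cell_rhs_cpp(v, .gate_ss_cpp(v, params), params, upstroke_scale,
                  apd_scale)$current
  }
  # walk the upper bracket up until the net current turns outward (large
  # sodium scales shift the zero crossing above the nominal interval)
  hi <- interval[2]
  while (f(hi) < 0 && hi < -30) hi <- hi + 5
  if (f(interval[1]) >= 0 || f(hi) < 0)
    stop("no stable resting potential in [", interval[1], ", ", hi, "] mV")
  v <- uniroot(f, c(interval[1], hi), tol = 1e-12)$root
  cell_state(v, params = params)
}

#' Simulate a single-cell action potential
#'
#' @inheritParams ionic_current
#' @param duration Total simulated time in ms.
#' @param dt Time step in ms.
#' @param stim_onset,stim_dur,stim_amp Square stimulus window (ms, ms,
#'   mV/ms). `stim_amp = NULL` uses twice the diastolic threshold.
#' @param v0 Initial potential; defaults to the resting state.
#' @param record_stride Record every this-many steps.
#' @return Data frame with columns `t` (ms) and `v` (mV).
#' @export
simulate_cell <- function(params = cell_params(), duration = 600, dt = 0.01,
                          stim_onset = 10, stim_dur = 2, stim_amp = NULL,
                          upstroke_scale = 1, apd_scale = 1, v0 = NULL,
                          record_stride = 10) {
  stopifnot(dt > 0, duration > 0)
  if (is.null(v0)) v0 <- rest_state(params, upstroke_scale, apd_scale)$v
  if (is.null(stim_amp))
    stim_amp <- 2 * diastolic_threshold(params, stim_dur, dt,
                                        upstroke_scale, apd_scale)
  n_steps <- ceiling(duration / dt)
  m <- .simulate_cell_cpp(params, upstroke_scale, apd_scale, v0,
                          numeric(0), dt, n_steps, stim_onset, stim_dur,
                          stim_amp, as.integer(record_stride))
  data.frame(t = m[, "t"], v = m[, "v"])
}

#' Minimal 2 ms stimulus current that elicits an action potential
#'
#' Bisection on the stimulus amplitude for a single resting cell; "fires"
#' means the potential exceeds -10 mV within 50 ms of stimulus onset.
#'
#' @inheritParams simulate_cell
#' @return Threshold amplitude in mV/ms.
#' @export
diastolic_threshold <- function(params = cell_params(), stim_dur = 2,
                                dt = 0.01, upstroke_scale = 1,
                                apd_scale = 1) {
  key <- paste0("thr_", signif(upstroke_scale, 6), "_",
                signif(apd_scale, 6), "_", stim_dur, "_", dt, "_",
                paste(signif(params, 8), collapse = ","))
  cached <- .ccsim_env$thresholds[[key]]
  if (!is.null(cached)) return(cached)
  v0 <- rest_state(params, upstroke_scale, apd_scale)$v
  fires <- function(amp) {
    n <- ceiling(52 / dt)
    m <- .simulate_cell_cpp(params, upstroke_scale, apd_scale, v0,
                            numeric(0), dt, n, 1, stim_dur, amp, 20L)
    max(m[, "v"]) > -10
  }
  lo <- 0; hi <- 2
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 5000) stop("cell cannot be excited by any plausible stimulus")
  }
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  if (is.null(.ccsim_env$thresholds)) .ccsim_env$thresholds <- list()
  .ccsim_env$thresholds[[key]] <- hi
  hi
}

#' Action potential duration at 90% repolarisation
#'
#' Measured from the time of maximum upstroke velocity to the first
#' subsequent return to within 10% of the action-potential amplitude above
#' the pre-stimulus baseline (the first sample of the trace).
#'
#' @param trace Data frame or matrix with columns `t` (ms) and `v` (mV).
#' @return APD90 in ms.
#' @export
apd90 <- function(trace) {
  t <- trace[, 1]; v <- trace[, 2]
  stopifnot(length(t) > 2)
  baseline <- v[1]
  dvdt <- diff(v) / diff(t)
  i_up <- which.max(dvdt)
  peak_i <- i_up + which.max(v[(i_up + 1):length(v)])
  amp <- v[peak_i] - baseline
  if (!is.finite(amp) || amp < 5 || max(dvdt) <= 0)
    stop("no action potential found in trace")
  thr <- baseline + 0.1 * amp
  below <- which(v[(peak_i):length(v)] <= thr)
  if (!length(below)) stop("trace does not repolarise to 90%")
  i_rep <- peak_i + below[1] - 1
  t[i_rep] - t[i_up]
}

#' Maximum upstroke velocity of a trace
#'
#' @inheritParams apd90
#' @return Maximum dV/dt in mV/ms.
#' @export
max_upstroke <- function(trace) {
  t <- trace[, 1]; v <- trace[, 2]
  max(diff(v) / diff(t))
}

#' Calibrate the sodium-conductance scale against a target conduction velocity
#'
#' Bisection on the upstroke (sodium) scale of working myocardium until a
#' planar wave in a 30 x 3 x 3 mm slab cable, simulated at the given
#' diffusion coefficient, grid spacing and time step, propagates at the
#' target velocity. The resulting scale is cached and becomes the baseline
#' multiplier of [default_region_table()].
#'
#' @param target_cv Target conduction velocity in m/s.
#' @param D Diffusion coefficient in mm^2/ms.
#' @param dx Grid spacing in mm.
#' @param dt Time step in ms.
#' @param params Cell parameter vector.
#' @param tol Relative CV tolerance for convergence.
#' @param bounds Search bounds for the scale.
#' @return The calibrated scale (numeric), with attribute `cv` giving the
#'   velocity measured at that scale.
#' @export
calibrate_excitability <- function(target_cv, D = 0.3, dx = 0.292,
                                   dt = 0.01, params = cell_params(),
                                   tol = 0.01, bounds = c(0.01, 100)) {
  stopifnot(target_cv > 0, D > 0, dx > 0, dt > 0)
  if (target_cv > dx / dt)
    stop("target conduction velocity ", target_cv,
         " m/s unreachable: faster than one grid cell per time step")
  cv_lo <- slab_cv(bounds[1], D, dx, dt, params)
  cv_hi <- slab_cv(bounds[2], D, dx, dt, params)
  if ((is.finite(cv_hi) && cv_hi < target_cv) ||
      (is.finite(cv_lo) && cv_lo > target_cv) ||
      (is.na(cv_hi) && is.na(cv_lo)))
    stop("target conduction velocity ", target_cv,
         " m/s unreachable within scale bounds [", bounds[1], ", ",
         bounds[2], "]")
  lo <- bounds[1]; hi <- bounds[2]; cv_mid <- NA_real_; mid <- NA_real_
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    cv_mid <- slab_cv(mid, D, dx, dt, params)
    if (is.finite(cv_mid) && abs(cv_mid - target_cv) / target_cv < tol) break
    if (is.na(cv_mid) || cv_mid < target_cv) lo <- mid else hi <- mid
  }
  if (!is.finite(cv_mid) || abs(cv_mid - target_cv) / target_cv >= tol)
    stop("conduction-velocity calibration did not converge")
  .ccsim_env$base_upstroke <- mid
  structure(mid, cv = cv_mid)
}

#' Currently calibrated baseline upstroke scale
#'
#' @return The scale cached by the last [calibrate_excitability()] call, or
#'   1 if none has been run.
#' @export
calibrated_upstroke <- function() {
  if (is.null(.ccsim_env$base_upstroke)) 1 else .ccsim_env$base_upstroke
}

#' Planar conduction velocity in the standard calibration slab
#'
#' Builds a 30 x 3 x 3 mm working-myocardium slab at spacing `dx`,
#' stimulates one end face and measures the velocity between probe planes
#' at 25% and 75% of the slab length.
#'
#' @inheritParams calibrate_excitability
#' @param upstroke_scale Sodium-conductance scale to simulate at.
#' @return CV in m/s, or `NA` if the wave fails to propagate.
#' @export
slab_cv <- function(upstroke_scale, D = 0.3, dx = 0.292, dt = 0.01,
                    params = cell_params()) {
  slab <- make_slab(c(30, 3, 3), dx, code = 4L)
  regions <- region_table(codes = 4L, D = D, upstroke = upstroke_scale,
                          apd = 1)
  config <- sim_config(dt = dt, duration = min(200 / sqrt(D / 0.3), 400),
                       early_stop_ms = 10)
  prot <- stimulus_protocol("custom", mask = slab_face_mask(slab, axis = 1L),
                            onset = 0, duration = 2, amplitude = NULL)
  tryCatch({
    res <- suppressWarnings(
      simulate(slab, regions, default_policy(), prot, config, params))
    nx <- dim(slab$codes)[1]
    xa <- 2L + as.integer(round(0.25 * (nx - 2)))
    xb <- 2L + as.integer(round(0.75 * (nx - 2)))
    measure_cv(res$activation_map, xa, xb, axis = 1L)
  }, error = function(e) {
    # a diverging explicit upstroke means the scale is far too large
    # (arbitrarily fast wave); a wave that never reaches the probes means
    # the scale is too small
    if (grepl("diverged", conditionMessage(e))) Inf else NA_real_
  })
}
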