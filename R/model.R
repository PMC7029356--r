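# model_core surface: stimulation protocols, right-hand side, currents,
# RyR fluxes and the trace-producing integrator.

#' Stimulation protocol
#'
#' Defines how the model is driven: paced with a square stimulus pulse,
#' voltage-clamped at a fixed potential, or free running.
#'
#' @param mode one of `"paced"`, `"clamp"`, `"free"`.
#' @param hz pacing frequency (Hz), paced mode.
#' @param beats number of paced beats.
#' @param stim_amp stimulus amplitude (A/F); negative is depolarizing.
#' @param stim_dur stimulus duration (ms).
#' @param clamp_v clamp potential (mV), clamp mode.
#' @param duration total duration (ms) for clamp and free modes.
#' @param sample_dt output sampling interval (ms), > 0.
#' @return a list of class `"protocol"`.
#' @export
protocol <- function(mode = c("paced", "clamp", "free"), hz = 1, beats = 1,
                     stim_amp = -40, stim_dur = 2, clamp_v = 0,
                     duration = 100, sample_dt = 1) {
  mode <- match.arg(mode)
  if (sample_dt <= 0) stop("sample_dt must be positive")
  if (mode == "paced") {
    if (beats < 0) stop("beats must be non-negative")
    if (hz <= 0) stop("pacing frequency must be positive")
  }
  structure(list(mode = mode, hz = hz, beats = beats, stim_amp = stim_amp,
                 stim_dur = stim_dur, clamp_v = clamp_v, duration = duration,
                 sample_dt = sample_dt),
            class = "protocol")
}

.as_param_vec <- function(params) {
  p <- unclass(params)
  if (!identical(names(p), .param_names)) {
    stop("params must be a full model_params vector; see model_parameters()")
  }
  as.numeric(p)
}

.as_state_vec <- function(state) {
  y <- unclass(state)
  if (!identical(names(y), .state_names)) {
    stop("state must be a full model_state vector; see model_state()")
  }
  validate_state(stats::setNames(as.numeric(y), .state_names))
  as.numeric(y)
}

#' Membrane currents at a model state
#'
#' Evaluates all membrane currents (A/F) and Ca2+ fluxes (mmol/ms) at a
#' given state. Gated currents are `g_x * o_x * (v - E_x)`; pumps and
#' exchangers follow their saturating kinetic forms.
#'
#' @param state model state vector.
#' @param params model parameters.
#' @param istim instantaneous stimulus current (A/F).
#' @return list with named numeric vectors `currents` and `fluxes`.
#' @export
compute_currents <- function(state, params, istim = 0) {
  res <- .bm_derivs(.as_state_vec(state), .as_param_vec(params), istim, FALSE)
  list(currents = stats::setNames(res$currents, .current_names),
       fluxes = stats::setNames(res$fluxes, .flux_names))
}

#' Time derivative of the model state
#'
#' The membrane potential obeys dv/dt = -sum(I_x); each compartment's free
#' Ca2+ follows its net flux divided by compartment volume, buffered Ca2+
#' mirrors the buffering flux, and RyR availability follows its
#' depletion/recovery balance. In clamp mode dv/dt is forced to zero.
#'
#' @inheritParams compute_currents
#' @param clamp logical; if `TRUE` the membrane potential derivative is 0.
#' @return named numeric derivative vector (per ms).
#' @export
model_rhs <- function(state, params, istim = 0, clamp = FALSE) {
  res <- .bm_derivs(.as_state_vec(state), .as_param_vec(params), istim, clamp)
  stats::setNames(res$deriv, .state_names)
}

#' RyR release fluxes
#'
#' Returns the availability-limited RyR release flux
#' `J_RyR = p * r * a_RyR * (c_s - c_sl)`, the constitutive leak
#' `J_leak = gamma_RyR * a_RyR * (c_s - c_sl)` and the open probability
#' `p = c_d^3 / (c_d^3 + kappa_RyR^3)`.
#'
#' @inheritParams compute_currents
#' @return list with `J_RyR`, `J_leak`, `p`.
#' @export
ryr_fluxes <- function(state, params) {
  fl <- compute_currents(state, params)$fluxes
  cd <- state[["c_d"]]
  kap <- params[["kappa_RyR"]]
  list(J_RyR = unname(fl["J_RyR"]), J_leak = unname(fl["J_leak"]),
       p = cd^3 / (cd^3 + kap^3))
}

#' Integrate the base model
#'
#' Deterministically integrates the model under a protocol with the
#' package's fixed-step Rush-Larsen scheme and returns a sampled trace.
#' For paced mode all beats are returned together with the index range of
#' the final (measurement) beat.
#'
#' @param params model parameters.
#' @param proto a [protocol()].
#' @param initial starting state; defaults to the preset resting state
#'   matching `params` when it carries a preset attribute.
#' @param record_currents if `TRUE`, per-current and per-flux columns are
#'   included in the trace.
#' @param keep_states if `TRUE`, all state columns are kept (otherwise the
#'   trace has `t`, `v`, `ca` plus any recorded currents).
#' @param dt integrator step (ms).
#' @return list of class `"sim_trace"` with elements `trace` (data frame),
#'   `final_beat` (row indices of the measurement beat, paced mode) and
#'   `protocol`.
#' @export
integrate_model <- function(params, proto, initial = NULL,
                            record_currents = FALSE, keep_states = FALSE,
                            dt = 0.02) {
  if (!inherits(proto, "protocol")) stop("proto must be a protocol()")
  if (is.null(initial)) {
    preset <- attr(params, "preset")
    if (is.null(preset) || preset == "custom") {
      stop("initial state required for non-preset parameters")
    }
    initial <- initial_state(preset)
  }
  pv <- .as_param_vec(params)
  yv <- .as_state_vec(initial)

  period <- 1000 / proto$hz
  duration <- switch(proto$mode,
    paced = proto$beats * period,
    clamp = proto$duration,
    free = proto$duration)
  mode <- match(proto$mode, c("paced", "clamp", "free")) - 1L

  res <- .bm_integrate(pv, yv, mode, duration, period, proto$stim_amp,
                       proto$stim_dur, proto$clamp_v, proto$sample_dt, dt,
                       record_currents || keep_states || TRUE)
  cols <- c("t", .state_names, .current_names, .flux_names)
  tr <- as.data.frame(res$trace)
  names(tr) <- cols[seq_len(ncol(tr))]

  if (res$status != 0) {
    cond <- structure(
      class = c("cardioinverse_solver_error", "error", "condition"),
      list(message = sprintf(
             "solver failure (state blow-up) at t = %.3f ms", res$t_fail),
           call = sys.call(-1), t_fail = res$t_fail,
           partial = tr))
    stop(cond)
  }

  tr$ca <- tr$c_c
  keep <- c("t", "v", "ca")
  if (keep_states) keep <- c("t", .state_names, "ca")
  if (record_currents) keep <- c(keep, .current_names, .flux_names)
  tr <- tr[, unique(keep), drop = FALSE]

  final_beat <- NULL
  if (proto$mode == "paced" && proto$beats >= 1) {
    t0 <- (proto$beats - 1) * period
    final_beat <- which(tr$t >= t0 - 1e-9)
  }
  structure(list(trace = tr, final_beat = final_beat, protocol = proto),
            class = "sim_trace")
}

#' Extract the measurement beat of a paced simulation as a Trace
#'
#' @param sim result of [integrate_model()] in paced mode.
#' @param rebase if `TRUE` time is shifted so the beat starts at 0 ms.
#' @return data frame with columns `t`, `v`, `ca` (and any recorded
#'   currents), one pacing cycle long.
#' @export
measurement_beat <- function(sim, rebase = TRUE) {
  if (!inherits(sim, "sim_trace") || is.null(sim$final_beat)) {
    stop("sim must be a paced sim_trace with at least one beat")
  }
  tr <- sim$trace[sim$final_beat, , drop = FALSE]
  if (rebase) tr$t <- tr$t - tr$t[1]
  rownames(tr) <- NULL
  tr
}
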