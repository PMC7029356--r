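# drug_study: synthetic dose-escalation studies, the graded-release clamp
# experiment, optical-trace preprocessing and the adult prediction step.

#' Specification of a simulated drug study
#'
#' Describes a synthetic dose-escalation experiment: the true IC50 per
#' targeted current, the dose ladder, a background density perturbation
#' applied to the generating model (mimicking cell-line variability), and
#' the beat that is recorded after each parameter change.
#'
#' @param name drug name.
#' @param ic50 named vector of true IC50s, names among `CaL`, `NaL`, `Kr`,
#'   in `units`.
#' @param doses strictly increasing non-zero dose ladder in `units`; if
#'   `NULL`, a 4-point geometric ladder from `min(ic50)/8` to
#'   `1.6 * max(ic50)` is used, so that every targeted channel is probed
#'   both well below and beyond its half-blocking concentration.
#' @param units concentration unit label.
#' @param lambda_bg named background adjustment factors applied to the
#'   generating model (default 0.1 on CaL, NaL and Kr densities).
#' @param beat index of the recorded AP after each parameter change.
#' @return list of class `"drug_spec"`.
#' @export
simulated_drug_spec <- function(name, ic50, doses = NULL, units = "nM",
                                lambda_bg = c(lambda_CaL = 0.1,
                                              lambda_NaL = 0.1,
                                              lambda_Kr = 0.1),
                                beat = 6) {
  stopifnot(all(names(ic50) %in% c("CaL", "NaL", "Kr")), all(ic50 > 0))
  if (is.null(doses)) {
    doses <- exp(seq(log(min(ic50) / 8), log(1.6 * max(ic50)),
                     length.out = 4))
  }
  if (any(diff(doses) <= 0) || any(doses <= 0)) {
    stop("doses must be strictly increasing and positive")
  }
  structure(list(name = name, ic50 = ic50, doses = doses, units = units,
                 lambda_bg = lambda_bg, beat = beat),
            class = "drug_spec")
}

#' The five shipped simulated drug studies
#'
#' Nifedipine (pure CaL blocker, IC50 10 nM, doses 3/30/300/3000 nM),
#' Lidocaine (pure NaL, 10 uM), Cisapride (pure Kr, 10 nM), Flecainide
#' (CaL 25 uM, NaL 20 uM, Kr 10 uM) and Verapamil (CaL 200 nM,
#' Kr 500 nM). Only the Nifedipine ladder is fixed by convention; the
#' others use the default geometric ladder spanning the targets' IC50s.
#'
#' @return named list of [simulated_drug_spec()] objects.
#' @export
shipped_drug_specs <- function() {
  list(
    nifedipine = simulated_drug_spec("Nifedipine", c(CaL = 10),
                                     doses = c(3, 30, 300, 3000),
                                     units = "nM"),
    lidocaine = simulated_drug_spec("Lidocaine", c(NaL = 10), units = "uM"),
    cisapride = simulated_drug_spec("Cisapride", c(Kr = 10), units = "nM"),
    flecainide = simulated_drug_spec("Flecainide",
                                     c(CaL = 25, NaL = 20, Kr = 10),
                                     units = "uM"),
    verapamil = simulated_drug_spec("Verapamil", c(CaL = 200, Kr = 500),
                                    units = "nM")
  )
}

#' Assemble a dose escalation dataset
#'
#' @param traces list of trace data frames (`t`, `v`, `ca`), one per dose
#'   including the control first.
#' @param doses numeric doses matching `traces`; first must be 0.
#' @param units concentration unit label.
#' @param meta list of provenance metadata; must include `preset`, `beats`
#'   and `hz` so cost evaluations can reproduce the protocol.
#' @return list of class `"dose_escalation_dataset"`.
#' @export
dose_escalation_dataset <- function(traces, doses, units, meta) {
  if (length(traces) != length(doses)) stop("one trace per dose required")
  if (doses[1] != 0) stop("first entry must be the control (dose 0)")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  for (req in c("preset", "beats", "hz")) {
    if (is.null(meta[[req]])) stop("meta$", req, " is required")
  }
  structure(list(traces = traces, doses = doses, units = units, meta = meta),
            class = "dose_escalation_dataset")
}

#' Generate a synthetic dose escalation dataset
#'
#' For the control and each dose, applies the background adjustment
#' factors and the IC50-based block to the preset model, paces it, and
#' records the configured beat. Generation is deterministic: no noise is
#' added and no random numbers are drawn.
#'
#' @param spec a [simulated_drug_spec()].
#' @param preset base preset to perturb (default `"hipsc"`).
#' @param hz pacing frequency.
#' @return a [dose_escalation_dataset()].
#' @export
generate_dose_escalation <- function(spec, preset = "hipsc", hz = 1) {
  base <- model_parameters(preset)
  lam <- do.call(adjustment_factors, as.list(spec$lambda_bg))
  ctrl <- apply_adjustments(base, lam)
  eps <- c(CaL = 0, NaL = 0, Kr = 0)
  eps[names(spec$ic50)] <- 1 / spec$ic50
  drug <- drug_effect(eps_CaL = eps[["CaL"]], eps_NaL = eps[["NaL"]],
                      eps_Kr = eps[["Kr"]], doses = spec$doses,
                      units = spec$units)
  proto <- protocol(mode = "paced", hz = hz, beats = spec$beat)
  initial <- initial_state(preset)
  doses <- c(0, spec$doses)
  traces <- lapply(doses, function(D) {
    pd <- apply_drug(ctrl, drug, D)
    sim <- tryCatch(integrate_model(pd, proto, initial = initial),
                    error = function(e) {
                      stop("simulation failed at dose ", D, " ", spec$units,
                           ": ", conditionMessage(e))
                    })
    measurement_beat(sim)
  })
  dose_escalation_dataset(traces, doses, spec$units,
                          meta = list(preset = preset, beats = spec$beat,
                                      hz = hz, drug = spec$name,
                                      true_ic50 = spec$ic50,
                                      lambda_bg = spec$lambda_bg,
                                      source = "synthetic"))
}

#' Graded-release voltage clamp experiment
#'
#' Clamps the membrane potential at each grid value, starting from the
#' preset's resting state, and integrates the L-type trigger flux and the
#' RyR release flux for `duration` ms. High gain shows as the integrated
#' release exceeding the integrated trigger; graded release as the peak
#' release increasing with the peak trigger along the ascending limb.
#'
#' @param preset `"adult"` or `"hipsc"` (or a `model_params` object).
#' @param vgrid clamp potentials (mV) within \[-50, 80\].
#' @param duration clamp duration (ms).
#' @param sample_dt sampling interval (ms) for the integrals.
#' @return data frame with per-clamp peak and integrated `J_CaL`/`J_RyR`.
#' @export
graded_release_experiment <- function(preset = "hipsc",
                                      vgrid = seq(-50, 80, by = 10),
                                      duration = 100, sample_dt = 0.5) {
  if (any(vgrid < -50 | vgrid > 80)) {
    stop("clamp grid must lie within [-50, 80] mV")
  }
  if (is.character(preset)) {
    params <- model_parameters(preset)
    initial <- initial_state(preset)
  } else {
    params <- preset
    initial <- initial_state(attr(params, "preset"))
  }
  rows <- lapply(vgrid, function(vc) {
    sim <- integrate_model(params,
                           protocol(mode = "clamp", clamp_v = vc,
                                    duration = duration,
                                    sample_dt = sample_dt),
                           initial = initial, record_currents = TRUE)
    tr <- sim$trace
    dt <- diff(tr$t)
    integ <- function(y) sum((y[-1] + y[-length(y)]) / 2 * dt)
    data.frame(v_clamp = vc,
               peak_J_CaL = max(tr$J_CaL), peak_J_RyR = max(tr$J_RyR),
               int_J_CaL = integ(tr$J_CaL), int_J_RyR = integ(tr$J_RyR))
  })
  do.call(rbind, rows)
}

#' Preprocess optically recorded beats into one representative beat
#'
#' Applies a 3-point median filter to each channel, aligns the beats at
#' the sample of maximum first difference of the voltage channel (integer
#' shifts), trims to the common support and averages, mirroring standard
#' processing of fluorescence recordings.
#'
#' @param beats list of >= 2 trace data frames (`t`, `v`, `ca`) at a
#'   common frame rate.
#' @param frame_rate frames per second; used to rebuild the time axis.
#' @return single averaged trace data frame in the input units.
#' @export
preprocess_optical <- function(beats, frame_rate = 200) {
  if (length(beats) < 2) stop("at least two beats are required")
  med3 <- function(y) as.numeric(stats::runmed(y, 3, endrule = "keep"))
  filt <- lapply(beats, function(b) {
    data.frame(v = med3(b$v), ca = med3(b$ca))
  })
  anchor <- vapply(filt, function(b) which.max(diff(b$v)), integer(1))
  lead <- min(anchor - 1L)
  tail_len <- min(vapply(filt, nrow, integer(1)) - anchor)
  n <- lead + tail_len + 1L
  if (n < 2) stop("beats share no common support after alignment")
  aligned <- lapply(filt, function(b) {
    i0 <- which.max(diff(b$v))
    b[(i0 - lead):(i0 + tail_len), , drop = FALSE]
  })
  v <- rowMeans(do.call(cbind, lapply(aligned, `[[`, "v")))
  ca <- rowMeans(do.call(cbind, lapply(aligned, `[[`, "ca")))
  data.frame(t = (seq_len(n) - 1) * 1000 / frame_rate, v = v, ca = ca)
}

#' Predict the adult drug response from an hiPSC-CM fit
#'
#' Applies the fitted potencies unchanged to the adult model (the
#' single-channel invariance assumption: a drug blocks an individual
#' channel identically at both maturity stages) and simulates every dose
#' of the ladder.
#'
#' @param eps named fitted potencies (`CaL`, `NaL`, `Kr`), or an
#'   [invert()] result.
#' @param doses dose ladder (0 = control prepended if absent).
#' @param adult_base adult parameter set.
#' @param units concentration unit label.
#' @param beats paced beats before the recorded AP.
#' @return a [dose_escalation_dataset()] of predicted adult traces.
#' @export
predict_adult_response <- function(eps, doses,
                                   adult_base = model_parameters("adult"),
                                   units = "nM", beats = 6) {
  if (inherits(eps, "inversion_result")) {
    if (missing(doses)) doses <- eps$doses
    if (missing(units)) units <- eps$units
    eps <- eps$eps
  }
  eps_full <- c(CaL = 0, NaL = 0, Kr = 0)
  eps_full[names(eps)] <- as.numeric(eps)
  if (length(doses) == 0 || doses[1] != 0) doses <- c(0, doses)
  drug <- drug_effect(eps_CaL = eps_full[["CaL"]], eps_NaL = eps_full[["NaL"]],
                      eps_Kr = eps_full[["Kr"]], doses = setdiff(doses, 0),
                      units = units)
  proto <- protocol(mode = "paced", beats = beats)
  initial <- initial_state("adult")
  traces <- lapply(doses, function(D) {
    pd <- apply_drug(adult_base, drug, D)
    measurement_beat(integrate_model(pd, proto, initial = initial))
  })
  dose_escalation_dataset(traces, doses, units,
                          meta = list(preset = "adult", beats = beats,
                                      hz = 1, source = "adult-prediction"))
}
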