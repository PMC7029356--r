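# Model parameter sets, presets and state definitions.

.param_names <- c(
  "g_Na", "g_NaL", "g_CaL", "g_to", "g_Kr", "g_Ks", "g_K1", "g_NaK",
  "g_NaCa", "g_pCa", "g_bCa", "g_bCl", "g_f",
  "a_RyR", "b_RyR", "gamma_RyR", "eta_RyR", "kappa_RyR",
  "g_SERCA", "k_SERCA",
  "B_d", "B_sl", "B_c", "B_s",
  "kon_d", "kon_sl", "kon_c", "kon_s",
  "koff_d", "koff_sl", "koff_c", "koff_s",
  "a_dc", "a_slc", "a_ns",
  "V_cell", "chi", "C_m",
  "frac_d", "frac_sl", "frac_c", "frac_s", "frac_n",
  "Nai", "Ki", "Nao", "Ko", "Cao",
  "E_f", "E_Cl", "k_fCa"
)

.state_names <- c(
  "v",
  "m", "h", "j", "mL", "hL", "d", "f", "fCa",
  "r_to", "s_to", "xr1", "xr2", "xs", "xf",
  "c_d", "c_sl", "c_c", "c_s", "c_n",
  "b_d", "b_sl", "b_c", "b_s",
  "r"
)

.current_names <- c(
  "I_Na", "I_NaL", "I_CaL", "I_to", "I_Kr", "I_Ks", "I_K1", "I_NaK",
  "I_NaCa", "I_pCa", "I_bCa", "I_bCl", "I_f", "I_stim"
)

.flux_names <- c(
  "J_CaL", "J_esl", "J_dc", "J_slc", "J_ns", "J_RyR", "J_leak",
  "J_SERCA", "J_db", "J_slb", "J_cb", "J_sb"
)

# currents whose densities carry a lambda adjustment factor, in the fixed
# ordering shared by AdjustmentFactors, the current matrix and the
# identifiability analysis
.lambda_currents <- c(
  "Na", "NaL", "CaL", "to", "Kr", "Ks", "K1", "NaK", "NaCa", "pCa",
  "bCa", "bCl", "f"
)

#' Model parameters for one maturity stage
#'
#' Construct a validated parameter set for the base model. Parameters are
#' lumped channel densities `g_x` (dimensioned so currents are in A/F),
#' RyR release constants, SERCA density, buffer totals and rate constants
#' per compartment, inter-compartment diffusion rates, geometry and fixed
#' ionic concentrations. Start from a preset (see [model_parameters()]
#' presets `"adult"` and `"hipsc"`) and override individual values.
#'
#' @param preset `"adult"` or `"hipsc"`. The adult parameterization is the
#'   default base model; the hiPSC-CM preset is derived from it through the
#'   shipped maturation factors (surface-to-volume ratio 0.9 1/um instead
#'   of 0.6 1/um, reduced fast sodium, inward rectifier and transient
#'   outward densities, a substantial funny current, and rescaled Ca2+
#'   handling).
#' @param ... named numeric overrides of individual parameters.
#' @return a named numeric vector of class `"model_params"`.
#' @export
model_parameters <- function(preset = c("adult", "hipsc"), ...) {
  preset <- match.arg(preset)
  p <- if (preset == "adult") .adult_defaults() else .hipsc_defaults()
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .param_names)
    if (length(bad)) {
      stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(dots)] <- as.numeric(unlist(dots))
  }
  validate_parameters(p)
  structure(p, class = "model_params", preset = preset)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> preset:", attr(x, "preset") %||% "custom", "\n")
  print(unclass(stats::setNames(as.numeric(x), names(x))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_parameters <- function(p) {
  if (!is.numeric(p) || length(p) != length(.param_names) ||
      !identical(names(p), .param_names)) {
    stop("parameter vector must carry the full named parameter set")
  }
  if (any(!is.finite(p))) {
    stop("non-finite model parameter: ",
         paste(names(p)[!is.finite(p)], collapse = ", "))
  }
  nonneg <- setdiff(.param_names, c("E_f", "E_Cl"))
  if (any(p[nonneg] < 0)) {
    stop("negative value for parameter(s): ",
         paste(intersect(names(p)[p < 0], nonneg), collapse = ", "))
  }
  fr <- p[c("frac_d", "frac_sl", "frac_c", "frac_s", "frac_n")]
  if (sum(fr) > 1) stop("compartment volume fractions sum to more than 1")
  if (p["kappa_RyR"] <= 0) stop("kappa_RyR must be positive")
  invisible(p)
}

# The default base model: generic adult ventricular parameterization.
# Channel densities are tuned in-house so that the 1 Hz paced AP and Ca2+
# transient, SR gain and identifiability structure are physiological; see
# the methods vignette for the tuning targets.
.adult_defaults <- function() {
  p <- c(
    g_Na = 14.838, g_NaL = 0.040, g_CaL = 2.2e-4, g_to = 0.10,
    g_Kr = 0.07, g_Ks = 0.10, g_K1 = 5.405, g_NaK = 1.362,
    g_NaCa = 150, g_pCa = 0.02, g_bCa = 0.002, g_bCl = 0.0040,
    g_f = 2.0e-4,
    a_RyR = 3.0e-13, b_RyR = 1.5e-13, gamma_RyR = 5.0e-4,
    eta_RyR = 0.10, kappa_RyR = 0.003,
    g_SERCA = 8.0e-14, k_SERCA = 4.0e-4,
    B_d = 1.0, B_sl = 0.40, B_c = 0.070, B_s = 6.0,
    kon_d = 5, kon_sl = 10, kon_c = 32.7, kon_s = 2.5,
    koff_d = 0.065, koff_sl = 0.13, koff_c = 0.0196, koff_s = 1.625,
    a_dc = 3.3e-13, a_slc = 2.2e-13, a_ns = 1.6e-14,
    V_cell = 3.3e-11, chi = 0.6, C_m = 0.01,
    frac_d = 0.001, frac_sl = 0.02, frac_c = 0.65,
    frac_s = 0.005, frac_n = 0.03,
    Nai = 10, Ki = 140, Nao = 140, Ko = 5.4, Cao = 1.8,
    E_f = -17, E_Cl = -61.5, k_fCa = 0.0015
  )
  p[.param_names]
}

# Maturation factors between the shipped hiPSC-CM and adult presets:
# (1 + lambda) * p_hiPSC = p_adult, so the hiPSC preset is the adult
# preset divided elementwise by these factors. Buffer factors are stored
# per compartment for the shipped presets even though newly fitted
# adjustment factors share a single lambda_B.
.maturation_lambda <- function() {
  c(
    Na = 2.00, NaL = -0.08, CaL = -0.53, to = 8.45, Kr = -0.54,
    Ks = 0.68, K1 = 2.23, NaK = -0.16, NaCa = -0.69, pCa = -0.85,
    bCa = 3.90, bCl = 42.43, f = -0.99,
    RyR = -0.20, SERCA = -0.53,
    Bd = -0.72, Bsl = -0.60, Bc = -0.56, Bs = -0.58,
    dc = -0.61, slc = -0.14, ns = -0.10,
    chi = -0.33
  )
}

.hipsc_defaults <- function() {
  p <- .adult_defaults()
  lam <- .maturation_lambda()
  for (x in .lambda_currents) {
    p[paste0("g_", x)] <- p[paste0("g_", x)] / (1 + lam[[x]])
  }
  p["a_RyR"] <- p["a_RyR"] / (1 + lam[["RyR"]])
  p["b_RyR"] <- p["b_RyR"] / (1 + lam[["RyR"]])
  p["g_SERCA"] <- p["g_SERCA"] / (1 + lam[["SERCA"]])
  p["B_d"] <- p["B_d"] / (1 + lam[["Bd"]])
  p["B_sl"] <- p["B_sl"] / (1 + lam[["Bsl"]])
  p["B_c"] <- p["B_c"] / (1 + lam[["Bc"]])
  p["B_s"] <- p["B_s"] / (1 + lam[["Bs"]])
  p["a_dc"] <- p["a_dc"] / (1 + lam[["dc"]])
  p["a_slc"] <- p["a_slc"] / (1 + lam[["slc"]])
  p["a_ns"] <- p["a_ns"] / (1 + lam[["ns"]])
  p["chi"] <- p["chi"] / (1 + lam[["chi"]])
  p["V_cell"] <- 3.0e-12
  # geometry-linked absolute rates scale with cell volume so that the
  # per-compartment equilibration time constants are preserved
  vr <- 3.0e-12 / 3.3e-11
  p[c("a_dc", "a_slc", "a_ns", "a_RyR", "b_RyR", "g_SERCA")] <-
    p[c("a_dc", "a_slc", "a_ns", "a_RyR", "b_RyR", "g_SERCA")] * vr
  p
}

#' Model state vector
#'
#' Build a full model state: membrane potential (mV), gating variables,
#' free and buffered Ca2+ per compartment (mM) and RyR availability.
#'
#' @param preset resting state of which shipped preset to use as template.
#' @param ... named overrides of individual state variables.
#' @return named numeric vector of class `"model_state"`.
#' @export
model_state <- function(preset = c("adult", "hipsc"), ...) {
  preset <- match.arg(preset)
  y <- initial_state(preset)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .state_names)
    if (length(bad)) stop("unknown state variable(s): ",
                          paste(bad, collapse = ", "))
    y[names(dots)] <- as.numeric(unlist(dots))
  }
  validate_state(y)
  structure(y, class = "model_state")
}

validate_state <- function(y) {
  if (!identical(names(y), .state_names)) {
    stop("state vector must carry the full named state set")
  }
  if (any(!is.finite(y))) {
    stop("non-finite state variable: ",
         paste(names(y)[!is.finite(y)], collapse = ", "))
  }
  conc <- c("c_d", "c_sl", "c_c", "c_s", "c_n", "b_d", "b_sl", "b_c", "b_s")
  if (any(y[conc] < 0)) {
    stop("negative concentration: ",
         paste(intersect(names(y)[y < 0], conc), collapse = ", "))
  }
  gates <- c("m", "h", "j", "mL", "hL", "d", "f", "fCa", "r_to", "s_to",
             "xr1", "xr2", "xs", "xf", "r")
  if (any(y[gates] < 0 | y[gates] > 1)) {
    stop("gating variable outside [0, 1]: ",
         paste(gates[y[gates] < 0 | y[gates] > 1], collapse = ", "))
  }
  invisible(y)
}

#' Resting initial conditions for a shipped preset
#'
#' Returns the stored quiescent-pacing steady state of the preset (the
#' state reached after prolonged 1 Hz pacing of the default
#' parameterization, computed once with [steady_state()] and stored).
#'
#' @param preset `"adult"` or `"hipsc"`.
#' @return named numeric state vector.
#' @export
initial_state <- function(preset = c("adult", "hipsc")) {
  preset <- match.arg(preset)
  y <- if (preset == "adult") .adult_rest else .hipsc_rest
  stats::setNames(y, .state_names)
}

#' Pace a model to an approximate steady state
#'
#' Runs `beats` paced cycles and returns the final state; used to
#' regenerate the stored preset initial conditions.
#'
#' @param params model parameters.
#' @param beats number of 1 Hz conditioning beats.
#' @param hz pacing frequency.
#' @param from optional starting state (defaults to a generic rest state).
#' @return named numeric state vector.
#' @export
steady_state <- function(params, beats = 100, hz = 1, from = NULL) {
  if (is.null(from)) from <- .generic_rest()
  tr <- integrate_model(params, protocol(mode = "paced", hz = hz,
                                         beats = beats),
                        initial = from, keep_states = TRUE)
  st <- as.numeric(tr$trace[nrow(tr$trace), .state_names])
  stats::setNames(st, .state_names)
}

.generic_rest <- function() {
  y <- stats::setNames(numeric(length(.state_names)), .state_names)
  y["v"] <- -80
  y["m"] <- 0.003; y["h"] <- 0.7; y["j"] <- 0.7
  y["mL"] <- 0.001; y["hL"] <- 0.6
  y["d"] <- 0; y["f"] <- 1; y["fCa"] <- 1
  y["r_to"] <- 0; y["s_to"] <- 1
  y["xr1"] <- 0; y["xr2"] <- 0.4; y["xs"] <- 0; y["xf"] <- 0.1
  y["c_d"] <- 1e-4; y["c_sl"] <- 1e-4; y["c_c"] <- 1e-4
  y["c_s"] <- 0.5; y["c_n"] <- 0.5
  y["b_d"] <- 0.0076; y["b_sl"] <- 0.003; y["b_c"] <- 0.01; y["b_s"] <- 1.13
  y["r"] <- 0.9
  y
}
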