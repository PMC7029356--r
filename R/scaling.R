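# scaling_maturation: lambda adjustment factors, IC50/epsilon drug block
# and the hiPSC -> adult maturation map.

.lambda_names <- c(
  paste0("lambda_", .lambda_currents),
  "lambda_RyR", "lambda_SERCA", "lambda_B", "lambda_alpha", "lambda_chi"
)

#' Adjustment factors for channel densities and geometry
#'
#' A lambda vector scaling the default base model into a fitted cell model:
#' per-current membrane channel densities, RyR and SERCA densities, one
#' shared buffer factor, one shared intracellular-diffusion factor, and a
#' surface-to-volume factor. Every density is multiplied by `(1 + lambda)`,
#' so each lambda must exceed -1.
#'
#' @param ... named values `lambda_<x>` with
#'   `x` in `Na, NaL, CaL, to, Kr, Ks, K1, NaK, NaCa, pCa, bCa, bCl, f,
#'   RyR, SERCA, B, alpha, chi`. Unspecified factors are 0.
#' @return named numeric vector of class `"adjustment_factors"`.
#' @export
adjustment_factors <- function(...) {
  lam <- stats::setNames(numeric(length(.lambda_names)), .lambda_names)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .lambda_names)
    if (length(bad)) stop("unknown adjustment factor(s): ",
                          paste(bad, collapse = ", "))
    lam[names(dots)] <- as.numeric(unlist(dots))
  }
  validate_lambda(lam)
  structure(lam, class = "adjustment_factors")
}

validate_lambda <- function(lam) {
  if (any(!is.finite(lam))) stop("non-finite adjustment factor")
  if (any(1 + lam <= 0)) {
    stop("adjustment factor(s) at or below -1 (density must stay positive): ",
         paste(names(lam)[1 + lam <= 0], collapse = ", "))
  }
  invisible(lam)
}

#' Apply adjustment factors to a parameter set
#'
#' Multiplies every density-like parameter by its `(1 + lambda)`: the 13
#' membrane channel densities, the RyR release rate and depletion scale
#' (which share `lambda_RyR`), the SERCA density, all four buffer totals
#' (shared `lambda_B`), all three diffusion rates (shared `lambda_alpha`)
#' and the surface-to-volume ratio. Single-channel kinetics are untouched.
#'
#' @param base model parameters.
#' @param lam an [adjustment_factors()] vector.
#' @return adjusted `model_params`.
#' @export
apply_adjustments <- function(base, lam) {
  if (!inherits(lam, "adjustment_factors")) {
    lam <- do.call(adjustment_factors, as.list(lam))
  }
  validate_lambda(lam)
  p <- unclass(base)
  for (x in .lambda_currents) {
    p[paste0("g_", x)] <- p[paste0("g_", x)] * (1 + lam[[paste0("lambda_", x)]])
  }
  p["a_RyR"] <- p["a_RyR"] * (1 + lam[["lambda_RyR"]])
  p["b_RyR"] <- p["b_RyR"] * (1 + lam[["lambda_RyR"]])
  p["g_SERCA"] <- p["g_SERCA"] * (1 + lam[["lambda_SERCA"]])
  for (b in c("B_d", "B_sl", "B_c", "B_s")) {
    p[b] <- p[b] * (1 + lam[["lambda_B"]])
  }
  for (a in c("a_dc", "a_slc", "a_ns")) {
    p[a] <- p[a] * (1 + lam[["lambda_alpha"]])
  }
  p["chi"] <- p["chi"] * (1 + lam[["lambda_chi"]])
  structure(p, class = "model_params", preset = attr(base, "preset"))
}

#' Drug effect: inverse-IC50 potencies and a dose ladder
#'
#' Represents a channel blocker by `epsilon = 1/IC50` for each targeted
#' current (`CaL`, `NaL`, `Kr`) plus a strictly increasing dose ladder
#' whose first entry `D_0 = 0` is the control.
#'
#' @param eps_CaL,eps_NaL,eps_Kr potencies in inverse concentration units
#'   (must be >= 0; 0 means the current is untouched).
#' @param doses numeric dose ladder; a leading 0 (control) is added if
#'   absent.
#' @param units concentration unit label (informational), e.g. `"nM"`.
#' @return list of class `"drug_effect"`.
#' @export
drug_effect <- function(eps_CaL = 0, eps_NaL = 0, eps_Kr = 0,
                        doses = numeric(), units = "nM") {
  eps <- c(CaL = eps_CaL, NaL = eps_NaL, Kr = eps_Kr)
  if (any(eps < 0) || any(!is.finite(eps))) {
    stop("epsilon values must be finite and non-negative")
  }
  doses <- as.numeric(doses)
  if (length(doses) == 0 || doses[1] != 0) doses <- c(0, doses)
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  structure(list(eps = eps, doses = doses, units = units),
            class = "drug_effect")
}

#' Apply a channel blocker at one dose
#'
#' Scales each targeted conductance by the dose-response factor
#' `1 / (1 + D * epsilon)`; at `D = IC50` this is exactly one half (50%
#' block). All other parameters are returned unchanged.
#'
#' @param control model parameters in the absence of drug.
#' @param drug a [drug_effect()].
#' @param dose drug concentration (same units as the epsilons), >= 0.
#' @return blocked `model_params`.
#' @export
apply_drug <- function(control, drug, dose) {
  if (!inherits(drug, "drug_effect")) stop("drug must be a drug_effect()")
  if (!is.numeric(dose) || length(dose) != 1 || dose < 0) {
    stop("dose must be a single non-negative number")
  }
  p <- unclass(control)
  for (x in names(drug$eps)) {
    p[paste0("g_", x)] <- p[paste0("g_", x)] / (1 + dose * drug$eps[[x]])
  }
  structure(p, class = "model_params", preset = attr(control, "preset"))
}

#' Convert between epsilon and IC50
#'
#' `epsilon = 1/IC50`; both carry reciprocal concentration units.
#' An epsilon of zero has no finite IC50 and is reported as `NA` with
#' the interpretation "no detectable block within the tested range".
#'
#' @param eps potency (inverse concentration), > 0 for a finite IC50.
#' @return IC50 in the reciprocal units of `eps` (`NA` if `eps` is 0).
#' @export
epsilon_to_ic50 <- function(eps) {
  if (any(eps < 0)) stop("epsilon must be non-negative")
  out <- ifelse(eps == 0, NA_real_, 1 / eps)
  if (any(eps == 0)) {
    warning("epsilon of 0: no detectable block / IC50 above tested range")
  }
  out
}

#' @rdname epsilon_to_ic50
#' @param ic50 half-blocking concentration, > 0.
#' @export
ic50_to_epsilon <- function(ic50) {
  if (any(ic50 <= 0)) stop("IC50 must be positive")
  1 / ic50
}

#' Maturation map between two parameter sets
#'
#' The per-parameter multiplicative map `Q` with
#' `Q * p_immature = p_mature`, representing changed channel densities and
#' geometry with unchanged single-channel function. Applying the map to a
#' drugged immature parameterization predicts the drugged mature model.
#'
#' @param hipsc immature (hiPSC-CM) parameter set.
#' @param adult mature parameter set sharing the same structure.
#' @return named numeric factor vector of class `"maturation_map"`.
#' @export
build_maturation_map <- function(hipsc, adult) {
  ph <- unclass(hipsc); pa <- unclass(adult)
  if (!identical(names(ph), names(pa))) {
    stop("parameter sets must share structure")
  }
  bad <- names(pa)[pa == 0 & ph != 0]
  if (length(bad)) {
    stop("undefined ratio: zero-valued mature parameter with nonzero ",
         "immature counterpart: ", paste(bad, collapse = ", "))
  }
  q <- ifelse(ph == 0 & pa == 0, 1, pa / ph)
  structure(stats::setNames(q, names(pa)), class = "maturation_map")
}

#' Apply a maturation map
#'
#' @param map a [build_maturation_map()] result.
#' @param params immature-stage parameters (possibly drugged).
#' @return mature-stage `model_params`.
#' @export
apply_maturation_map <- function(map, params) {
  if (!inherits(map, "maturation_map")) stop("map must be a maturation_map")
  p <- unclass(params) * unclass(map)
  structure(p, class = "model_params", preset = "adult")
}

#' Invert a maturation map
#'
#' @param map a maturation map.
#' @return the elementwise inverse map (mature -> immature).
#' @export
invert_maturation_map <- function(map) {
  structure(1 / unclass(map), class = "maturation_map")
}

#' Format an IC50 report table
#'
#' Formats inversion-estimated potencies as an IC50 table with one row per
#' targeted current, in the unit of the fitted dose ladder.
#'
#' @param eps named potency vector (`CaL`, `NaL`, `Kr`).
#' @param units concentration unit of the reciprocal potencies.
#' @return data frame with columns `current`, `epsilon`, `IC50`, `units`.
#' @export
ic50_report <- function(eps, units = "nM") {
  ic <- suppressWarnings(epsilon_to_ic50(as.numeric(eps)))
  data.frame(current = names(eps), epsilon = as.numeric(eps),
             IC50 = ic, units = units, row.names = NULL)
}

#' Shipped maturation factors between the default presets
#'
#' The lambda values defining the map between the shipped hiPSC-CM and
#' adult presets (`(1 + lambda) * p_hipsc = p_adult`), including the
#' per-compartment buffer factors the presets store.
#'
#' @return named numeric vector.
#' @export
preset_maturation_lambda <- function() .maturation_lambda()
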