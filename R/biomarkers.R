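# biomarkers_cost: waveform characteristics of AP / Ca2+ traces, the
# weighted multi-dose cost function and its continuation variant.

.apd_percents <- c(30, 50, 80)
.cad_percents <- seq(20, 80, by = 10)

# linearly interpolated crossing time of `level`, first crossing of the
# given sign within index range [from, to]
.crossing <- function(t, y, level, from, to, rising = TRUE) {
  if (from >= to) return(NA_real_)
  idx <- from:(to - 1)
  hit <- if (rising) {
    which(y[idx] < level & y[idx + 1] >= level)
  } else {
    which(y[idx] > level & y[idx + 1] <= level)
  }
  if (!length(hit)) {
    # boundary case: already at/over the level at the window start
    if (rising && y[from] >= level) return(t[from])
    return(NA_real_)
  }
  i <- idx[hit[1]]
  frac <- (level - y[i]) / (y[i + 1] - y[i])
  t[i] + frac * (t[i + 1] - t[i])
}

# durations of one transient at the given repolarization/decay percents:
# time from the upstroke crossing of the p% level to the downstroke
# crossing, with the level at peak - (p/100) * (peak - rest)
.durations <- function(t, y, percents) {
  ipk <- which.max(y)
  rest <- min(y)
  peak <- y[ipk]
  out <- stats::setNames(rep(NA_real_, length(percents)), percents)
  if (peak <= rest) return(out)
  for (k in seq_along(percents)) {
    lev <- peak - percents[k] / 100 * (peak - rest)
    t_up <- .crossing(t, y, lev, 1L, ipk, rising = TRUE)
    t_dn <- .crossing(t, y, lev, ipk, length(y), rising = FALSE)
    out[k] <- t_dn - t_up
  }
  out
}

#' Extract AP and Ca2+ transient biomarkers from one beat
#'
#' Computes action-potential durations (APD30/50/80), Ca2+ transient
#' durations (CaD20..CaD80), maximum upstroke velocities, Ca2+ amplitude
#' and baseline, and the area measure Int30 (integral of `v - v_rest`
#' where `v` exceeds the 30%-repolarization level). Durations are measured
#' between linearly interpolated level crossings, with levels defined
#' relative to the trace's own peak and rest values, so they are invariant
#' to time shifts and positive rescaling of the signal. If the trace
#' carries recorded current/flux columns, their peak magnitudes are
#' included as `I_<x>_max` / `J_<x>_max` entries.
#'
#' @param trace data frame with columns `t`, `v`, `ca` covering one beat
#'   (upstroke to return near baseline).
#' @return named numeric vector of class `"biomarker_set"` with attribute
#'   `valid` (FALSE when no upstroke is detected or the AP does not return
#'   through the 80% level, which drives the penalty cost).
#' @export
extract_biomarkers <- function(trace) {
  stopifnot(all(c("t", "v", "ca") %in% names(trace)))
  t <- trace$t; v <- trace$v; ca <- trace$ca
  apd <- .durations(t, v, .apd_percents)
  cad <- .durations(t, ca, .cad_percents)

  dvdt <- max(diff(v) / diff(t))
  dcdt <- max(diff(ca) / diff(t))
  ca_base <- min(ca)
  ca_amp <- max(ca) - ca_base

  vrest <- min(v)
  vpeak <- max(v)
  lev30 <- vpeak - 0.30 * (vpeak - vrest)
  above <- v > lev30
  int30 <- if (any(above)) {
    y <- pmax(v - vrest, 0) * above
    sum((y[-1] + y[-length(y)]) / 2 * diff(t))
  } else 0

  bm <- c(stats::setNames(apd, paste0("APD", .apd_percents)),
          stats::setNames(cad, paste0("CaD", .cad_percents)),
          Int30 = int30, dvdt_max = dvdt, dcdt_max = dcdt,
          Ca_amp = ca_amp, Ca_base = ca_base)

  extra <- setdiff(names(trace), c("t", "v", "ca"))
  extra <- grep("^[IJ]_", extra, value = TRUE)
  for (cn in extra) {
    bm[paste0(cn, "_max")] <- max(abs(trace[[cn]]))
  }

  valid <- is.finite(dvdt) && dvdt > 0 && vpeak > vrest &&
    all(is.finite(apd))
  structure(bm, class = "biomarker_set", valid = valid)
}

#' Is a biomarker set valid?
#' @param bm a biomarker set.
#' @return logical.
#' @export
biomarkers_valid <- function(bm) isTRUE(attr(bm, "valid"))

#' Cost specification
#'
#' Selects the cost-function terms and their weights, optionally per dose,
#' and the penalty value substituted for every term when a simulation
#' fails or yields invalid biomarkers.
#'
#' @param weights named numeric vector of per-term weights (term names as
#'   in [extract_biomarkers()]); terms absent or weighted 0 are disabled.
#' @param dose_weights optional numeric multiplier per dose (recycled).
#' @param penalty value each term takes on failure; must dominate any
#'   realistic relative difference.
#' @return list of class `"cost_spec"`.
#' @export
cost_spec <- function(weights, dose_weights = NULL, penalty = 10) {
  if (is.null(names(weights)) || any(!is.finite(weights)) ||
      any(weights < 0)) {
    stop("weights must be a named, finite, non-negative vector")
  }
  weights <- weights[weights > 0]
  if (!length(weights)) stop("at least one term must be enabled")
  structure(list(weights = weights, dose_weights = dose_weights,
                 penalty = penalty), class = "cost_spec")
}

#' Default cost specification for voltage/Ca2+ trace data
#'
#' APD80 and CaD80 carry weight 5, the intermediate Ca2+ durations
#' (CaD20..CaD70) weight 0.5, and the remaining waveform terms weight 1.
#'
#' @param include_currents if `TRUE`, peak-current magnitude terms for the
#'   major currents are enabled with weight 0.5.
#' @return a [cost_spec()].
#' @export
default_cost_spec <- function(include_currents = FALSE) {
  w <- c(APD30 = 1, APD50 = 1, APD80 = 5,
         stats::setNames(rep(0.5, 6), paste0("CaD", seq(20, 70, 10))),
         CaD80 = 5, Int30 = 1, dvdt_max = 1, dcdt_max = 1,
         Ca_amp = 1, Ca_base = 1)
  if (include_currents) {
    w <- c(w, stats::setNames(rep(0.5, 7),
      paste0("I_", c("Na", "CaL", "to", "Kr", "Ks", "K1", "NaCa"), "_max")))
  }
  cost_spec(w)
}

#' Relative-difference cost term
#'
#' `|R_model - R_target| / |R_target|`. A zero or non-finite target makes
#' the term undefined; it is skipped (returned as `NA`).
#'
#' @param r_model model characteristic value(s).
#' @param r_target target characteristic value(s), elementwise.
#' @return numeric relative absolute difference(s); `NA` where skipped.
#' @export
cost_term <- function(r_model, r_target) {
  out <- abs(r_model - r_target) / abs(r_target)
  out[!is.finite(r_target) | r_target == 0 | !is.finite(r_model)] <- NA_real_
  out
}

#' Blend continuation targets
#'
#' Elementwise convex combination `(1 - theta) * R0 + theta * R1` between
#' the default-model characteristics `R0` and the data characteristics
#' `R1`, used as the moving target of the continuation method.
#'
#' @param r0 characteristics of the default model (theta = 0 end).
#' @param r1 characteristics of the data (theta = 1 end).
#' @param theta blend parameter in \[0, 1\].
#' @return blended characteristics.
#' @export
continuation_targets <- function(r0, r1, theta) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1) {
    stop("theta must be a single value in [0, 1]")
  }
  (1 - theta) * unclass(r0) + theta * unclass(r1)
}

# weighted squared accumulation of one dose's terms
.dose_cost <- function(bm_model, target, spec, dw) {
  w <- spec$weights
  w <- w[names(w) %in% names(target)]
  if (is.null(bm_model) || !biomarkers_valid(bm_model)) {
    return(sum(dw * w * spec$penalty^2))
  }
  h <- cost_term(unclass(bm_model)[names(w)], target[names(w)])
  h[is.na(h)] <- 0   # skipped terms (zero/undefined targets)
  sum(dw * w * h^2)
}

#' Multi-dose cost function and its continuation form
#'
#' Evaluates the weighted sum of squared relative biomarker differences
#' between the model parameterized by `(lambda, eps)` and a dose
#' escalation dataset, summed over the control and every dose. With
#' `theta < 1` the targets are the continuation blend between the default
#' model's characteristics and the data's, so that at `theta = 0` the
#' optimum is exactly `lambda = eps = 0`; at `theta = 1` the plain cost is
#' recovered.
#'
#' @param lambda named adjustment-factor values for the free lambdas
#'   (e.g. `c(lambda_CaL = 0.1)`); missing factors are 0.
#' @param eps named potency values for targeted currents
#'   (e.g. `c(CaL = 0.01)`); missing entries are 0.
#' @param dataset a dose escalation dataset
#'   (see [generate_dose_escalation()]).
#' @param spec a [cost_spec()].
#' @param theta continuation blend in \[0, 1\]; 1 gives the plain cost.
#' @param base base model the adjustments act on; defaults to the
#'   dataset's preset.
#' @param problem optional precomputed [cost_problem()] (target biomarkers
#'   and default-model characteristics); computed on the fly otherwise.
#' @return total cost (non-negative scalar).
#' @export
total_cost <- function(lambda, eps, dataset, spec = default_cost_spec(),
                       theta = 1, base = NULL, problem = NULL) {
  if (is.null(problem)) problem <- cost_problem(dataset, spec, base)
  lam_full <- stats::setNames(numeric(length(.lambda_names)), .lambda_names)
  if (length(lambda)) {
    nm <- names(lambda)
    bad <- setdiff(nm, .lambda_names)
    if (length(bad)) stop("unknown lambda name(s): ",
                          paste(bad, collapse = ", "))
    lam_full[nm] <- as.numeric(lambda)
  }
  eps_full <- c(CaL = 0, NaL = 0, Kr = 0)
  if (length(eps)) eps_full[names(eps)] <- as.numeric(eps)

  adj <- apply_adjustments(problem$base, structure(lam_full,
                                            class = "adjustment_factors"))
  drug <- drug_effect(eps_CaL = eps_full[["CaL"]],
                      eps_NaL = eps_full[["NaL"]],
                      eps_Kr = eps_full[["Kr"]],
                      doses = setdiff(problem$doses, 0),
                      units = dataset$units)
  total <- 0
  for (d in seq_along(problem$doses)) {
    dw <- if (is.null(spec$dose_weights)) 1 else
      spec$dose_weights[(d - 1) %% length(spec$dose_weights) + 1]
    target <- continuation_targets(problem$R0, problem$R1[[d]], theta)
    pd <- apply_drug(adj, drug, problem$doses[d])
    key <- paste(format(unclass(pd), digits = 15), collapse = ",")
    bm <- if (!is.null(problem$cache)) problem$cache[[key]]
    if (is.null(bm)) {
      bm <- tryCatch({
        sim <- integrate_model(pd, problem$protocol,
                               initial = problem$initial)
        extract_biomarkers(measurement_beat(sim))
      }, error = function(e) structure(NA_real_, valid = FALSE))
      if (!is.null(problem$cache)) problem$cache[[key]] <- bm
    }
    total <- total + .dose_cost(bm, target, spec, dw)
  }
  total
}

#' Precompute the fixed pieces of a cost evaluation
#'
#' Extracts the per-dose target biomarkers from the dataset and the
#' default-model characteristics `R0` (the theta = 0 continuation end),
#' so repeated cost evaluations during inversion only re-simulate the
#' candidate model.
#'
#' @param dataset dose escalation dataset.
#' @param spec a [cost_spec()].
#' @param base base model; defaults to the dataset's recorded preset.
#' @return list of class `"cost_problem"`.
#' @export
cost_problem <- function(dataset, spec = default_cost_spec(), base = NULL) {
  if (is.null(base)) base <- model_parameters(dataset$meta$preset)
  proto <- protocol(mode = "paced", hz = dataset$meta$hz,
                    beats = dataset$meta$beats)
  initial <- initial_state(dataset$meta$preset)
  R1 <- lapply(dataset$traces, function(tr) unclass(extract_biomarkers(tr)))
  sim0 <- integrate_model(base, proto, initial = initial)
  R0 <- unclass(extract_biomarkers(measurement_beat(sim0)))
  structure(list(base = base, doses = dataset$doses, protocol = proto,
                 initial = initial, R0 = R0, R1 = R1,
                 cache = new.env(parent = emptyenv())),
            class = "cost_problem")
}
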