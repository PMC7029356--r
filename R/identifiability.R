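# identifiability: SVD of the model's current matrix, singular-vector
# perturbation scans and the per-current identifiability index.

#' Build the current matrix of one measurement beat
#'
#' Simulates one paced beat and samples every membrane current (stimulus
#' excluded) on a regular grid, giving the matrix whose singular value
#' decomposition underpins the identifiability analysis. Column order
#' matches the lambda ordering used for conductance perturbations.
#'
#' @param params model parameters (or preset name).
#' @param dt sampling interval (ms).
#' @param hz pacing frequency.
#' @param beats conditioning beats; the last beat is sampled.
#' @return list of class `"current_matrix"` with the matrix `A`
#'   (`N_t x N_c`), `dt` and `currents` (column names).
#' @export
build_current_matrix <- function(params = "hipsc", dt = 1, hz = 1,
                                 beats = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (is.character(params)) params <- model_parameters(params)
  sim <- integrate_model(params,
                         protocol(mode = "paced", hz = hz, beats = beats,
                                  sample_dt = dt),
                         record_currents = TRUE)
  tr <- sim$trace[sim$final_beat, , drop = FALSE]
  cols <- paste0("I_", .lambda_currents)
  A <- as.matrix(tr[, cols, drop = FALSE])
  dimnames(A) <- list(NULL, cols)
  structure(list(A = A, dt = dt, currents = cols, params = params),
            class = "current_matrix")
}

#' Maximum perturbation cost along a direction in conductance space
#'
#' Scales the current densities by `(1 + omega * v)` for each `omega` in
#' the grid, simulates, and measures the AP change against the
#' unperturbed model with the duration-based cost (APD30/50/80 and Int30,
#' APD80 weighted 5). Failed simulations take the penalty value.
#'
#' @param params unperturbed model parameters.
#' @param v unit direction vector over the 13 current densities (ordered
#'   as in [build_current_matrix()]).
#' @param omega grid of perturbation magnitudes in \[0, 1\].
#' @param spec cost specification; default is the duration-based scan
#'   cost.
#' @param beats conditioning beats for each simulation.
#' @return list with `max_cost`, `costs` (per omega) and `omega`.
#' @export
perturbation_scan <- function(params, v, omega = seq(0, 1, by = 0.1),
                              spec = scan_cost_spec(), beats = 1) {
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6) stop("v must be a unit vector")
  proto <- protocol(mode = "paced", beats = beats)
  preset <- attr(params, "preset")
  initial <- initial_state(preset)
  ref <- unclass(extract_biomarkers(measurement_beat(
    integrate_model(params, proto, initial = initial))))
  w <- spec$weights
  costs <- vapply(omega, function(om) {
    lam <- stats::setNames(om * v, paste0("lambda_", .lambda_currents))
    if (any(1 + lam <= 0)) return(sum(w * spec$penalty^2))
    bm <- tryCatch({
      p <- apply_adjustments(params, do.call(adjustment_factors,
                                             as.list(lam)))
      extract_biomarkers(measurement_beat(
        integrate_model(p, proto, initial = initial)))
    }, error = function(e) NULL)
    if (is.null(bm) || !biomarkers_valid(bm)) {
      return(sum(w * spec$penalty^2))
    }
    h <- cost_term(unclass(bm)[names(w)], ref[names(w)])
    h[is.na(h)] <- 0
    sum(w * h^2)
  }, numeric(1))
  list(max_cost = max(costs), costs = costs, omega = omega)
}

#' Cost specification of the perturbation scan
#'
#' @return a [cost_spec()] with APD30, APD50, Int30 weight 1 and APD80
#'   weight 5.
#' @export
scan_cost_spec <- function() {
  cost_spec(c(APD30 = 1, APD50 = 1, APD80 = 5, Int30 = 1))
}

#' Basis of the unidentifiable conductance subspace
#'
#' Collects the right singular vectors whose maximum perturbation cost
#' over the omega grid stays below the threshold into an orthonormal
#' basis.
#'
#' @param V matrix of right singular vectors (columns).
#' @param max_costs per-vector maximum perturbation costs.
#' @param threshold cost threshold below which a direction is considered
#'   unidentifiable.
#' @return matrix whose columns span the unidentifiable space (possibly
#'   zero columns).
#' @export
unidentifiable_space <- function(V, max_costs, threshold = 0.05) {
  stopifnot(ncol(V) == length(max_costs))
  V[, max_costs < threshold, drop = FALSE]
}

#' Identifiability index of one current
#'
#' `k = ||e_j - P e_j||` where `P` projects onto the unidentifiable
#' space: 1 means fully identifiable, 0 means the current lies entirely
#' in the unidentifiable space.
#'
#' @param j current index or name (see [build_current_matrix()] order).
#' @param basis orthonormal basis of the unidentifiable space.
#' @return index in \[0, 1\].
#' @export
identifiability_index <- function(j, basis) {
  nc <- length(.lambda_currents)
  if (is.character(j)) j <- match(sub("^I_", "", j), .lambda_currents)
  if (is.na(j) || j < 1 || j > nc) stop("unknown current")
  e <- numeric(nc); e[j] <- 1
  if (ncol(basis) == 0) return(1)
  proj <- basis %*% (t(basis) %*% e)
  sqrt(sum((e - proj)^2))
}

#' Full identifiability analysis of a preset
#'
#' Builds the current matrix, computes its SVD, scans the AP perturbation
#' cost along every right singular vector, forms the unidentifiable
#' space and reports the identifiability index of each current.
#' Singular vectors are sign-normalized so their largest-magnitude
#' component is positive.
#'
#' @param preset preset name or `model_params`.
#' @param dt current-matrix sampling interval (ms).
#' @param omega perturbation magnitude grid.
#' @param threshold unidentifiability cost threshold.
#' @param beats conditioning beats per scan simulation.
#' @return list of class `"identifiability_result"`: singular values
#'   `sigma`, sign-normalized vectors `V`, per-vector `max_costs`, the
#'   unidentifiable `basis` and the per-current index `k`.
#' @export
identifiability_analysis <- function(preset = "hipsc", dt = 1,
                                     omega = seq(0, 1, by = 0.1),
                                     threshold = 0.05, beats = 1) {
  cm <- build_current_matrix(preset, dt = dt, beats = beats)
  sv <- svd(cm$A)
  V <- sv$v
  for (i in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, i])), i] < 0) V[, i] <- -V[, i]
  }
  rownames(V) <- cm$currents
  params <- cm$params
  scans <- lapply(seq_len(ncol(V)), function(i) {
    perturbation_scan(params, V[, i], omega = omega, beats = beats)
  })
  max_costs <- vapply(scans, `[[`, numeric(1), "max_cost")
  basis <- unidentifiable_space(V, max_costs, threshold)
  k <- vapply(seq_along(cm$currents), identifiability_index, numeric(1),
              basis = basis)
  structure(list(sigma = sv$d, V = V, max_costs = max_costs,
                 basis = basis, threshold = threshold,
                 k = stats::setNames(k, cm$currents),
                 current_matrix = cm),
            class = "identifiability_result")
}

#' @export
print.identifiability_result <- function(x, ...) {
  cat("<identifiability_result>\n")
  print(data.frame(sigma = signif(x$sigma, 4),
                   max_cost = signif(x$max_costs, 4)))
  cat("identifiability index k per current:\n")
  print(round(x$k, 3))
  invisible(x)
}
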