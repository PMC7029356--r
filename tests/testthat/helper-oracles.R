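# Shared helpers: independent literal-transcription oracles and small
# synthetic fixtures, kept deliberately separate from the package's own
# computation paths.

# literal transcription of the RyR flux model: open probability as a
# cubic Hill function of dyadic Ca2+, availability-limited release into
# the subsarcolemmal space, and the constitutive leak
oracle_ryr <- function(c_d, c_s, c_sl, r, a_ryr, gamma, kappa) {
  p <- c_d^3 / (c_d^3 + kappa^3)
  list(J_RyR = p * r * a_ryr * (c_s - c_sl),
       J_leak = gamma * a_ryr * (c_s - c_sl),
       p = p)
}

# literal transcription of the relative-difference cost term
oracle_cost_term <- function(r_model, r_target) {
  abs(r_model - r_target) / abs(r_target)
}

# closed-form triangle pulse: linear rise from v0 to vp over t_up, linear
# fall back to v0 over t_down; APDp has an exact expression
make_triangle <- function(v0 = -80, vp = 40, t_up = 2, t_down = 100,
                          dt = 0.05, pad = 20) {
  t <- seq(0, pad + t_up + t_down + pad, by = dt)
  v <- ifelse(t < pad, v0,
        ifelse(t < pad + t_up, v0 + (vp - v0) * (t - pad) / t_up,
          ifelse(t < pad + t_up + t_down,
                 vp - (vp - v0) * (t - pad - t_up) / t_down, v0)))
  data.frame(t = t, v = v, ca = (v - v0) / (vp - v0))
}

triangle_apd <- function(p, t_up = 2, t_down = 100) {
  # crossing of the level at fraction p/100 below the peak on both limbs
  f <- p / 100
  (t_up + t_down) * f
}

# a quick two-dose synthetic dataset for cost/inversion plumbing tests;
# short conditioning keeps it fast while remaining fully self-consistent
quick_dataset <- function(ic50 = c(CaL = 50), doses = c(10, 100),
                          lambda_bg = c(lambda_CaL = 0.1), beat = 2,
                          units = "nM") {
  spec <- simulated_drug_spec("test-drug", ic50, doses = doses,
                              units = units, lambda_bg = lambda_bg,
                              beat = beat)
  generate_dose_escalation(spec)
}

# independent bare-bones Nelder-Mead transcription (Nelder & Mead 1965
# with the standard 1/2/0.5/0.5 coefficients), used as a
# second-implementation oracle for local_minimize
oracle_nelder_mead <- function(f, start, maxit = 200) {
  n <- length(start)
  simplex <- rbind(start, t(sapply(seq_len(n), function(i) {
    x <- start
    x[i] <- if (x[i] != 0) x[i] * 1.1 else 0.1
    x
  })))
  vals <- apply(simplex, 1, f)
  for (it in seq_len(maxit)) {
    o <- order(vals)
    simplex <- simplex[o, , drop = FALSE]; vals <- vals[o]
    centroid <- colMeans(simplex[-(n + 1), , drop = FALSE])
    xr <- centroid + (centroid - simplex[n + 1, ])
    fr <- f(xr)
    if (fr < vals[1]) {
      xe <- centroid + 2 * (centroid - simplex[n + 1, ])
      fe <- f(xe)
      if (fe < fr) { simplex[n + 1, ] <- xe; vals[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; vals[n + 1] <- fr }
    } else if (fr < vals[n]) {
      simplex[n + 1, ] <- xr; vals[n + 1] <- fr
    } else {
      xc <- centroid + 0.5 * (simplex[n + 1, ] - centroid)
      fc <- f(xc)
      if (fc < vals[n + 1]) { simplex[n + 1, ] <- xc; vals[n + 1] <- fc }
      else {
        for (i in 2:(n + 1)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          vals[i] <- f(simplex[i, ])
        }
      }
    }
  }
  i <- which.min(vals)
  list(par = simplex[i, ], value = vals[i])
}
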