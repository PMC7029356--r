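# model_core: currents, right-hand side, RyR fluxes and the integrator.

test_that("closed channels carry no current and ohmic currents vanish at their reversal potential", {
  p <- model_parameters("adult")
  y <- model_state("adult", m = 0, d = 0, r_to = 0, xr1 = 0, xs = 0, xf = 0)
  cur <- compute_currents(y, p)$currents
  expect_identical(unname(cur[c("I_Na", "I_CaL", "I_to", "I_Kr", "I_Ks",
                                "I_f")]),
                   rep(0, 6))

  EK <- 26.712832 * log(p[["Ko"]] / p[["Ki"]])
  y2 <- model_state("adult", v = EK, r_to = 0.5, s_to = 0.5, xr1 = 0.5,
                    xr2 = 0.5)
  cur2 <- compute_currents(y2, p)$currents
  expect_equal(unname(cur2["I_to"]), 0, tolerance = 1e-12)
  expect_equal(unname(cur2["I_Kr"]), 0, tolerance = 1e-12)
  ECl <- p[["E_Cl"]]
  y3 <- model_state("adult", v = ECl)
  expect_equal(unname(compute_currents(y3, p)$currents["I_bCl"]), 0)
})

test_that("the current sum matches -dv/dt of an integrated beat (finite-difference oracle)", {
  p <- model_parameters("adult")
  sim <- integrate_model(p, protocol(mode = "paced", beats = 1,
                                     sample_dt = 0.1),
                         record_currents = TRUE)
  tr <- sim$trace
  # compare away from the stimulus edges where the square pulse switches
  i <- which(tr$t > 5 & tr$t < 995)
  dvdt_fd <- (tr$v[i + 1] - tr$v[i - 1]) / (tr$t[i + 1] - tr$t[i - 1])
  isum <- rowSums(tr[i, c("I_Na", "I_NaL", "I_CaL", "I_to", "I_Kr", "I_Ks",
                          "I_K1", "I_NaK", "I_NaCa", "I_pCa", "I_bCa",
                          "I_bCl", "I_f", "I_stim")])
  # integrator tolerance: finite differencing of a 0.1 ms sampled upstroke
  # dominates the error budget, so compare in a least-squares sense
  expect_lt(sqrt(mean((dvdt_fd + isum)^2)) / sqrt(mean(isum^2)), 0.05)
})

test_that("rhs honors flux bookkeeping: zero SR gradient means zero release", {
  p <- model_parameters("adult")
  y <- model_state("adult", c_s = 2e-4, c_sl = 2e-4)
  fl <- compute_currents(y, p)$fluxes
  expect_identical(unname(fl["J_RyR"]), 0)
  expect_identical(unname(fl["J_leak"]), 0)
  r <- ryr_fluxes(y, p)
  expect_identical(r$J_RyR, 0)
  expect_identical(r$J_leak, 0)
})

test_that("clamp mode forces dv/dt to zero", {
  p <- model_parameters("adult")
  y <- model_state("adult")
  d <- model_rhs(y, p, clamp = TRUE)
  expect_identical(unname(d["v"]), 0)
})

test_that("non-finite state is rejected with the offending variable named", {
  p <- model_parameters("adult")
  y <- initial_state("adult")
  y["c_sl"] <- NaN
  expect_error(compute_currents(structure(y, class = "model_state"), p),
               "c_sl")
})

test_that("whole-cell Ca2+ bookkeeping closes over a paced beat", {
  p <- model_parameters("adult")
  sim <- integrate_model(p, protocol(mode = "paced", beats = 1,
                                     sample_dt = 0.1),
                         record_currents = TRUE, keep_states = TRUE)
  tr <- sim$trace
  vols <- p[c("frac_d", "frac_sl", "frac_c", "frac_s", "frac_n")] *
    p[["V_cell"]]
  total <- vols[1] * (tr$c_d + tr$b_d) + vols[2] * (tr$c_sl + tr$b_sl) +
    vols[3] * (tr$c_c + tr$b_c) + vols[4] * (tr$c_s + tr$b_s) +
    vols[5] * tr$c_n
  d_total <- total[nrow(tr)] - total[1]
  net_in <- tr$J_CaL + tr$J_esl
  integral <- sum((net_in[-1] + net_in[-length(net_in)]) / 2 * diff(tr$t))
  expect_equal(d_total, integral, tolerance = 1e-3)
})

test_that("RyR availability stays in [0, 1] under randomized forcing", {
  set.seed(42)
  for (rep in 1:5) {
    lam <- stats::setNames(stats::runif(3, -0.5, 1),
                           c("lambda_CaL", "lambda_Kr", "lambda_RyR"))
    p <- apply_adjustments(model_parameters("hipsc"),
                           do.call(adjustment_factors, as.list(lam)))
    y0 <- initial_state("hipsc")
    y0["r"] <- stats::runif(1)
    sim <- integrate_model(p, protocol(mode = "paced", beats = 2),
                           initial = structure(y0, class = "model_state"),
                           keep_states = TRUE)
    expect_true(all(sim$trace$r >= 0 & sim$trace$r <= 1))
  }
})

test_that("integrating zero beats returns the initial state sampled once", {
  p <- model_parameters("adult")
  sim <- integrate_model(p, protocol(mode = "paced", beats = 0),
                         keep_states = TRUE)
  expect_equal(nrow(sim$trace), 1)
  expect_equal(sim$trace$v, unname(initial_state("adult")["v"]))
})

test_that("halving the integrator step changes APD80 of the final beat by under 0.5 ms", {
  p <- model_parameters("hipsc")
  apd80 <- function(dt) {
    sim <- integrate_model(p, protocol(mode = "paced", beats = 2), dt = dt)
    unname(unclass(extract_biomarkers(measurement_beat(sim)))["APD80"])
  }
  expect_lt(abs(apd80(0.02) - apd80(0.01)), 0.5)
})

test_that("solver failure raises a structured error carrying the last valid time", {
  p <- model_parameters("adult", g_f = 50, E_f = 2000)
  err <- tryCatch(
    integrate_model(p, protocol(mode = "paced", beats = 1)),
    cardioinverse_solver_error = function(e) e
  )
  expect_s3_class(err, "cardioinverse_solver_error")
  expect_true(is.finite(err$t_fail))
})
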