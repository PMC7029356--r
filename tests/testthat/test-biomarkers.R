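# biomarkers_cost: biomarker extraction, cost terms, continuation blend.

test_that("triangle-pulse durations match the closed-form crossing times", {
  tri <- make_triangle(t_up = 2, t_down = 100, dt = 0.05)
  bm <- unclass(extract_biomarkers(tri))
  for (p in c(30, 50, 80)) {
    expect_equal(unname(bm[paste0("APD", p)]), triangle_apd(p),
                 tolerance = 1e-6)
  }
  for (p in seq(20, 80, 10)) {
    expect_equal(unname(bm[paste0("CaD", p)]), triangle_apd(p),
                 tolerance = 1e-6)
  }
  # closed form for the triangle's Int30: over the window where v exceeds
  # the 30% level, v - v_rest is a trapezoid from 0.7*amp up to amp
  amp <- 120
  expect_equal(unname(bm["Int30"]),
               triangle_apd(30) * amp * (0.7 + 0.15), tolerance = 1e-3)
})

test_that("durations are invariant to time shift and positive rescaling", {
  tri <- make_triangle()
  bm0 <- unclass(extract_biomarkers(tri))
  shifted <- tri; shifted$t <- shifted$t + 137.5
  scaled <- tri; scaled$v <- 3 * scaled$v + 20; scaled$ca <- 0.01 * scaled$ca
  nm <- c(paste0("APD", c(30, 50, 80)), paste0("CaD", seq(20, 80, 10)))
  expect_equal(unclass(extract_biomarkers(shifted))[nm], bm0[nm],
               tolerance = 1e-9)
  expect_equal(unclass(extract_biomarkers(scaled))[nm], bm0[nm],
               tolerance = 1e-9)
})

test_that("repolarization levels nest on simulated beats", {
  for (preset in c("adult", "hipsc")) {
    sim <- integrate_model(model_parameters(preset),
                           protocol(mode = "paced", beats = 2))
    bm <- unclass(extract_biomarkers(measurement_beat(sim)))
    expect_lte(bm[["APD30"]], bm[["APD50"]])
    expect_lte(bm[["APD50"]], bm[["APD80"]])
    expect_true(all(diff(bm[paste0("CaD", seq(20, 80, 10))]) >= 0))
    expect_gte(bm[["Ca_amp"]], 0)
  }
})

test_that("a flat trace is flagged invalid", {
  flat <- data.frame(t = 0:100, v = rep(-80, 101), ca = rep(1e-4, 101))
  expect_false(biomarkers_valid(extract_biomarkers(flat)))
})

test_that("cost terms match the literal relative-difference transcription", {
  expect_identical(cost_term(5, 5), 0)
  expect_identical(cost_term(10, 5), 1)
  set.seed(7)
  r_m <- stats::rnorm(50, 100, 30)
  r_t <- stats::rnorm(50, 100, 30)
  expect_identical(cost_term(r_m, r_t), oracle_cost_term(r_m, r_t))
  expect_true(is.na(cost_term(1, 0)))
})

test_that("continuation targets blend convexly", {
  r0 <- c(APD80 = 200, Ca_amp = 1)
  r1 <- c(APD80 = 300, Ca_amp = 3)
  expect_identical(continuation_targets(r0, r1, 0), unclass(r0))
  expect_identical(continuation_targets(r0, r1, 1), unclass(r1))
  expect_equal(continuation_targets(r0, r1, 0.5),
               c(APD80 = 250, Ca_amp = 2))
  expect_error(continuation_targets(r0, r1, 1.2), "0, 1")
})

test_that("the cost is zero for self-consistent data and scales linearly in the weights", {
  ds <- quick_dataset(ic50 = c(CaL = 1e15), doses = c(1, 2),
                      lambda_bg = c(lambda_CaL = 0))
  H <- total_cost(c(), c(), ds)
  expect_lt(H, 1e-6)
  expect_identical(total_cost(c(), c(), ds, theta = 0), 0)

  ds2 <- quick_dataset()
  spec1 <- default_cost_spec()
  spec2 <- cost_spec(spec1$weights * 2, penalty = spec1$penalty)
  lam <- c(lambda_CaL = 0.05)
  eps <- c(CaL = 0.001)
  h1 <- total_cost(lam, eps, ds2, spec1)
  h2 <- total_cost(lam, eps, ds2, spec2)
  expect_gt(h1, 0)
  expect_equal(h2, 2 * h1, tolerance = 1e-12)
})

test_that("the continuation cost interpolates between the trivial and full problems", {
  ds <- quick_dataset()
  pr <- cost_problem(ds)
  h_theta0 <- total_cost(c(), c(), ds, theta = 0, problem = pr)
  h_full <- total_cost(c(), c(), ds, theta = 1, problem = pr)
  h_mid <- total_cost(c(), c(), ds, theta = 0.5, problem = pr)
  expect_identical(h_theta0, 0)
  expect_gt(h_full, 0)
  expect_true(h_mid > 0 && h_mid < h_full)
})

test_that("a brute-force recomputation of the cost agrees with total_cost", {
  ds <- quick_dataset()
  spec <- cost_spec(c(APD80 = 5, Ca_amp = 1, CaD80 = 2))
  lam <- c(lambda_CaL = 0.2, lambda_Kr = -0.1)
  eps <- c(CaL = 1 / 80)
  got <- total_cost(lam, eps, ds, spec)

  # independent path: explicit loop over doses with direct parameter
  # arithmetic and the oracle cost term
  base <- model_parameters("hipsc")
  expected <- 0
  for (i in seq_along(ds$doses)) {
    D <- ds$doses[i]
    p <- base
    p["g_CaL"] <- p["g_CaL"] * 1.2 / (1 + D / 80)
    p["g_Kr"] <- p["g_Kr"] * 0.9
    sim <- integrate_model(p, protocol(mode = "paced", beats = 2))
    bm <- unclass(extract_biomarkers(measurement_beat(sim)))
    tgt <- unclass(extract_biomarkers(ds$traces[[i]]))
    for (term in names(spec$weights)) {
      expected <- expected + spec$weights[[term]] *
        oracle_cost_term(bm[[term]], tgt[[term]])^2
    }
  }
  expect_equal(got, expected, tolerance = 1e-12)
})
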