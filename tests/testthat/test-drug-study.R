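# drug_study: shipped specs, synthetic generation, clamp experiment,
# optical preprocessing and the adult prediction step.

test_that("the shipped drug specifications carry the published targets", {
  specs <- shipped_drug_specs()
  expect_equal(specs$nifedipine$ic50, c(CaL = 10))
  expect_equal(specs$nifedipine$doses, c(3, 30, 300, 3000))
  expect_equal(specs$nifedipine$units, "nM")
  expect_equal(specs$lidocaine$ic50, c(NaL = 10))
  expect_equal(specs$lidocaine$units, "uM")
  expect_equal(specs$cisapride$ic50, c(Kr = 10))
  expect_equal(specs$flecainide$ic50, c(CaL = 25, NaL = 20, Kr = 10))
  expect_equal(specs$verapamil$ic50, c(CaL = 200, Kr = 500))
  expect_false("NaL" %in% names(specs$verapamil$ic50))
  for (s in specs) {
    expect_equal(unname(s$lambda_bg),
                 rep(0.1, 3))
    expect_true(all(diff(s$doses) > 0))
  }
})

test_that("a no-target drug produces doses identical to control", {
  ds <- quick_dataset(ic50 = c(CaL = 1e15), doses = c(10, 100),
                      lambda_bg = c(lambda_CaL = 0.1))
  for (i in 2:3) {
    expect_equal(ds$traces[[i]]$v, ds$traces[[1]]$v, tolerance = 1e-9)
    expect_equal(ds$traces[[i]]$ca, ds$traces[[1]]$ca, tolerance = 1e-9)
  }
})

test_that("a CaL blocker at D = IC50 is definitionally a halved conductance", {
  spec <- simulated_drug_spec("half", c(CaL = 40), doses = 40, beat = 2)
  ds <- generate_dose_escalation(spec)
  base <- model_parameters("hipsc")
  lam <- do.call(adjustment_factors, as.list(spec$lambda_bg))
  p <- apply_adjustments(base, lam)
  p["g_CaL"] <- p["g_CaL"] / 2
  direct <- measurement_beat(
    integrate_model(p, protocol(mode = "paced", beats = 2)))
  expect_identical(ds$traces[[2]]$v, direct$v)
  expect_identical(ds$traces[[2]]$ca, direct$ca)
})

test_that("a pure Kr blocker prolongs the AP monotonically across its ladder", {
  ds <- generate_dose_escalation(shipped_drug_specs()$cisapride)
  apd <- vapply(ds$traces, function(tr) {
    unclass(extract_biomarkers(tr))[["APD80"]]
  }, numeric(1))
  expect_true(all(diff(apd) > 0))
})

test_that("generation is deterministic and the JSON round trip is exact", {
  spec <- simulated_drug_spec("det", c(Kr = 100), doses = c(20, 60),
                              beat = 2)
  a <- generate_dose_escalation(spec)
  b <- generate_dose_escalation(spec)
  expect_identical(a$traces, b$traces)

  path <- tempfile(fileext = ".json")
  write_dataset(a, path)
  back <- read_dataset(path)
  expect_identical(back$doses, a$doses)
  for (i in seq_along(a$traces)) {
    expect_identical(back$traces[[i]]$v, a$traces[[i]]$v)
    expect_identical(back$traces[[i]]$ca, a$traces[[i]]$ca)
  }
  unlink(path)
})

test_that("the clamp experiment shows graded release and quiescence at rest", {
  for (preset in c("adult", "hipsc")) {
    tab <- graded_release_experiment(preset)
    # clamping at the resting potential itself leaves both fluxes tiny
    rest_v <- initial_state(preset)[["v"]]
    sim <- integrate_model(model_parameters(preset),
                           protocol(mode = "clamp", clamp_v = rest_v,
                                    duration = 100, sample_dt = 0.5),
                           record_currents = TRUE)
    expect_lt(max(sim$trace$J_CaL), 0.01 * max(tab$peak_J_CaL))
    expect_lt(max(sim$trace$J_RyR), 0.01 * max(tab$peak_J_RyR))
    # high gain at 0 mV
    i0 <- which(tab$v_clamp == 0)
    expect_gt(tab$int_J_RyR[i0], tab$int_J_CaL[i0])
    # graded: release peak tracks trigger peak on the ascending limb
    asc <- seq_len(which.max(tab$peak_J_CaL))
    expect_gt(stats::cor(tab$peak_J_CaL[asc], tab$peak_J_RyR[asc],
                         method = "spearman"), 0.8)
  }
})

test_that("optical preprocessing filters, aligns and averages beats", {
  set.seed(8)
  n <- 120
  t <- (0:(n - 1)) * 5
  wave <- function(shift) {
    v <- -80 + 100 * exp(-((seq_len(n) - 30 - shift) / 12)^2)
    ca <- 0.1 + exp(-((seq_len(n) - 35 - shift) / 18)^2)
    data.frame(t = t, v = v, ca = ca)
  }
  # identical beats pass through unchanged (up to the median filter)
  same <- preprocess_optical(list(wave(0), wave(0)), frame_rate = 200)
  med3 <- function(y) as.numeric(stats::runmed(y, 3, endrule = "keep"))
  expect_equal(same$v, med3(wave(0)$v)[seq_len(nrow(same))],
               tolerance = 1e-12)

  # known integer shifts are removed exactly
  shifted <- preprocess_optical(list(wave(0), wave(7), wave(-4)),
                                frame_rate = 200)
  aligned_ref <- wave(0)
  i0 <- which.max(diff(med3(aligned_ref$v)))
  j0 <- which.max(diff(shifted$v))
  expect_equal(shifted$v[j0 + (-3:3)],
               med3(aligned_ref$v)[i0 + (-3:3)], tolerance = 1e-9)

  # a single-sample spike is bounded by its neighbors after filtering
  spiky <- wave(0)
  spiky$v[50] <- 500
  out <- preprocess_optical(list(spiky, wave(0)), frame_rate = 200)
  expect_lt(max(out$v), 100)

  expect_error(preprocess_optical(list(wave(0))), "two beats")
})

test_that("adult predictions equal direct conductance scaling and respond to Kr block", {
  eps <- c(Kr = 1 / 100)
  doses <- c(0, 50, 150)
  pred <- predict_adult_response(eps, doses, beats = 2)
  # epsilon = 0 gives the control trace
  eps0 <- predict_adult_response(c(Kr = 0), c(0, 50), beats = 2)
  expect_identical(eps0$traces[[1]]$v, eps0$traces[[2]]$v)
  # definitional equivalence
  p <- model_parameters("adult")
  p["g_Kr"] <- p["g_Kr"] / (1 + 150 / 100)
  direct <- measurement_beat(
    integrate_model(p, protocol(mode = "paced", beats = 2)))
  expect_identical(pred$traces[[3]]$v, direct$v)
  # monotone APD prolongation with dose
  apd <- vapply(pred$traces, function(tr) {
    unclass(extract_biomarkers(tr))[["APD80"]]
  }, numeric(1))
  expect_true(all(diff(apd) > 0))
})
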