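# inversion: start sampling, budget-limited simplex, continuation plumbing.

test_that("degenerate sampling ranges collapse onto the incumbent and seeds reproduce", {
  cfg0 <- inversion_config(M = 1, starts = 5, lambda_halfwidth = 0,
                           eps_range = 1, seed = 1)
  lam <- c(lambda_CaL = 0.1, lambda_Kr = -0.2)
  eps <- c(CaL = 0.05, Kr = 0.001)
  set.seed(1)
  st <- sample_starts(lam, eps, cfg0)
  for (s in st) {
    expect_equal(s$lambda, lam)
    expect_equal(s$eps, eps, tolerance = 1e-12)
  }

  cfg <- inversion_config(M = 1, starts = 20, seed = 99)
  set.seed(99); a <- sample_starts(lam, eps, cfg)
  set.seed(99); b <- sample_starts(lam, eps, cfg)
  expect_identical(a, b)
})

test_that("start distributions respect the stated ranges", {
  cfg <- inversion_config(M = 1, starts = 10000, lambda_halfwidth = 0.2,
                          eps_range = 5)
  cfg$eps_floor <- 1e-4
  lam <- c(lambda_CaL = 0.3)
  eps <- c(Kr = 0.01)
  set.seed(5)
  st <- sample_starts(lam, eps, cfg)
  ls <- vapply(st, function(s) s$lambda[[1]], numeric(1))
  es <- vapply(st, function(s) s$eps[[1]], numeric(1))
  expect_gte(min(ls), 0.1); expect_lte(max(ls), 0.5)
  expect_gte(min(es), 0.01 / 5); expect_lte(max(es), 0.01 * 5)
  # the empirical extremes approach the stated bounds
  expect_lt(min(ls), 0.105); expect_gt(max(ls), 0.495)
  expect_lt(min(es), 0.0021); expect_gt(max(es), 0.048)
  # a floored incumbent explores the whole configured block range
  cfg$eps_ceiling <- 1
  set.seed(6)
  st0 <- sample_starts(lam, c(Kr = 0), cfg)
  es0 <- vapply(st0, function(s) s$eps[[1]], numeric(1))
  expect_gte(min(es0), 1e-4); expect_lte(max(es0), 1)
  expect_gt(max(es0) / min(es0), 100)
})

test_that("lambda starts are clipped at the search bound", {
  cfg <- inversion_config(M = 1, starts = 2000, lambda_halfwidth = 0.2)
  set.seed(2)
  st <- sample_starts(c(lambda_CaL = -0.9), c(CaL = 0.1), cfg)
  ls <- vapply(st, function(s) s$lambda[[1]], numeric(1))
  expect_gte(min(ls), -0.95)
  expect_true(any(ls == -0.95))
})

test_that("budget-limited simplex descends, never worsens, and honors a zero budget", {
  f <- function(x) sum((x - c(2, -1))^2)
  start <- c(0, 0)
  res0 <- local_minimize(f, start, 0)
  expect_identical(res0$par, start)
  res <- local_minimize(f, start, 500)
  expect_lt(sum((res$par - c(2, -1))^2), 1e-3)
  expect_lte(res$value, f(start))
  res5 <- local_minimize(f, start, 5)
  expect_lte(res5$value, f(start))
})

test_that("the simplex endpoint agrees with an independent transcription on a random quadratic", {
  set.seed(21)
  A <- crossprod(matrix(stats::rnorm(9), 3, 3)) + diag(3)
  b <- stats::rnorm(3)
  f <- function(x) as.numeric(t(x - b) %*% A %*% (x - b))
  start <- c(1, 1, 1)
  mine <- local_minimize(f, start, 400)
  oracle <- oracle_nelder_mead(f, start, 400)
  expect_equal(mine$par, oracle$par, tolerance = 1e-2)
  expect_lt(mine$value, 1e-5)
  expect_lt(oracle$value, 1e-5)
})

test_that("a one-parameter two-current relaxation toy recovers the grid-search optimum", {
  # two ohmic currents with constant open probabilities: the membrane
  # relaxes exponentially; a drug scales the second conductance by
  # 1/(1 + D*eps)
  sim_toy <- function(eps, D) {
    g1 <- 0.08; g2 <- 0.12; E1 <- -80; E2 <- 20
    g2d <- g2 / (1 + D * eps)
    tt <- seq(0, 200, 1)
    gsum <- g1 + g2d
    vinf <- (g1 * E1 + g2d * E2) / gsum
    v0 <- 0
    vinf + (v0 - vinf) * exp(-gsum * tt)
  }
  eps_true <- 0.02
  doses <- c(0, 25, 100)
  data <- lapply(doses, function(D) sim_toy(eps_true, D))
  cost <- function(eps) {
    sum(vapply(seq_along(doses), function(i) {
      mean((sim_toy(eps, doses[i]) - data[[i]])^2)
    }, numeric(1)))
  }
  grid <- exp(seq(log(1e-4), log(1), length.out = 2000))
  eps_grid <- grid[which.min(vapply(grid, cost, numeric(1)))]
  fit <- local_minimize(function(x) cost(exp(x)), log(0.001), 300)
  expect_equal(exp(fit$par), eps_grid, tolerance = 0.01)
  expect_equal(exp(fit$par), eps_true, tolerance = 0.01)
})

test_that("the continuation path is monotone in theta, complete and seed-reproducible", {
  ds <- quick_dataset(ic50 = c(CaL = 50), doses = c(20, 80),
                      lambda_bg = c(lambda_CaL = 0.05), beat = 2)
  cfg <- inversion_config(free_lambda = "CaL", free_eps = "CaL",
                          M = 3, starts = 2, iters_early = 3,
                          iters_late = 6, late_from = 3, seed = 4)
  res <- invert(ds, cfg)
  expect_equal(nrow(res$path), cfg$M + 1)
  expect_equal(res$path$theta, seq(0, 1, length.out = cfg$M + 1))
  expect_identical(res$path$theta[nrow(res$path)], 1)
  expect_true(all(is.finite(res$path$H)))
  res2 <- invert(ds, cfg)
  expect_identical(res$path, res2$path)
  expect_identical(res$eps, res2$eps)
})
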