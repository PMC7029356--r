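# inversion: continuation-based multi-start Nelder-Mead minimization,
# jointly fitting control adjustment factors and drug potencies over all
# doses of a dose escalation series.

#' Inversion configuration
#'
#' @param free_lambda currents whose density factors are free (names
#'   without the `lambda_` prefix, e.g. `c("CaL", "NaL", "Kr")`). The
#'   weakly identifiable densities (Na, bCa, Ks, bCl) are fixed by
#'   default, following the identifiability analysis.
#' @param free_eps currents whose drug potencies are free.
#' @param M number of continuation steps (theta goes 0 -> 1 in M steps).
#' @param starts random start vectors per continuation step (the incumbent
#'   is always evaluated in addition).
#' @param iters_early,iters_late Nelder-Mead iterations per start during
#'   the early/late continuation steps.
#' @param late_from step index from which the late iteration budget is
#'   used.
#' @param lambda_halfwidth half-width of the uniform sampling interval for
#'   lambda starts around the incumbent.
#' @param eps_range multiplicative range of the log-uniform sampling
#'   interval for epsilon starts (`[eps/range, eps*range]`).
#' @param eps_floor lower floor used for epsilon starts when the incumbent
#'   is 0; defaults to `0.01 / max(dose)` (a just-detectable block at the
#'   top dose).
#' @param eps_ceiling upper end of the exploration range used for an
#'   epsilon whose incumbent is still at the floor; defaults to
#'   `10 / min(dose)` (a strong block already at the lowest dose).
#' @param lambda_bounds search box for each lambda component (clipping).
#' @param seed RNG seed making the inversion reproducible.
#' @param restarts additional full continuation attempts (with seeds
#'   `seed + 1`, `seed + 2`, ...) made while the final cost stays above
#'   `restart_H`; the best attempt is returned. The whole procedure
#'   remains a deterministic function of `seed`.
#' @param restart_H final-cost threshold below which an attempt is
#'   accepted without further restarts.
#' @param workers reserved for concurrent start evaluation (1 = serial;
#'   results are defined to be identical for any value).
#' @return list of class `"inversion_config"`.
#' @export
inversion_config <- function(free_lambda = c("CaL", "NaL", "Kr"),
                             free_eps = c("CaL", "NaL", "Kr"),
                             M = 20, starts = 63,
                             iters_early = 5, iters_late = 25,
                             late_from = 16,
                             lambda_halfwidth = 0.2, eps_range = 5,
                             eps_floor = NULL, eps_ceiling = NULL,
                             lambda_bounds = c(-0.95, 20),
                             seed = 1, restarts = 0, restart_H = 0.05,
                             workers = 1) {
  stopifnot(M >= 1, starts >= 1, lambda_halfwidth >= 0, eps_range >= 1)
  bad <- setdiff(free_lambda, .lambda_currents)
  if (length(bad)) stop("unknown free lambda(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(free_eps, c("CaL", "NaL", "Kr"))
  if (length(bad)) stop("unknown free epsilon(s): ", paste(bad, collapse = ", "))
  if (!length(free_lambda) && !length(free_eps)) {
    stop("at least one free parameter is required")
  }
  structure(list(free_lambda = free_lambda, free_eps = free_eps, M = M,
                 starts = starts, iters_early = iters_early,
                 iters_late = iters_late, late_from = late_from,
                 lambda_halfwidth = lambda_halfwidth, eps_range = eps_range,
                 eps_floor = eps_floor, eps_ceiling = eps_ceiling,
                 lambda_bounds = lambda_bounds,
                 seed = seed, restarts = restarts, restart_H = restart_H,
                 workers = workers),
            class = "inversion_config")
}

#' Draw random start vectors around an incumbent
#'
#' Lambda components are uniform in `incumbent +/- halfwidth`, clipped to
#' the search box; epsilon components are log-uniform in
#' `[eps/range, eps*range]`. An epsilon whose incumbent sits at (or
#' below) the floor carries no scale information yet, so its start is
#' drawn log-uniformly over the whole plausible block range
#' `[eps_floor, eps_ceiling]` instead of around the floor. Draws come
#' from R's RNG, so a fixed seed gives identical start sets.
#'
#' @param lambda named incumbent lambda values (free components).
#' @param eps named incumbent epsilon values (free components).
#' @param config an [inversion_config()].
#' @return list of `starts` elements, each `list(lambda, eps)`.
#' @export
sample_starts <- function(lambda, eps, config) {
  floor_eps <- config$eps_floor
  if (is.null(floor_eps)) floor_eps <- 1e-6
  ceil_eps <- config$eps_ceiling
  if (is.null(ceil_eps)) ceil_eps <- floor_eps * 1e6
  lapply(seq_len(config$starts), function(i) {
    lam <- vapply(lambda, function(x) {
      v <- stats::runif(1, x - config$lambda_halfwidth,
                        x + config$lambda_halfwidth)
      min(max(v, config$lambda_bounds[1]), config$lambda_bounds[2])
    }, numeric(1))
    ep <- vapply(eps, function(x) {
      if (x <= floor_eps) {
        # uninformed potency: explore the whole plausible block range
        exp(stats::runif(1, log(floor_eps), log(ceil_eps)))
      } else {
        exp(stats::runif(1, log(x / config$eps_range),
                         log(x * config$eps_range)))
      }
    }, numeric(1))
    list(lambda = lam, eps = ep)
  })
}

#' Budget-limited Nelder-Mead descent
#'
#' Runs the simplex algorithm for at most `iterations` iterations from
#' `start` and returns the best point found; the returned value never
#' exceeds the start value. A zero budget returns the start unchanged.
#'
#' @param f objective; must be finite at `start` (penalty-valued on
#'   simulation failure).
#' @param start numeric start vector.
#' @param iterations iteration budget.
#' @return list with `par` and `value`.
#' @export
local_minimize <- function(f, start, iterations) {
  f0 <- f(start)
  if (iterations <= 0) return(list(par = start, value = f0))
  res <- if (length(start) == 1) {
    # simplex needs >= 2 points; use golden-section search on a bracket
    # wide enough to cover the continuation step ranges
    o <- stats::optimize(f, lower = start - 4, upper = start + 4)
    list(par = o$minimum, value = o$objective)
  } else {
    o <- suppressWarnings(stats::optim(start, f, method = "Nelder-Mead",
                                       control = list(maxit = iterations)))
    list(par = o$par, value = o$value)
  }
  if (res$value <= f0) res else list(par = start, value = f0)
}

# pack/unpack the optimization vector: free lambdas linear, free epsilons
# in log space (scale-free treatment, matching the multiplicative start
# range)
.pack <- function(lambda, eps) c(lambda, log(eps))
.unpack <- function(x, config) {
  nl <- length(config$free_lambda)
  lam <- x[seq_len(nl)]
  names(lam) <- paste0("lambda_", config$free_lambda, recycle0 = TRUE)
  ep <- exp(x[nl + seq_along(config$free_eps)])
  names(ep) <- config$free_eps
  list(lambda = lam, eps = ep)
}

#' Continuation-based joint inversion of a dose escalation dataset
#'
#' Steps the continuation parameter theta from 0 to 1 in `M` steps. At
#' each step the blended-target cost is minimized with budget-limited
#' Nelder-Mead descents from the incumbent and from `starts` random
#' vectors around it; the best point becomes the incumbent. The result
#' carries the full continuation path and is deterministic for a fixed
#' seed.
#'
#' @param dataset a dose escalation dataset with a control and at least
#'   one dose.
#' @param config an [inversion_config()].
#' @param spec a [cost_spec()].
#' @param base base model the adjustments act on; defaults to the
#'   dataset's preset.
#' @param verbose print per-step progress to stderr.
#' @return list of class `"inversion_result"`: fitted `lambda`, `eps`,
#'   `ic50` (in dataset units), the continuation `path`, `doses`, `units`,
#'   `seed` and the config echo.
#' @export
invert <- function(dataset, config = inversion_config(),
                   spec = default_cost_spec(), base = NULL,
                   verbose = FALSE) {
  if (!inherits(dataset, "dose_escalation_dataset")) {
    stop("dataset must be a dose_escalation_dataset")
  }
  if (length(dataset$doses) < 2) stop("dataset needs control plus >= 1 dose")
  problem <- cost_problem(dataset, spec, base)
  restarts <- config$restarts %||% 0
  best <- NULL
  for (k in 0:restarts) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    res <- .invert_once(dataset, cfg_k, spec, problem, verbose)
    if (is.null(best) || res$final_cost < best$final_cost) best <- res
    if (best$final_cost <= (config$restart_H %||% 0.05)) break
    if (verbose && k < restarts) {
      message(sprintf("final cost %.4g above threshold; restarting (%d/%d)",
                      res$final_cost, k + 1, restarts))
    }
  }
  best$seed <- config$seed
  best
}

.invert_once <- function(dataset, config, spec, problem, verbose) {
  dmax <- max(dataset$doses)
  cfg <- config
  if (is.null(cfg$eps_floor)) cfg$eps_floor <- 0.01 / dmax
  if (is.null(cfg$eps_ceiling)) {
    dmin <- min(dataset$doses[dataset$doses > 0])
    cfg$eps_ceiling <- 10 / dmin
  }

  set.seed(cfg$seed)
  lam_inc <- stats::setNames(numeric(length(cfg$free_lambda)),
                             paste0("lambda_", cfg$free_lambda,
                                    recycle0 = TRUE))
  eps_inc <- stats::setNames(rep(0, length(cfg$free_eps)), cfg$free_eps)

  objective <- function(theta) {
    function(x) {
      pe <- .unpack(x, cfg)
      lam <- pmin(pmax(pe$lambda, cfg$lambda_bounds[1]), cfg$lambda_bounds[2])
      total_cost(lam, pe$eps, dataset, spec, theta = theta,
                 problem = problem)
    }
  }

  path <- list()
  path[[1]] <- c(theta = 0, H = 0, lam_inc, .eps_path(eps_inc))
  failed_steps <- 0
  for (m in seq_len(cfg$M)) {
    theta <- m / cfg$M
    f <- objective(theta)
    iters <- if (m >= cfg$late_from) cfg$iters_late else cfg$iters_early
    starts <- sample_starts(lam_inc, eps_inc, cfg)
    eps_inc0 <- ifelse(eps_inc <= 0, cfg$eps_floor, eps_inc)
    cand <- c(list(list(lambda = lam_inc, eps = eps_inc0)), starts)
    best <- NULL
    for (s in cand) {
      res <- tryCatch(local_minimize(f, .pack(s$lambda, s$eps), iters),
                      error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) {
        best <- res
      }
    }
    if (is.null(best)) {
      warning("all starts failed at continuation step ", m,
              "; returning partial path")
      failed_steps <- m
      break
    }
    pe <- .unpack(best$par, cfg)
    lam_inc <- pmin(pmax(pe$lambda, cfg$lambda_bounds[1]),
                    cfg$lambda_bounds[2])
    eps_inc <- pe$eps
    path[[m + 1]] <- c(theta = theta, H = best$value, lam_inc,
                       .eps_path(eps_inc))
    if (verbose) {
      message(sprintf("step %d/%d theta=%.2f H=%.5g", m, cfg$M, theta,
                      best$value))
    }
  }

  eps_full <- c(CaL = 0, NaL = 0, Kr = 0)
  eps_full[names(eps_inc)] <- eps_inc
  structure(list(
    lambda = lam_inc, eps = eps_full[cfg$free_eps],
    ic50 = suppressWarnings(epsilon_to_ic50(eps_full[cfg$free_eps])),
    path = as.data.frame(do.call(rbind, path)),
    doses = dataset$doses, units = dataset$units,
    seed = cfg$seed, config = cfg, aborted_at = failed_steps,
    final_cost = path[[length(path)]][["H"]]
  ), class = "inversion_result")
}

.eps_path <- function(eps) {
  stats::setNames(eps, paste0("eps_", names(eps), recycle0 = TRUE))
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("<inversion_result> final cost", signif(x$final_cost, 4),
      "after", nrow(x$path) - 1, "continuation steps\n")
  cat("lambda:\n"); print(round(x$lambda, 4))
  print(ic50_report(x$eps, x$units))
  invisible(x)
}
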