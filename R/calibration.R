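#' Firefly-Algorithm configuration
#'
#' Control settings of the constrained Firefly Algorithm. Defaults are
#' the published calibration setup: swarm 100, 50 iterations,
#' improvement tolerance 1e-4, randomization (mutation) coefficient
#' alpha 0.2, light absorption coefficient gamma 0.8, and base
#' attractiveness beta0 1. Distances, attraction and the random walk
#' all operate in the unit hypercube obtained by scaling each parameter
#' to its bounds; alpha is held fixed (no decay schedule).
#'
#' @param swarm_size Number of fireflies (>= 2 for a swarm; 1 allowed
#'   for degenerate testing).
#' @param iterations Maximum iteration count.
#' @param tolerance Convergence target on the objective: iteration
#'   stops early once the best objective falls to or below this value.
#'   (An improvement-based reading would halt a stochastic swarm on its
#'   first zero-improvement iteration, long before the iteration
#'   budget.)
#' @param alpha Randomization coefficient in \[0, 1\]: the random-walk
#'   step is `alpha * U(-0.5, 0.5)` per coordinate in scaled space.
#' @param gamma Light absorption coefficient (> 0): attraction decays
#'   as `exp(-gamma r^2)` with scaled Euclidean distance r.
#' @param beta0 Attractiveness at zero distance.
#' @param seed Integer RNG seed; mandatory for reproducible runs.
#' @return List of class `vb_fa_config`.
#' @export
fa_config <- function(swarm_size = 100, iterations = 50, tolerance = 1e-4,
                      alpha = 0.2, gamma = 0.8, beta0 = 1, seed = 1L) {
  if (swarm_size < 1) abort("swarm_size must be >= 1")
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (gamma <= 0) abort("gamma must be > 0")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 tolerance = tolerance, alpha = alpha, gamma = gamma,
                 beta0 = beta0, seed = as.integer(seed)),
            class = "vb_fa_config")
}

#' One firefly update step
#'
#' Moves firefly i given firefly j, in bound-scaled (unit hypercube)
#' coordinates. If j is brighter (larger `brightness_j`, i.e. lower
#' objective), i is attracted:
#' `x_i <- x_i + beta0 exp(-gamma r^2) (x_j - x_i) + alpha u`,
#' with `u ~ U(-0.5, 0.5)` per coordinate and r the Euclidean distance.
#' Otherwise only the random walk applies (the move of the current
#' best). Consumes the global RNG stream.
#'
#' @param position_i,position_j Numeric vectors in the unit hypercube.
#' @param brightness_i,brightness_j Brightness values (higher is
#'   better; use the negated objective).
#' @param config A `vb_fa_config`.
#' @return Updated position of firefly i (unclipped).
#' @export
firefly_move <- function(position_i, position_j, brightness_i, brightness_j,
                         config) {
  u <- runif(length(position_i), -0.5, 0.5)
  if (brightness_j > brightness_i) {
    r2 <- sum((position_i - position_j)^2)
    beta <- config$beta0 * exp(-config$gamma * r2)
    position_i + beta * (position_j - position_i) + config$alpha * u
  } else {
    position_i + config$alpha * u
  }
}

#' Minimize an objective with the constrained Firefly Algorithm
#'
#' Generic bound-constrained FA minimizer. The swarm is initialized
#' uniformly over the box (seeded), optionally projected onto a
#' feasible set, and iterated: within each iteration every ordered pair
#' is visited with brightness values frozen at the iteration start,
#' less-bright fireflies move toward brighter ones via
#' [firefly_move()], the iteration-best firefly performs a pure random
#' walk, positions are clipped to the box, re-projected, and
#' re-evaluated once per firefly. The best-so-far solution is tracked,
#' so the returned history is non-increasing; iteration stops at the
#' iteration budget or as soon as the best objective reaches
#' `tolerance`, whichever comes first.
#'
#' @param fn Objective to minimize; takes a numeric vector in original
#'   (unscaled) units.
#' @param lower,upper Box bounds, equal lengths.
#' @param config A `vb_fa_config`.
#' @param project Optional feasibility projection applied to every
#'   candidate before evaluation: function from and to original units.
#' @return List: `best` (original units), `best_objective`, `history`
#'   tibble (iteration, best_objective, improvement), `evaluations`,
#'   `seed`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- firefly_optimize(sphere, c(-5, -5), c(5, 5),
#'                         fa_config(swarm_size = 30, iterations = 20, seed = 7))
#' fit$best_objective
#' @export
firefly_optimize <- function(fn, lower, upper, config = fa_config(),
                             project = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  span <- upper - lower
  to_raw <- function(u) lower + u * span
  to_unit <- function(x) (x - lower) / span
  feas <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    if (is.null(project)) u else to_unit(project(to_raw(u)))
  }
  withr::local_seed(config$seed)
  ns <- config$swarm_size
  X <- matrix(runif(ns * d), nrow = ns)
  X <- t(apply(X, 1, feas))
  if (d == 1) X <- matrix(t(X), ncol = 1)  # apply() drops dims
  obj <- apply(X, 1, function(u) fn(to_raw(u)))
  evals <- ns
  best_i <- which.min(obj)
  best_u <- X[best_i, ]
  best_f <- obj[best_i]
  hist_f <- numeric(0)
  hist_imp <- numeric(0)
  for (it in seq_len(config$iterations)) {
    prev_best <- best_f
    iter_best <- which.min(obj)
    for (i in seq_len(ns)) {
      if (i == iter_best) {
        # current best: pure random walk
        X[i, ] <- X[i, ] + config$alpha * runif(d, -0.5, 0.5)
        next
      }
      for (j in seq_len(ns)) {
        if (obj[j] < obj[i])
          X[i, ] <- firefly_move(X[i, ], X[j, ], -obj[i], -obj[j], config)
      }
    }
    X <- t(apply(X, 1, feas))
    if (d == 1) X <- matrix(t(X), ncol = 1)
    obj <- apply(X, 1, function(u) fn(to_raw(u)))
    evals <- evals + ns
    if (min(obj) < best_f) {
      best_i <- which.min(obj)
      best_f <- obj[best_i]
      best_u <- X[best_i, ]
    }
    hist_f <- c(hist_f, best_f)
    hist_imp <- c(hist_imp, prev_best - best_f)
    if (best_f <= config$tolerance) break
  }
  list(best = to_raw(best_u), best_objective = best_f,
       history = tibble(iteration = seq_along(hist_f),
                        best_objective = hist_f, improvement = hist_imp),
       evaluations = evals, seed = config$seed)
}

#' Weighted squared-error calibration objective
#'
#' The quantity the calibrator minimizes: the weighted sum of squared
#' magnitude errors between model and target curves over the target
#' frequency grid,
#' `F = sum_i lambda_1 (|STHT_e| - |STHT_p|)^2 +
#'          lambda_2 (|DPMI_e| - |DPMI_p|)^2 +
#'          lambda_3 (|AM_e| - |AM_p|)^2`.
#' Phases are not fitted. Because DPMI magnitudes run in the thousands
#' while STHT is near one, the raw objective effectively prioritizes
#' DPMI; `normalize = TRUE` divides each response's residuals by the
#' mean target magnitude to balance the three responses (default off,
#' matching the literal definition).
#'
#' @param params A `vb_params`.
#' @param targets Target magnitude table (`frequency_hz`, `stht_mag`,
#'   `dpmi_mag`, `am_mag`).
#' @param topology A `vb_topology`.
#' @param weights Response weights `(lambda_1, lambda_2, lambda_3)`,
#'   normalized to sum to 1.
#' @param normalize Balance response scales by the target means?
#' @return Non-negative scalar; 0 iff the model reproduces every target
#'   point exactly.
#' @export
objective_value <- function(params, targets, topology,
                            weights = c(1, 1, 1) / 3, normalize = FALSE) {
  weights <- weights / sum(weights)
  sys <- assemble_system(topology, params)
  mags <- curve_magnitudes(biodynamic_curves(sys, targets$frequency_hz))
  scl <- if (normalize)
    c(mean(targets$stht_mag), mean(targets$dpmi_mag), mean(targets$am_mag))
  else c(1, 1, 1)
  sum(weights[1] * ((targets$stht_mag - mags$stht_mag) / scl[1])^2 +
      weights[2] * ((targets$dpmi_mag - mags$dpmi_mag) / scl[2])^2 +
      weights[3] * ((targets$am_mag - mags$am_mag) / scl[3])^2)
}

#' Calibrate model parameters against target biodynamic curves
#'
#' Fits the segment masses and coupling coefficients to target
#' magnitude curves by minimizing [objective_value()] with the
#' constrained Firefly Algorithm. Every candidate — including the
#' initial swarm — is projected through [project_constraints()] before
#' evaluation, so all evaluated parameter sets satisfy the mass-sum,
#' left/right symmetry and bound constraints exactly.
#'
#' @inheritParams objective_value
#' @param targets Target magnitude table; its `frequency_hz` column is
#'   the fitting grid.
#' @param config A [fa_config()]; the seed is echoed into the result.
#' @return Object of class `vb_calibration`: `best_params`
#'   (a constrained `vb_params`), `best_objective`, `history` tibble,
#'   `evaluations`, `seed`, `gof` (one-row [gof_report()] of the fitted
#'   model), and the `config`.
#' @export
calibrate <- function(targets, topology, config = fa_config(),
                      weights = c(1, 1, 1) / 3, normalize = FALSE) {
  check_grid(targets$frequency_hz)
  b <- parameter_bounds(topology)
  fit <- firefly_optimize(
    fn = function(v) objective_value(decode_parameters(v, topology),
                                     targets, topology, weights, normalize),
    lower = b$lower, upper = b$upper, config = config,
    project = function(v) encode_parameters(project_constraints(v, topology)))
  best_params <- project_constraints(fit$best, topology)
  sys <- assemble_system(topology, best_params)
  curves <- biodynamic_curves(sys, targets$frequency_hz)
  structure(list(best_params = best_params,
                 best_objective = fit$best_objective,
                 history = fit$history, evaluations = fit$evaluations,
                 seed = fit$seed,
                 gof = gof_report(curves, targets, weights),
                 config = config, topology = topology),
            class = "vb_calibration")
}

#' @export
print.vb_calibration <- function(x, ...) {
  cat("<vb_calibration> objective ", format(x$best_objective),
      " after ", nrow(x$history), " iterations (",
      x$evaluations, " evaluations, seed ", x$seed, ")\n", sep = "")
  cat("weighted goodness of fit: ",
      sprintf("%.2f%%", 100 * x$gof$eps_weighted), "\n", sep = "")
  invisible(x)
}

#' @describeIn calibrate Fitted parameters as a long tibble
#'   (`parameter`, `value`, `unit`).
#' @param x A `vb_calibration`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vb_calibration <- function(x, ...) {
  as_tibble(x$best_params)
}

#' @describeIn calibrate One-row run summary: objective, evaluation
#'   count, iterations run, seed, and the goodness-of-fit columns.
#' @exportS3Method generics::glance
glance.vb_calibration <- function(x, ...) {
  dplyr::bind_cols(
    tibble(best_objective = x$best_objective,
           iterations_run = nrow(x$history),
           evaluations = x$evaluations, seed = x$seed),
    x$gof)
}
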