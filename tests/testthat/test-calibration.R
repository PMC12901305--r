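test_that("objective is zero on self-targets and quadratic in the residuals", {
  topo <- female_10dof_topology()
  truth <- female_truth(topo)
  targets <- generate_targets(truth, topo, coarse_grid())
  expect_equal(objective_value(truth, targets, topo), 0)
  # doubling every pointwise error quadruples the objective
  sys <- assemble_system(topo, truth)
  model <- curve_magnitudes(biodynamic_curves(sys, coarse_grid()))
  t1 <- targets; t2 <- targets
  delta <- 0.03 * model$stht_mag
  t1$stht_mag <- model$stht_mag + delta
  t2$stht_mag <- model$stht_mag + 2 * delta
  expect_equal(objective_value(truth, t2, topo),
               4 * objective_value(truth, t1, topo), tolerance = 1e-10)
})

test_that("objective reproduces the three-point hand computation", {
  topo <- female_10dof_topology()
  truth <- female_truth(topo)
  grid <- c(2, 5, 8)
  sys <- assemble_system(topo, truth)
  model <- curve_magnitudes(biodynamic_curves(sys, grid))
  targets <- model
  targets$stht_mag <- targets$stht_mag + c(0.1, 0.2, 0.3)
  class(targets) <- c("vb_targets", class(targets))
  expect_equal(objective_value(truth, targets, topo),
               (0.01 + 0.04 + 0.09) / 3, tolerance = 1e-10)
  expect_equal((0.01 + 0.04 + 0.09) / 3, 0.046667, tolerance = 1e-5)
  # per-response normalization divides residuals by the target means
  expect_equal(objective_value(truth, targets, topo, normalize = TRUE),
               sum((c(0.1, 0.2, 0.3) / mean(targets$stht_mag))^2) / 3,
               tolerance = 1e-10)
})

test_that("objective is invariant under left/right arm relabeling", {
  topo <- female_10dof_topology()
  truth <- female_truth(topo)
  targets <- generate_targets(truth, topo, coarse_grid())
  v <- encode_parameters(truth)
  # deliberately asymmetric arms
  v[c("m5", "m6", "m7")] <- c(3.1, 1.2, 0.5)
  v[c("k5", "k6", "k7")] <- c(9e4, 1.2e5, 8e4)
  v[c("c5", "c6", "c7")] <- c(1200, 900, 1500)
  swap <- v
  arm_l <- c("m5", "m6", "m7", "k5", "k6", "k7", "c5", "c6", "c7")
  arm_r <- c("m8", "m9", "m10", "k8", "k9", "k10", "c8", "c9", "c10")
  swap[arm_l] <- v[arm_r]; swap[arm_r] <- v[arm_l]
  expect_equal(
    objective_value(decode_parameters(swap, topo), targets, topo),
    objective_value(decode_parameters(v, topo), targets, topo),
    tolerance = 1e-12)
})

test_that("firefly moves obey the attraction limits", {
  cfg0 <- fa_config(alpha = 0, gamma = 0.8, seed = 1)
  xj <- c(0.2, 0.7)
  # zero distance, full attraction: lands exactly on the brighter firefly
  expect_equal(firefly_move(xj, xj + 0, -5, -1, cfg0), xj)
  # infinite absorption: attraction vanishes
  cfg_inf <- fa_config(alpha = 0, gamma = 1e12, seed = 1)
  xi <- c(0.1, 0.1)
  expect_equal(firefly_move(xi, xj, -5, -1, cfg_inf), xi, tolerance = 1e-12)
  # unit distance: attraction factor exp(-gamma)
  xi2 <- c(0, 0.5); xj2 <- c(1, 0.5)
  moved <- firefly_move(xi2, xj2, -5, -1, cfg0)
  expect_equal((moved - xi2)[1] / (xj2 - xi2)[1], exp(-0.8),
               tolerance = 1e-12)
  expect_equal(exp(-0.8), 0.44933, tolerance = 1e-5)
  # dimmer j: pure random walk, zero with alpha = 0
  expect_equal(firefly_move(xi2, xj2, -1, -5, cfg0), xi2)
})

test_that("the swarm solves the sphere benchmark and beats random search", {
  cfg <- fa_config(swarm_size = 100, iterations = 50, seed = 11)
  fit <- firefly_optimize(function(x) sum(x^2), c(-5, -5), c(5, 5), cfg)
  expect_lt(fit$best_objective, 1e-3)
  # random-search baseline with the same evaluation budget
  baseline <- withr::with_seed(11, {
    min(vapply(seq_len(fit$evaluations),
               function(i) sum(runif(2, -5, 5)^2), numeric(1)))
  })
  expect_lt(fit$best_objective, baseline)
})

test_that("identical seeds give bit-identical runs and monotone history", {
  topo <- female_10dof_topology()
  truth <- female_truth(topo)
  targets <- generate_targets(truth, topo, coarse_grid())
  cfg <- fa_config(swarm_size = 12, iterations = 6, seed = 303)
  fit1 <- calibrate(targets, topo, cfg)
  fit2 <- calibrate(targets, topo, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$best_params, fit2$best_params)
  expect_true(all(diff(fit1$history$best_objective) <= 0))
  expect_equal(fit1$best_objective,
               fit1$history$best_objective[nrow(fit1$history)])
  expect_equal(fit1$seed, 303L)
})

test_that("a single firefly with zero alpha is stationary", {
  cfg <- fa_config(swarm_size = 1, iterations = 5, alpha = 0, seed = 9)
  fit <- firefly_optimize(function(x) sum((x - 2)^2), c(-5, -5), c(5, 5), cfg)
  expect_equal(length(unique(fit$history$best_objective)), 1)
  expect_equal(fit$history$best_objective[1], fit$best_objective)
})

test_that("every evaluated candidate satisfies the constraint block", {
  topo <- female_10dof_topology()
  truth <- female_truth(topo)
  targets <- generate_targets(truth, topo, coarse_grid())
  seen <- list()
  fn <- function(v) {
    seen[[length(seen) + 1]] <<- v
    objective_value(decode_parameters(v, topo), targets, topo)
  }
  b <- parameter_bounds(topo)
  invisible(firefly_optimize(
    fn, b$lower, b$upper, fa_config(swarm_size = 8, iterations = 4, seed = 5),
    project = function(v) encode_parameters(project_constraints(v, topo))))
  expect_gt(length(seen), 8)
  for (v in seen)
    expect_true(is_constrained(decode_parameters(v, topo), topo, tol = 1e-8))
})

test_that("calibration tidiers summarize the fitted model", {
  topo <- female_10dof_topology()
  truth <- female_truth(topo)
  targets <- generate_targets(truth, topo, coarse_grid())
  fit <- calibrate(targets, topo,
                   fa_config(swarm_size = 10, iterations = 4, seed = 2))
  td <- tidy(fit)
  expect_equal(nrow(td), 30)
  expect_named(td, c("parameter", "value", "unit"))
  g <- glance(fit)
  expect_equal(g$best_objective, fit$best_objective)
  expect_true(all(c("eps_weighted", "evaluations", "seed") %in% names(g)))
})
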