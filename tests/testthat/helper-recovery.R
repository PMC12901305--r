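# One full-size parameter-recovery calibration, shared by the acceptance
# tests (swarm 100, 50 iterations, alpha 0.2, gamma 0.8, default grid).
# Cached so the suite pays its ~1 minute cost once.
recovery_cache <- new.env(parent = emptyenv())

recovery_run <- function() {
  if (!is.null(recovery_cache$fit)) return(recovery_cache$fit)
  topo <- female_10dof_topology()
  truth <- female_truth(topo)
  targets <- generate_targets(truth, topo, frequency_grid(), noise_cv = 0)
  fit <- calibrate(targets, topo, fa_config(seed = 1))
  recovery_cache$fit <- list(topology = topo, truth = truth,
                             targets = targets, fit = fit)
  recovery_cache$fit
}
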