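#' Generate synthetic target curves with known ground truth
#'
#' Forward-models the three biodynamic magnitude curves from a known
#' ("true") parameter set and optionally corrupts each point with
#' independent multiplicative lognormal noise of unit median and
#' coefficient of variation `noise_cv`. Magnitude curves are positive
#' and their measurement error scales with level, which is what the
#' multiplicative lognormal model expresses. The returned table plays
#' the role of experimental data in calibration and parameter-recovery
#' studies: the generating truth is recorded in the `provenance`
#' attribute, closing the loop with [calibrate()] and [gof_report()]
#' (noiseless targets give objective 0 and goodness of fit 1 at the
#' true parameters).
#'
#' @param true_params A constrained `vb_params`: the ground truth.
#' @param topology A `vb_topology`.
#' @param frequencies Frequency grid in Hz (default [frequency_grid()]).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   noise (>= 0; 0 = noiseless passthrough).
#' @param seed Integer seed for the noise draws; required when
#'   `noise_cv > 0`.
#' @param driving_point Passed to [biodynamic_curves()].
#' @return Tibble of class `vb_targets` with columns `frequency_hz`,
#'   `stht_mag`, `dpmi_mag`, `am_mag`; attribute `provenance` records
#'   `true_params`, `seed` and `noise_cv`.
#' @examples
#' topo <- female_10dof_topology()
#' truth <- project_constraints(default_parameters(topo), topo)
#' tgt <- generate_targets(truth, topo, noise_cv = 0.05, seed = 7)
#' @export
generate_targets <- function(true_params, topology,
                             frequencies = frequency_grid(),
                             noise_cv = 0, seed = NULL,
                             driving_point = c("seat", "pelvis")) {
  stopifnot(inherits(true_params, "vb_params"), noise_cv >= 0)
  if (noise_cv > 0 && is.null(seed))
    abort("a seed is required when noise_cv > 0")
  sys <- assemble_system(topology, true_params)
  mags <- curve_magnitudes(
    biodynamic_curves(sys, frequencies, driving_point = match.arg(driving_point)))
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))  # unit-median lognormal with CV = noise_cv
    n <- nrow(mags)
    withr::with_seed(seed, {
      for (col in c("stht_mag", "dpmi_mag", "am_mag"))
        mags[[col]] <- mags[[col]] * rlnorm(n, meanlog = 0, sdlog = sdlog)
    })
  }
  class(mags) <- c("vb_targets", class(mags))
  attr(mags, "provenance") <- list(true_params = true_params,
                                   seed = seed, noise_cv = noise_cv)
  mags
}
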