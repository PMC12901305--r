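#' Normalized goodness of fit between two magnitude curves
#'
#' The fit statistic used throughout the calibration reports:
#' `eps = 1 - sqrt(sum((tau_e - tau_p)^2) / (N - 2)) / (mean(tau_e))`,
#' i.e. one minus the residual RMS (with an N - 2 denominator) relative
#' to the mean target level. `eps = 1` iff the curves are identical;
#' very poor fits can drive it negative, and it is deliberately not
#' clipped. Scale-covariant: rescaling both curves by the same positive
#' factor leaves it unchanged.
#'
#' @param tau_e Target (experimental) magnitude vector; mean must be
#'   positive.
#' @param tau_p Model magnitude vector, same length; N > 2 required.
#' @return Dimensionless scalar (<= 1).
#' @examples
#' goodness_of_fit(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2))  # 0.925167
#' @export
goodness_of_fit <- function(tau_e, tau_p) {
  if (length(tau_e) != length(tau_p)) abort("curve lengths differ")
  n <- length(tau_e)
  if (n <= 2) abort("need more than 2 points (N - 2 denominator)")
  if (sum(tau_e) <= 0) abort("target curve has non-positive mean")
  1 - sqrt(sum((tau_e - tau_p)^2) / (n - 2)) / (sum(tau_e) / n)
}

#' Weighted overall goodness of fit
#'
#' Combines the per-response statistics into the overall score
#' `eps_bar = lambda_1 eps_STHT + lambda_2 eps_DPMI + lambda_3 eps_AM`.
#' With the default equal weights this is the arithmetic mean. Given a
#' matrix (one row per model), returns one weighted value per row;
#' `max()` of that vector is the best-model score used in multi-model
#' comparisons.
#'
#' @param eps Numeric length-3 vector `(eps_stht, eps_dpmi, eps_am)`,
#'   or a 3-column matrix with one row per model.
#' @param weights Non-negative weights; normalized to sum to 1 (default
#'   equal thirds).
#' @return Scalar, or vector with one entry per row of `eps`.
#' @export
weighted_gof <- function(eps, weights = c(1, 1, 1) / 3) {
  if (any(weights < 0)) abort("weights must be non-negative")
  weights <- weights / sum(weights)
  if (is.matrix(eps)) {
    stopifnot(ncol(eps) == length(weights))
    drop(eps %*% weights)
  } else {
    stopifnot(length(eps) == length(weights))
    sum(eps * weights)
  }
}

#' Goodness-of-fit report for a fitted model
#'
#' Per-response fit statistics of model curves against target curves on
#' a matching grid, the weighted overall statistic, and the sample
#' variance of the three per-response values (a dispersion indicator:
#' low variance means the model fits all three responses equally well).
#' Values are stored on the 0-1 scale; multiply by 100 for display as
#' percentages.
#'
#' @param model_curves A `vb_curves` tibble (or magnitude table).
#' @param targets A target magnitude table with `frequency_hz`,
#'   `stht_mag`, `dpmi_mag`, `am_mag`.
#' @param weights Response weights, as in [weighted_gof()].
#' @return One-row tibble: `eps_stht`, `eps_dpmi`, `eps_am`,
#'   `eps_weighted`, `variance`, `n_points`.
#' @export
gof_report <- function(model_curves, targets, weights = c(1, 1, 1) / 3) {
  mags <- if (all(c("stht_mag", "dpmi_mag", "am_mag") %in% names(model_curves)))
    model_curves else curve_magnitudes(model_curves)
  if (nrow(mags) != nrow(targets) ||
      max(abs(mags$frequency_hz - targets$frequency_hz)) >
        1e-8 * max(targets$frequency_hz))
    abort("model and target grids do not match")
  eps <- vapply(c("stht_mag", "dpmi_mag", "am_mag"), function(col)
    goodness_of_fit(targets[[col]], mags[[col]]), numeric(1))
  tibble(eps_stht = eps[[1]], eps_dpmi = eps[[2]], eps_am = eps[[3]],
         eps_weighted = weighted_gof(unname(eps), weights),
         variance = var(unname(eps)),
         n_points = nrow(mags))
}
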