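#' Frequency grid for biodynamic response evaluation
#'
#' @param fmin,fmax Grid limits in Hz; defaults span 0.5-20 Hz, the
#'   band where seated occupants are most vibration-sensitive.
#' @param df Step in Hz (default 0.1, giving 196 points on the default
#'   span).
#' @return Strictly increasing numeric vector of frequencies (Hz).
#' @export
frequency_grid <- function(fmin = 0.5, fmax = 20, df = 0.1) {
  if (fmin <= 0) abort("fmin must be > 0 (the static point is a limit, not a grid point)")
  if (fmax <= fmin) abort("fmax must exceed fmin")
  if (df <= 0) abort("df must be > 0")
  f <- seq(fmin, fmax, by = df)
  check_grid(f)
  f
}

check_grid <- function(f, min_points = 3L) {
  if (length(f) < min_points)
    abort("frequency grid needs at least 3 points (the N - 2 goodness-of-fit denominator)")
  if (any(f <= 0) || any(diff(f) <= 0))
    abort("frequencies must be positive and strictly increasing")
  invisible(f)
}

#' Harmonic steady-state response under base excitation
#'
#' Solves the frequency-domain equations of motion
#' `(-omega^2 M + i omega C + K) Z = (base_k + i omega base_c) Z0 e_b`
#' for unit seat displacement amplitude `Z0 = 1`, where `e_b` selects
#' the base row. As `omega -> 0` every grounded segment follows the
#' seat, so `Z -> 1`.
#'
#' @param sys A `vb_system`.
#' @param omega Angular frequency, rad/s (>= 0).
#' @return Complex displacement vector of length n (per unit seat
#'   displacement).
#' @export
steady_state_response <- function(sys, omega) {
  stopifnot(inherits(sys, "vb_system"), omega >= 0)
  n <- nrow(sys$K)
  A <- -omega^2 * sys$M + (1i * omega) * sys$C + sys$K
  f <- complex(length.out = n)
  f[sys$base_row] <- sys$base_k + 1i * omega * sys$base_c
  Z <- tryCatch(solve(A, f),
                error = function(e)
                  abort(paste0("singular system matrix at omega = ", omega,
                               " (ungrounded system?): ", conditionMessage(e))))
  Z
}

#' Biodynamic transfer functions on a frequency grid
#'
#' Computes the three standard seated-body responses per unit seat
#' displacement: seat-to-head transmissibility `STHT = Z_head / Z0`
#' (dimensionless), and from the force transmitted through the seat
#' coupling, `F = (base_k + i omega base_c) (Z0 - Z_base)`, the
#' driving-point mechanical impedance `DPMI = F / (i omega Z0)` (N.s/m)
#' and apparent mass `AM = F / (-omega^2 Z0)` (kg). With the seat
#' motion in the denominator the textbook static limit holds:
#' `AM -> total mass` as `f -> 0`, and `DPMI = i omega AM` identically.
#' `driving_point = "pelvis"` instead divides by the motion of the base
#' segment itself (the literal driving-location reading); it changes
#' the low-frequency plateau and is provided for comparison.
#'
#' @param sys A `vb_system`.
#' @param frequencies Frequency grid in Hz (see [frequency_grid()]).
#' @param head Segment index whose motion defines transmissibility
#'   (default 1).
#' @param driving_point `"seat"` (default) or `"pelvis"`: the motion
#'   used in the DPMI/AM denominators.
#' @return A tibble of class `vb_curves` with columns `frequency_hz`
#'   and complex `stht`, `dpmi`, `am`.
#' @examples
#' topo <- female_10dof_topology()
#' sys <- assemble_system(topo, default_parameters(topo))
#' curves <- biodynamic_curves(sys, frequency_grid())
#' peak_summary(curves)
#' @export
biodynamic_curves <- function(sys, frequencies = frequency_grid(),
                              head = 1L,
                              driving_point = c("seat", "pelvis")) {
  stopifnot(inherits(sys, "vb_system"))
  check_grid(frequencies, min_points = 1L)
  driving_point <- match.arg(driving_point)
  res <- purrr::map(frequencies, function(f) {
    w <- 2 * pi * f
    Z <- steady_state_response(sys, w)
    Ft <- (sys$base_k + 1i * w * sys$base_c) * (1 - Z[sys$base_row])
    denom <- if (driving_point == "seat") 1 + 0i else Z[sys$base_row]
    c(stht = Z[head],
      dpmi = Ft / (1i * w * denom),
      am = Ft / (-w^2 * denom))
  })
  out <- tibble(
    frequency_hz = frequencies,
    stht = vapply(res, `[[`, complex(1), "stht"),
    dpmi = vapply(res, `[[`, complex(1), "dpmi"),
    am = vapply(res, `[[`, complex(1), "am"))
  class(out) <- c("vb_curves", class(out))
  attr(out, "total_mass") <- sum(sys$masses)
  attr(out, "driving_point") <- driving_point
  out
}

#' Magnitude table of a set of biodynamic curves
#'
#' @param curves A `vb_curves` tibble.
#' @return Tibble with columns `frequency_hz`, `stht_mag`, `dpmi_mag`,
#'   `am_mag` — the schema used for calibration targets.
#' @export
curve_magnitudes <- function(curves) {
  tibble(frequency_hz = curves$frequency_hz,
         stht_mag = Mod(curves$stht),
         dpmi_mag = Mod(curves$dpmi),
         am_mag = Mod(curves$am))
}

#' Peak magnitude and frequency of each biodynamic response
#'
#' The reported peak is the grid argmax of each magnitude curve; exact
#' ties resolve to the lower frequency.
#'
#' @param curves A `vb_curves` tibble (or a magnitude table with
#'   `*_mag` columns).
#' @return Tibble with columns `response`, `peak_frequency_hz`,
#'   `peak_magnitude`.
#' @export
peak_summary <- function(curves) {
  mags <- if (all(c("stht_mag", "dpmi_mag", "am_mag") %in% names(curves)))
    curves else curve_magnitudes(curves)
  purrr::map_dfr(c("stht", "dpmi", "am"), function(resp) {
    m <- mags[[paste0(resp, "_mag")]]
    i <- which.max(m)  # which.max returns the first (lowest-f) maximum
    tibble(response = resp,
           peak_frequency_hz = mags$frequency_hz[i],
           peak_magnitude = m[i])
  })
}
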