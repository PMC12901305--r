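#' Undamped natural frequencies and mode shapes
#'
#' Solves the generalized symmetric eigenproblem `K phi = omega^2 M phi`
#' via the mass-normalized standard form
#' `M^(-1/2) K M^(-1/2) y = omega^2 y` (exact for the diagonal mass
#' matrix of a lumped model), then back-transforms `phi = M^(-1/2) y`.
#' Modes are returned sorted by ascending frequency. Each mode shape is
#' normalized to unit maximum absolute entry with a positive sign at its
#' largest-magnitude component, so comparisons against published mode
#' tables are made up to scale. With `base_k = 0` (ungrounded chain) the
#' lowest mode is the zero-frequency rigid-body mode.
#'
#' @param sys A `vb_system` (symmetric `K`; non-symmetric input is
#'   rejected).
#' @return An object of class `vb_modes`: list with
#'   `natural_frequencies_hz` (ascending, length n) and `mode_shapes`
#'   (n x n matrix, column j = mode j), plus the mass vector for
#'   orthogonality checks.
#' @examples
#' topo <- female_10dof_topology()
#' modes <- undamped_modes(assemble_system(topo, default_parameters(topo)))
#' head(modes$natural_frequencies_hz, 5)
#' @export
undamped_modes <- function(sys) {
  stopifnot(inherits(sys, "vb_system"))
  if (!isSymmetric(sys$K, tol = 0))
    abort("stiffness matrix is not symmetric")
  d <- sqrt(sys$masses)
  A <- sys$K / tcrossprod(d)      # M^(-1/2) K M^(-1/2)
  e <- eigen(A, symmetric = TRUE)
  ord <- order(e$values)
  lam <- e$values[ord]
  # clamp eigenvalue noise around the rigid-body zero
  lam[lam < 0 & lam > -1e-9 * max(abs(lam))] <- 0
  phi <- e$vectors[, ord, drop = FALSE] / d
  for (j in seq_len(ncol(phi))) {
    i <- which.max(abs(phi[, j]))
    phi[, j] <- phi[, j] / phi[i, j]
  }
  structure(list(natural_frequencies_hz = sqrt(lam) / (2 * pi),
                 mode_shapes = phi, masses = sys$masses),
            class = "vb_modes")
}

#' @export
print.vb_modes <- function(x, n_show = 5, ...) {
  cat("<vb_modes> ", length(x$natural_frequencies_hz), " modes; first ",
      min(n_show, length(x$natural_frequencies_hz)), ":\n", sep = "")
  print(round(head(x$natural_frequencies_hz, n_show), 3))
  invisible(x)
}

#' @describeIn undamped_modes Long tibble of mode shapes: one row per
#'   (mode, segment) with the mode's natural frequency and the
#'   normalized shape amplitude.
#' @param x A `vb_modes` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.vb_modes <- function(x, ...) {
  n <- length(x$natural_frequencies_hz)
  tidyr::expand_grid(mode = seq_len(n), segment = seq_len(n)) |>
    dplyr::mutate(
      frequency_hz = x$natural_frequencies_hz[.data$mode],
      amplitude = x$mode_shapes[cbind(.data$segment, .data$mode)]) |>
    dplyr::relocate("mode", "frequency_hz", "segment", "amplitude")
}

#' @describeIn undamped_modes One-row summary (mode count, frequency
#'   range, rigid-body flag).
#' @exportS3Method generics::glance
glance.vb_modes <- function(x, ...) {
  f <- x$natural_frequencies_hz
  tibble(n_modes = length(f), f_min_hz = min(f), f_max_hz = max(f),
         rigid_body = min(f) < 1e-8)
}
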