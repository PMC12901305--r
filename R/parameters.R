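#' Create a parameter set for a model topology
#'
#' Bundles the segment masses and the coupling stiffness and damping
#' coefficients of a lumped model. A parameter set is "constrained"
#' when it satisfies the anthropometric constraint block enforced by
#' [project_constraints()]: the masses sum to the total supported mass,
#' left/right symmetric segments and couplings are equal, and every
#' stiffness and damping lies inside its physiological bounds.
#'
#' @param masses Numeric vector of segment masses, kg (> 0), ordered by
#'   segment index.
#' @param stiffness Numeric vector of coupling stiffnesses, N/m, ordered
#'   by coupling id.
#' @param damping Numeric vector of coupling damping coefficients,
#'   N.s/m, ordered by coupling id.
#' @param total_mass Total supported body mass, kg (default 54, the
#'   seated-female model constraint).
#' @return An object of class `vb_params`.
#' @export
parameter_set <- function(masses, stiffness, damping, total_mass = 54) {
  stopifnot(is.numeric(masses), is.numeric(stiffness), is.numeric(damping),
            length(stiffness) == length(damping))
  if (any(!is.finite(c(masses, stiffness, damping))))
    abort("non-finite parameter values")
  if (any(masses <= 0)) abort("masses must be strictly positive")
  structure(list(masses = unname(masses), stiffness = unname(stiffness),
                 damping = unname(damping), total_mass = total_mass),
            class = "vb_params")
}

#' Default parameter set of a topology
#'
#' @param topology A `vb_topology`; its stored segment masses and
#'   coupling coefficients become the parameter values.
#' @return A `vb_params`.
#' @export
default_parameters <- function(topology) {
  parameter_set(topology$segments$mass_kg,
                topology$couplings$stiffness,
                topology$couplings$damping,
                total_mass = topology$total_mass)
}

#' @export
print.vb_params <- function(x, ...) {
  cat("<vb_params> ", length(x$masses), " masses (sum ",
      format(sum(x$masses)), " kg), ", length(x$stiffness),
      " couplings\n", sep = "")
  print(as_tibble(x), ...)
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.vb_params <- function(x, ...) {
  tibble(
    parameter = c(paste0("m", seq_along(x$masses)),
                  paste0("k", seq_along(x$stiffness)),
                  paste0("c", seq_along(x$damping))),
    value = c(x$masses, x$stiffness, x$damping),
    unit = rep(c("kg", "N/m", "N.s/m"),
               c(length(x$masses), length(x$stiffness), length(x$damping))))
}

#' Flatten a parameter set to the optimization vector
#'
#' The calibrator works on a flat vector ordered (m_1..m_n,
#' k_1..k_nc, c_1..c_nc) — length 30 for the 10-DOF female model,
#' matching its stated optimization variable size. The encoding is
#' bijective with [decode_parameters()].
#'
#' @param params A `vb_params`.
#' @return Named numeric vector.
#' @export
encode_parameters <- function(params) {
  stopifnot(inherits(params, "vb_params"))
  v <- c(params$masses, params$stiffness, params$damping)
  names(v) <- c(paste0("m", seq_along(params$masses)),
                paste0("k", seq_along(params$stiffness)),
                paste0("c", seq_along(params$damping)))
  v
}

#' @rdname encode_parameters
#' @param vector Numeric vector of length `n + 2 * n_c` as produced by
#'   `encode_parameters()`.
#' @param topology The `vb_topology` giving `n` and `n_c`.
#' @export
decode_parameters <- function(vector, topology) {
  n <- nrow(topology$segments)
  nc <- nrow(topology$couplings)
  if (length(vector) != n + 2L * nc)
    abort(paste0("parameter vector length ", length(vector),
                 ", expected ", n + 2L * nc))
  parameter_set(vector[seq_len(n)],
                vector[n + seq_len(nc)],
                vector[n + nc + seq_len(nc)],
                total_mass = topology$total_mass)
}

#' Physiological bounds of the parameter space
#'
#' Stiffness is bounded in (100, 300000) N/m and damping in (500, 4000)
#' N.s/m. Masses have no published bounds; they are kept in
#' \[0.1, total_mass\] kg, which rules out non-physical values while
#' leaving the mass-sum constraint authoritative.
#'
#' @param topology A `vb_topology`.
#' @return List with numeric vectors `lower` and `upper` matching the
#'   encoded parameter vector.
#' @export
parameter_bounds <- function(topology) {
  n <- nrow(topology$segments)
  nc <- nrow(topology$couplings)
  list(lower = c(rep(0.1, n), rep(100, nc), rep(500, nc)),
       upper = c(rep(topology$total_mass, n), rep(300000, nc), rep(4000, nc)))
}

#' Project a parameter vector onto the constraint set
#'
#' Enforces the calibration constraint block: (a) left/right symmetry —
#' each paired mass, stiffness and damping is replaced by the pair's
#' arithmetic mean; (b) bounds — stiffness clipped to (100, 300000) N/m,
#' damping to (500, 4000) N.s/m, masses to \[0.1, total_mass\] kg;
#' (c) mass sum — masses rescaled multiplicatively so they sum exactly
#' to `total_mass`. The order symmetry, clip, rescale guarantees the sum
#' constraint holds exactly on output; masses pinned at the 0.1 kg floor
#' by rescaling are resolved by rescaling only the free masses, so the
#' projection is idempotent.
#'
#' @param x A `vb_params` or an encoded parameter vector.
#' @param topology The `vb_topology` (supplies symmetry pairs and
#'   dimensions).
#' @param total_mass Mass-sum target, kg; defaults to the topology's.
#' @return A constrained `vb_params`.
#' @examples
#' topo <- female_10dof_topology()
#' p <- project_constraints(default_parameters(topo), topo)
#' sum(p$masses)  # exactly 54
#' @export
project_constraints <- function(x, topology, total_mass = topology$total_mass) {
  if (is.numeric(x)) x <- decode_parameters(x, topology)
  stopifnot(inherits(x, "vb_params"))
  if (any(!is.finite(c(x$masses, x$stiffness, x$damping))))
    abort("non-finite parameter values")
  m <- x$masses; k <- x$stiffness; cc <- x$damping
  for (pr in topology$symmetry_pairs) {
    m[pr] <- mean(m[pr]); k[pr] <- mean(k[pr]); cc[pr] <- mean(cc[pr])
  }
  k <- pmin(pmax(k, 100), 300000)
  cc <- pmin(pmax(cc, 500), 4000)
  m <- pmin(pmax(m, 0.1), total_mass)
  # rescale free masses so the sum constraint is met exactly even when
  # some masses sit on the 0.1 kg floor
  floor_kg <- 0.1
  pinned <- rep(FALSE, length(m))
  repeat {
    free <- !pinned
    scale <- (total_mass - floor_kg * sum(pinned)) / sum(m[free])
    m[free] <- m[free] * scale
    newly <- free & m < floor_kg
    if (!any(newly)) break
    m[newly] <- floor_kg
    pinned <- pinned | newly
  }
  parameter_set(m, k, cc, total_mass = total_mass)
}

#' Does a parameter set satisfy the constraint block?
#'
#' @param params A `vb_params`.
#' @param topology The `vb_topology`.
#' @param tol Relative tolerance on the mass sum.
#' @return Logical scalar.
#' @export
is_constrained <- function(params, topology, tol = 1e-9) {
  ok_sum <- abs(sum(params$masses) - params$total_mass) <=
    tol * params$total_mass
  ok_sym <- all(vapply(topology$symmetry_pairs, function(pr) {
    isTRUE(all.equal(params$masses[pr[1]], params$masses[pr[2]])) &&
      isTRUE(all.equal(params$stiffness[pr[1]], params$stiffness[pr[2]])) &&
      isTRUE(all.equal(params$damping[pr[1]], params$damping[pr[2]]))
  }, logical(1)))
  ok_bounds <- all(params$stiffness >= 100 & params$stiffness <= 300000) &&
    all(params$damping >= 500 & params$damping <= 4000)
  ok_sum && ok_sym && ok_bounds
}
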