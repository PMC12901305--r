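#' Assemble system matrices from a topology and parameter set
#'
#' Builds the mass, damping and stiffness matrices of the coupled
#' equations of motion. `M` is diagonal with the segment masses. Each
#' segment-segment coupling (i, j) with coefficients (k, c) contributes
#' the usual stencil `K[i,i] += k`, `K[j,j] += k`, `K[i,j] -= k`,
#' `K[j,i] -= k` (identically for `C`); the single base coupling adds
#' only to the diagonal of its segment's row, so every row of `K` sums
#' to zero except the base row, which sums to the seat stiffness. The
#' harmonic seat excitation enters through the force vector on the base
#' row, with coefficients (`base_k`, `base_c`).
#'
#' @param topology A `vb_topology`.
#' @param params A `vb_params` with lengths matching the topology.
#' @return An object of class `vb_system`: list with `M`, `C`, `K`
#'   (n x n matrices), `base_k`, `base_c`, `base_row`, and `masses`.
#' @examples
#' topo <- female_10dof_topology()
#' sys <- assemble_system(topo, default_parameters(topo))
#' rowSums(sys$K)  # zero everywhere except row 4 (= k4)
#' @export
assemble_system <- function(topology, params) {
  stopifnot(inherits(topology, "vb_topology"), inherits(params, "vb_params"))
  n <- nrow(topology$segments)
  nc <- nrow(topology$couplings)
  if (length(params$masses) != n ||
      length(params$stiffness) != nc)
    abort("parameter lengths do not match topology")
  if (any(params$masses <= 0)) abort("masses must be strictly positive")
  cpl <- topology$couplings
  if (sum(cpl$to == 0L) != 1L) abort("multiple BASE couplings")
  K <- matrix(0, n, n)
  C <- matrix(0, n, n)
  base_k <- 0; base_c <- 0; base_row <- NA_integer_
  for (r in seq_len(nc)) {
    i <- cpl$from[r]; j <- cpl$to[r]
    k <- params$stiffness[r]; cc <- params$damping[r]
    if (j == 0L) {
      K[i, i] <- K[i, i] + k
      C[i, i] <- C[i, i] + cc
      base_k <- k; base_c <- cc; base_row <- i
    } else {
      K[i, i] <- K[i, i] + k; K[j, j] <- K[j, j] + k
      K[i, j] <- K[i, j] - k; K[j, i] <- K[j, i] - k
      C[i, i] <- C[i, i] + cc; C[j, j] <- C[j, j] + cc
      C[i, j] <- C[i, j] - cc; C[j, i] <- C[j, i] - cc
    }
  }
  structure(list(M = diag(params$masses, n), C = C, K = K,
                 masses = params$masses,
                 base_k = base_k, base_c = base_c, base_row = base_row),
            class = "vb_system")
}

#' @export
print.vb_system <- function(x, ...) {
  cat("<vb_system> ", nrow(x$K), " DOF, base row ", x$base_row,
      " (k = ", format(x$base_k), " N/m, c = ", format(x$base_c),
      " N.s/m), total mass ", format(sum(x$masses)), " kg\n", sep = "")
  invisible(x)
}
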