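# Shared fixture builders. Everything is generated in code; no stored data.

# simple grounded chain: segment 1 at the top, segment n attached to the base
chain_topology <- function(n, masses = rep(1, n), k = rep(1000, n),
                           damping = rep(50, n), total_mass = sum(masses)) {
  model_topology(
    segments = tibble::tibble(index = seq_len(n),
                              name = paste0("seg", seq_len(n)),
                              mass_kg = masses),
    couplings = tibble::tibble(id = seq_len(n),
                               from = seq_len(n),
                               to = c(seq_len(n)[-1], 0L),
                               stiffness = k, damping = damping),
    total_mass = total_mass)
}

# random tree topology: random parent structure, base attached to a random
# segment; used for structural property checks
random_topology <- function(n) {
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  base_at <- sample.int(n, 1)
  model_topology(
    segments = tibble::tibble(index = seq_len(n),
                              name = paste0("seg", seq_len(n)),
                              mass_kg = runif(n, 0.5, 20)),
    couplings = tibble::tibble(
      id = seq_len(n),
      from = c(2:n, base_at),
      to = c(parent[-1], 0L),
      stiffness = runif(n, 500, 2e5),
      damping = runif(n, 10, 3000)),
    total_mass = 54)
}

# dense coarse grid for fast calibration tests
coarse_grid <- function() frequency_grid(0.5, 20, 1)

female_truth <- function(topo = female_10dof_topology()) {
  project_constraints(default_parameters(topo), topo)
}

# hand-built system matrices of the 10-DOF female model, written out
# literally from the corrected chain-and-branch stencil; independent of
# assemble_system()
female_matrices_by_hand <- function(k, cc) {
  stencil <- function(v) {
    A <- matrix(0, 10, 10)
    A[1, 1] <- v[1]; A[1, 2] <- A[2, 1] <- -v[1]
    A[2, 2] <- v[1] + v[2] + v[5] + v[8]
    A[2, 3] <- A[3, 2] <- -v[2]
    A[2, 5] <- A[5, 2] <- -v[5]
    A[2, 8] <- A[8, 2] <- -v[8]
    A[3, 3] <- v[2] + v[3]; A[3, 4] <- A[4, 3] <- -v[3]
    A[4, 4] <- v[3] + v[4]
    A[5, 5] <- v[5] + v[6]; A[5, 6] <- A[6, 5] <- -v[6]
    A[6, 6] <- v[6] + v[7]; A[6, 7] <- A[7, 6] <- -v[7]
    A[7, 7] <- v[7]
    A[8, 8] <- v[8] + v[9]; A[8, 9] <- A[9, 8] <- -v[9]
    A[9, 9] <- v[9] + v[10]; A[9, 10] <- A[10, 9] <- -v[10]
    A[10, 10] <- v[10]
    A
  }
  list(K = stencil(k), C = stencil(cc))
}
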