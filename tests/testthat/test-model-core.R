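test_that("female 10-DOF topology has the chain-and-branch structure", {
  topo <- female_10dof_topology()
  expect_equal(nrow(topo$segments), 10)
  expect_equal(nrow(topo$couplings), 10)
  expect_equal(sum(topo$couplings$to == 0L), 1)
  expect_equal(base_segment(topo), 4L)
  # the thorax carries the head, the abdomen chain and both arms
  thorax <- with(topo$couplings, id[from == 2L | to == 2L])
  expect_setequal(thorax, c(1L, 2L, 5L, 8L))
  # segments stay connected among themselves without the seat coupling:
  # walk the segment-segment graph from the head
  cpl <- topo$couplings[topo$couplings$to != 0L, ]
  adj <- lapply(1:10, function(i)
    unique(c(cpl$to[cpl$from == i], cpl$from[cpl$to == i])))
  seen <- logical(10); stack <- 1L
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  expect_true(all(seen))
})

test_that("single-DOF assembly gives scalar matrices", {
  topo <- chain_topology(1, masses = 2, k = 8, damping = 3)
  sys <- assemble_system(topo, default_parameters(topo))
  expect_equal(sys$M, matrix(2))
  expect_equal(sys$K, matrix(8))
  expect_equal(sys$C, matrix(3))
  expect_equal(sys$base_row, 1L)
})

test_that("female assembly matches the hand-written stencil", {
  topo <- female_10dof_topology()
  # distinct values so misplaced terms cannot cancel
  k <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  cc <- c(31, 37, 41, 43, 47, 53, 59, 61, 67, 71)
  params <- parameter_set(topo$segments$mass_kg, k, cc)
  sys <- assemble_system(topo, params)
  hand <- female_matrices_by_hand(k, cc)
  # base coupling contributes only to the diagonal of the forced row
  expect_identical(sys$K, hand$K)
  expect_identical(sys$C, hand$C)
  expect_equal(sys$K[2, 2], k[1] + k[2] + k[5] + k[8])
  expect_identical(sys$K[4, 5], 0)
  expect_identical(sys$base_k, 7)
})

test_that("assembled matrices satisfy structural invariants on random topologies", {
  withr::local_seed(421)
  for (rep in 1:100) {
    topo <- random_topology(sample(2:12, 1))
    sys <- assemble_system(topo, default_parameters(topo))
    expect_identical(sys$K, t(sys$K))
    expect_identical(sys$C, t(sys$C))
    rs <- rowSums(sys$K)
    expect_equal(rs[sys$base_row], sys$base_k, tolerance = 1e-12)
    expect_lt(max(abs(rs[-sys$base_row])), 1e-9 * sys$base_k)
    rsc <- rowSums(sys$C)
    expect_equal(rsc[sys$base_row], sys$base_c, tolerance = 1e-12)
    expect_lt(max(abs(rsc[-sys$base_row])), 1e-6 * max(sys$base_c, 1))
  }
})

test_that("grounded stiffness is positive definite; ungrounded has one rigid-body mode", {
  withr::local_seed(77)
  for (rep in 1:20) {
    topo <- random_topology(sample(2:10, 1))
    sys <- assemble_system(topo, default_parameters(topo))
    ev <- eigen(sys$K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # remove the ground connection: exactly one zero eigenvalue remains
    K0 <- sys$K
    K0[sys$base_row, sys$base_row] <- K0[sys$base_row, sys$base_row] - sys$base_k
    ev0 <- eigen(K0, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev0) < 1e-9 * max(ev0)), 1)
  }
})

test_that("parameter encoding is a 30-vector round trip for the female model", {
  topo <- female_10dof_topology()
  params <- female_truth(topo)
  v <- encode_parameters(params)
  expect_length(v, 30)
  expect_equal(unname(v[1:10]) * 54.01 / 54,
               c(6.91, 16.19, 10.80, 10.25, 2.87, 1.44, 0.62,
                 2.87, 1.44, 0.62), tolerance = 1e-12)
  back <- decode_parameters(v, topo)
  expect_equal(back$masses, params$masses)
  expect_equal(back$stiffness, params$stiffness)
  expect_equal(back$damping, params$damping)
  expect_error(decode_parameters(v[-1], topo), "length")
})

test_that("constraint projection enforces symmetry, bounds and the mass sum", {
  topo <- female_10dof_topology()
  # proportional mass scaling
  p <- project_constraints(parameter_set(rep(1, 10), rep(1000, 10),
                                         rep(1000, 10)), topo)
  expect_equal(p$masses, rep(5.4, 10))
  # symmetry averaging before rescaling
  m <- c(10, 10, 10, 10, 3, 1, 1, 5, 1, 1)
  p2 <- project_constraints(parameter_set(m, rep(1000, 10), rep(1000, 10)),
                            topo)
  expect_equal(p2$masses[5], p2$masses[8])
  expect_equal(p2$masses[5] / p2$masses[1], 4 / 10)  # averaged to 4 vs 10
  # bound clipping
  k <- rep(1000, 10); k[3] <- 5e5
  p3 <- project_constraints(parameter_set(rep(5.4, 10), k, rep(100, 10)), topo)
  expect_equal(p3$stiffness[3], 3e5)
  expect_equal(p3$damping, rep(500, 10))
  expect_error(project_constraints(c(rep(NA_real_, 30)), topo), "finite")
})

test_that("constraint projection is idempotent and exact on random vectors", {
  topo <- female_10dof_topology()
  withr::local_seed(99)
  for (rep in 1:50) {
    v <- c(runif(10, 0.01, 120), runif(10, 1, 1e6), runif(10, 1, 1e5))
    p1 <- project_constraints(v, topo)
    expect_true(is_constrained(p1, topo))
    expect_equal(sum(p1$masses), 54, tolerance = 1e-12)
    p2 <- project_constraints(p1, topo)
    expect_equal(p2$masses, p1$masses, tolerance = 1e-12)
    expect_equal(p2$stiffness, p1$stiffness, tolerance = 1e-12)
    expect_equal(p2$damping, p1$damping, tolerance = 1e-12)
  }
})

test_that("topology validation rejects malformed models", {
  seg <- tibble::tibble(index = 1:2, name = c("a", "b"), mass_kg = c(1, 1))
  expect_error(model_topology(
    seg,
    tibble::tibble(id = 1:2, from = c(1L, 2L), to = c(0L, 0L),
                   stiffness = 1, damping = 1), 2), "BASE")
  expect_error(model_topology(
    seg,
    tibble::tibble(id = 1L, from = 2L, to = 0L, stiffness = 1, damping = 1),
    2), "not connected")
  expect_error(model_topology(
    tibble::tibble(index = 1:2, name = c("a", "b"), mass_kg = c(1, -1)),
    tibble::tibble(id = 1:2, from = c(1L, 2L), to = c(2L, 0L),
                   stiffness = 1, damping = 1), 2), "mass")
})
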