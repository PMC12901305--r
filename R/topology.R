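#' Construct a lumped-parameter model topology
#'
#' A topology describes the structural blueprint of an n-DOF
#' mass-spring-damper body model: the rigid segments, the spring-damper
#' couplings between adjacent segments, and the single attachment to the
#' vibrating base (the seat). Segment masses and coupling
#' stiffness/damping stored here act as the model's default parameter
#' values; [default_parameters()] extracts them as a parameter set.
#'
#' @param segments A data frame with columns `index` (unique, contiguous
#'   1..n), `name`, and `mass_kg` (> 0).
#' @param couplings A data frame with columns `id` (unique, contiguous
#'   1..n_c), `from` (segment index), `to` (segment index, or 0 for the
#'   base), `stiffness` (N/m, > 0) and `damping` (N.s/m, >= 0). Exactly
#'   one coupling must have `to = 0`: the seat attachment.
#' @param total_mass Total supported body mass in kg; the mass-sum
#'   constraint used by [project_constraints()].
#' @param symmetry_pairs Optional list of integer pairs `c(i, j)` of
#'   segment/coupling indices constrained equal left/right (mass,
#'   stiffness and damping of pair members are averaged on projection).
#'
#' @return An object of class `vb_topology`.
#' @seealso [female_10dof_topology()]
#' @export
model_topology <- function(segments, couplings, total_mass,
                           symmetry_pairs = list()) {
  segments <- as_tibble(segments)
  couplings <- as_tibble(couplings)
  stopifnot(all(c("index", "name", "mass_kg") %in% names(segments)),
            all(c("id", "from", "to", "stiffness", "damping") %in% names(couplings)))
  topo <- structure(
    list(segments = segments, couplings = couplings,
         total_mass = total_mass, symmetry_pairs = symmetry_pairs),
    class = "vb_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  seg <- topo$segments
  cpl <- topo$couplings
  n <- nrow(seg)
  if (!identical(sort(seg$index), seq_len(n)))
    abort("segments$index must be unique and contiguous 1..n")
  if (any(seg$mass_kg <= 0))
    abort(paste0("non-positive mass for segment(s): ",
                 paste(seg$name[seg$mass_kg <= 0], collapse = ", ")))
  if (any(cpl$from == cpl$to))
    abort("coupling with from == to")
  base_ids <- cpl$id[cpl$to == 0L]
  if (length(base_ids) != 1L)
    abort(paste0("exactly one BASE coupling required, found ",
                 length(base_ids),
                 if (length(base_ids) > 1)
                   paste0(" (ids ", paste(base_ids, collapse = ", "), ")")))
  refs <- setdiff(c(cpl$from, cpl$to), 0L)
  if (!all(refs %in% seg$index))
    abort(paste0("coupling references undefined segment(s): ",
                 paste(setdiff(refs, seg$index), collapse = ", ")))
  if (any(cpl$stiffness <= 0)) abort("coupling stiffness must be > 0")
  if (any(cpl$damping < 0)) abort("coupling damping must be >= 0")
  # connectivity: every segment reachable once the base coupling grounds
  # the chain (no free-floating segment)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(cpl))) {
    i <- cpl$from[r]; j <- cpl$to[r]
    if (j == 0L) next
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  stack <- base_segment(topo)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  if (!all(seen))
    abort(paste0("segment(s) not connected to the base: ",
                 paste(seg$name[!seen], collapse = ", ")))
  invisible(topo)
}

#' Segment attached to the seat
#'
#' @param topology A `vb_topology`.
#' @return Integer index of the segment carrying the base coupling.
#' @export
base_segment <- function(topology) {
  topology$couplings$from[topology$couplings$to == 0L]
}

#' The 10-DOF seated-female model topology
#'
#' Fixed topology of the ten-segment seated-female model: a vertical
#' chain head(1)-thorax(2)-abdomen(3)-pelvis(4)-seat through couplings
#' 1-4, with two three-segment arm branches hanging from the thorax:
#' left upper-arm(5)-forearm(6)-hand(7) through couplings 5-7 and right
#' upper-arm(8)-forearm(9)-hand(10) through couplings 8-10. The pelvis
#' is the base segment; vibration enters through coupling 4 (the
#' seat-body interface). Left/right arm segments and couplings are
#' symmetry-paired: (5,8), (6,9), (7,10).
#'
#' Default masses are the published optimized first-iteration segment
#' masses (sum 54.01 kg, consistent with the 54 kg total-mass
#' constraint). Default stiffness and damping sit at the midpoints of
#' the physiological bounds (100, 300000) N/m and (500, 4000) N.s/m;
#' they are illustrative placeholders, not a fitted parameter set.
#'
#' @return A `vb_topology` with 10 segments and 10 couplings.
#' @examples
#' topo <- female_10dof_topology()
#' base_segment(topo)  # 4: the pelvis
#' @export
female_10dof_topology <- function() {
  segments <- tibble(
    index = 1:10,
    name = c("head", "thorax", "abdomen", "pelvis",
             "upper_arm_L", "forearm_L", "hand_L",
             "upper_arm_R", "forearm_R", "hand_R"),
    mass_kg = c(6.91, 16.19, 10.80, 10.25,
                2.87, 1.44, 0.62,
                2.87, 1.44, 0.62))
  couplings <- tibble(
    id = 1:10,
    from = c(1L, 2L, 3L, 4L, 2L, 5L, 6L, 2L, 8L, 9L),
    to   = c(2L, 3L, 4L, 0L, 5L, 6L, 7L, 8L, 9L, 10L),
    stiffness = rep(150050, 10),
    damping = rep(2250, 10))
  model_topology(segments, couplings, total_mass = 54,
                 symmetry_pairs = list(c(5L, 8L), c(6L, 9L), c(7L, 10L)))
}

#' @export
print.vb_topology <- function(x, ...) {
  cat("<vb_topology> ", nrow(x$segments), " segments, ",
      nrow(x$couplings), " couplings, base segment ",
      base_segment(x), " (",
      x$segments$name[x$segments$index == base_segment(x)],
      "), total mass ", x$total_mass, " kg\n", sep = "")
  print(x$segments, ...)
  invisible(x)
}
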