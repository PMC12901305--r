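#' Read and write model configuration files
#'
#' Model topology and parameters travel as a YAML (or JSON — YAML is a
#' superset) document with keys `total_mass`, `segments` (list of
#' `name`, `mass`), `couplings` (list of `from`, `to`, `k`, `c`, with
#' `to: base` marking the seat attachment), and optionally
#' `symmetry_pairs` (list of two-element index pairs). Validation
#' errors name the offending field.
#'
#' @param path File path.
#' @return `read_model_config()`: list with `topology` (`vb_topology`)
#'   and `params` (`vb_params`). `write_model_config()`: `path`,
#'   invisibly.
#' @examples
#' cfg <- read_model_config(
#'   system.file("extdata", "female_10dof_synthetic.yaml",
#'               package = "vibrobody"))
#' cfg$topology
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    abort(paste0("parse error in ", path, ": ",
                                 conditionMessage(e))))
  for (key in c("segments", "couplings", "total_mass"))
    if (is.null(doc[[key]])) abort(paste0("missing config key: ", key))
  seg <- purrr::imap_dfr(doc$segments, function(s, i) {
    if (is.null(s$name) || is.null(s$mass))
      abort(paste0("segments[", i, "]: need name and mass"))
    tibble(index = i, name = s$name, mass_kg = as.numeric(s$mass))
  })
  cpl <- purrr::imap_dfr(doc$couplings, function(cp, i) {
    for (key in c("from", "to", "k", "c"))
      if (is.null(cp[[key]]))
        abort(paste0("couplings[", i, "]: missing field '", key, "'"))
    to <- if (identical(cp$to, "base")) 0L else as.integer(cp$to)
    tibble(id = i, from = as.integer(cp$from), to = to,
           stiffness = as.numeric(cp$k), damping = as.numeric(cp$c))
  })
  pairs <- purrr::map(doc$symmetry_pairs %||% list(), as.integer)
  topo <- model_topology(seg, cpl, total_mass = as.numeric(doc$total_mass),
                         symmetry_pairs = pairs)
  list(topology = topo, params = default_parameters(topo))
}

#' @rdname read_model_config
#' @param topology A `vb_topology`.
#' @param params A `vb_params` written into the segment/coupling
#'   entries (defaults to the topology's stored values).
#' @export
write_model_config <- function(topology, path,
                               params = default_parameters(topology)) {
  doc <- list(
    total_mass = topology$total_mass,
    segments = purrr::map(seq_len(nrow(topology$segments)), function(i)
      list(name = topology$segments$name[i],
           mass = params$masses[i])),
    couplings = purrr::map(seq_len(nrow(topology$couplings)), function(i)
      list(from = topology$couplings$from[i],
           to = if (topology$couplings$to[i] == 0L) "base"
                else topology$couplings$to[i],
           k = params$stiffness[i], c = params$damping[i])),
    symmetry_pairs = purrr::map(topology$symmetry_pairs, as.integer))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

curve_csv_cols <- c("frequency_hz", "stht_mag", "stht_phase_rad",
                    "dpmi_mag", "dpmi_phase_rad", "am_mag", "am_phase_rad")

#' Read and write biodynamic curve and target CSV files
#'
#' Full curves are stored losslessly as magnitude/phase columns
#' (`frequency_hz`, `stht_mag`, `stht_phase_rad`, `dpmi_mag`,
#' `dpmi_phase_rad`, `am_mag`, `am_phase_rad`); calibration targets
#' carry magnitudes only (`frequency_hz`, `stht_mag`, `dpmi_mag`,
#' `am_mag`). Readers validate the header and require a strictly
#' increasing frequency column.
#'
#' @param curves A `vb_curves` tibble.
#' @param path File path.
#' @return Readers return the tibble; writers return `path` invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  readr::write_csv(tibble(
    frequency_hz = curves$frequency_hz,
    stht_mag = Mod(curves$stht), stht_phase_rad = Arg(curves$stht),
    dpmi_mag = Mod(curves$dpmi), dpmi_phase_rad = Arg(curves$dpmi),
    am_mag = Mod(curves$am), am_phase_rad = Arg(curves$am)), path)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  d <- read_checked_csv(path, curve_csv_cols)
  out <- tibble(
    frequency_hz = d$frequency_hz,
    stht = complex(modulus = d$stht_mag, argument = d$stht_phase_rad),
    dpmi = complex(modulus = d$dpmi_mag, argument = d$dpmi_phase_rad),
    am = complex(modulus = d$am_mag, argument = d$am_phase_rad))
  class(out) <- c("vb_curves", class(out))
  out
}

#' @rdname write_curves_csv
#' @param targets A target magnitude table (e.g. from
#'   [generate_targets()]).
#' @export
write_targets_csv <- function(targets, path) {
  readr::write_csv(targets[c("frequency_hz", "stht_mag",
                             "dpmi_mag", "am_mag")], path)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_targets_csv <- function(path) {
  out <- read_checked_csv(path,
                          c("frequency_hz", "stht_mag", "dpmi_mag", "am_mag"))
  class(out) <- c("vb_targets", class(out))
  out
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  if (any(diff(d$frequency_hz) <= 0))
    abort("frequency_hz must be strictly increasing")
  d[required]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
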