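#' @section Spectral pipeline:
#' For each snapshot the pipeline assembles the core Hessian (internal
#' springs plus the embedding terms), the dipole gradient (point charges
#' plus induced-dipole response) and the bond-model polarizability gradient;
#' mass-weights and (optionally) projects the Hessian; filters modes below
#' the PHVA cutoff; transforms the property gradients to normal coordinates;
#' converts to SI; and broadens onto a common grid. Snapshot spectra are
#' averaged pointwise.
#' @name pe-pipeline
#' @keywords internal
NULL

#' Assemble the property dump of one snapshot
#'
#' Computes the total core Hessian (internal springs + electrostatics +
#' induction + Lennard-Jones), the analytic dipole gradient and the toy
#' polarizability gradient for an embedded fixture.
#'
#' @param fixture A [make_fixture()] result (or list with `core`, `sites`,
#'   `bonds`).
#' @param tol Induced-dipole solver tolerance.
#' @return A `property_dump` list as produced by [read_property_dump()].
#' @export
snapshot_properties <- function(fixture, tol = 1e-10) {
  core <- fixture$core; sites <- fixture$sites
  H <- core_spring_terms(core, fixture$bonds)$hessian +
    pe_hessian(core, sites, tol = tol)
  dg <- toy_dipole_surface(core, sites, tol = tol)$gradient
  pg <- toy_polarizability_surface(core, fixture$bonds)$gradient
  structure(list(element = core$element, position = core$position,
                 masses = core$mass, hessian = (H + t(H)) / 2,
                 dipole_gradient = dg, polarizability_gradient = pg),
            class = "property_dump")
}

#' Normal modes and per-mode intensities from a property dump
#'
#' @param dump A `property_dump` (internal or read from disk).
#' @param project Project translations/rotations out of the mass-weighted
#'   Hessian before diagonalizing.
#' @param cutoff PHVA low-frequency cutoff (cm^-1).
#' @param settings [raman_settings()] for the cross sections.
#' @return List with `modes` (filtered [normal_modes()]), `mu_q_si` (C^2
#'   kg^-1 per mode), `mu_q_d2a2amu`, `invariants_si` (data frame `a`, `b2`),
#'   `cross_sections`, and `stick` (per-mode summary data frame).
#' @export
mode_intensities <- function(dump, project = FALSE,
                             cutoff = pe_phva_cutoff(),
                             settings = raman_settings()) {
  Hmw <- mass_weight_hessian(dump$hessian, dump$masses)
  if (project) {
    Hmw <- project_translations_rotations(Hmw, dump$position, dump$masses)
  }
  modes <- normal_modes(Hmw, dump$masses, geometry = dump$position,
                        projected = project)
  modes <- filter_modes(modes, cutoff)
  uf <- pe_unit_factors()
  out <- list(modes = modes)
  if (!is.null(dump$dipole_gradient)) {
    dq <- gradient_to_normal_coordinates(dump$dipole_gradient, modes)
    mu_q_au <- ir_mode_strength(dq)                  # e^2 amu^-1
    out$mu_q_si <- mu_q_au * uf$mu_q_au_to_si
    out$mu_q_d2a2amu <- out$mu_q_si * uf$mu_q_si_to_d2a2amu
  }
  if (!is.null(dump$polarizability_gradient)) {
    aq <- gradient_to_normal_coordinates(dump$polarizability_gradient, modes)
    inv_au <- raman_invariants(aq)
    au_lin <- sqrt(uf$alpha_q_au_to_si)              # linear a.u. -> SI
    out$invariants_si <- data.frame(a = inv_au$a * au_lin,
                                    b2 = inv_au$b2 * au_lin^2)
    out$cross_sections <- raman_cross_section(out$invariants_si$a,
                                              out$invariants_si$b2,
                                              modes$wavenumbers, settings)
  }
  out$stick <- data.frame(
    wavenumber_cm1 = modes$wavenumbers,
    mu_q_si = if (is.null(out$mu_q_si)) NA else out$mu_q_si,
    raman_cross_section = if (is.null(out$cross_sections)) NA else
      out$cross_sections)
  out
}

#' Snapshot-averaged IR or Raman spectrum of a fixture ensemble
#'
#' @param snapshots List of fixtures (e.g. [make_snapshots()]) or of
#'   `property_dump` objects.
#' @param kind `"ir"` or `"raman"`.
#' @param hwhm Lineshape HWHM (cm^-1).
#' @param grid Common wavenumber grid (cm^-1).
#' @inheritParams mode_intensities
#' @return A [spectrum_grid()] averaged over the snapshots.
#' @export
ensemble_spectrum <- function(snapshots, kind = c("ir", "raman"),
                              hwhm = pe_default_hwhm(),
                              grid = pe_default_grid(),
                              project = FALSE, cutoff = pe_phva_cutoff(),
                              settings = raman_settings()) {
  kind <- match.arg(kind)
  per <- lapply(seq_along(snapshots), function(j) {
    snap <- snapshots[[j]]
    dump <- if (inherits(snap, "property_dump")) snap else
      snapshot_properties(snap)
    mi_ <- mode_intensities(dump, project = project, cutoff = cutoff,
                            settings = settings)
    if (kind == "ir") {
      ir_spectrum(mi_$modes$wavenumbers, mi_$mu_q_si, gamma = hwhm,
                  grid = grid, snapshot = j)
    } else {
      raman_spectrum(mi_$modes$wavenumbers, mi_$cross_sections,
                     gamma = hwhm, grid = grid, snapshot = j)
    }
  })
  average_spectra(per)
}
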