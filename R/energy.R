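#' Total classical embedding energy and its analytic derivatives
#'
#' Sums the electrostatic, induction and Lennard-Jones contributions, each
#' with the environment frozen and derivatives taken with respect to
#' core-atom coordinates only.
#'
#' @param core A [pe_core()] object.
#' @param sites A [pe_sites()] environment.
#' @param terms Character subset of `c("es", "ind", "lj")`.
#' @param tol Induced-dipole solver tolerance.
#' @return `pe_energy`: named list with the per-term energies and `total`
#'   (hartree).
#' @export
pe_energy <- function(core, sites, terms = c("es", "ind", "lj"),
                      tol = 1e-10) {
  out <- list(es = 0, ind = 0, lj = 0)
  if ("es" %in% terms) out$es <- as.numeric(electrostatic_energy(sites, core))
  if ("ind" %in% terms) {
    out$ind <- induction_report(sites, core, tol = tol,
                                derivatives = FALSE)$energy
  }
  if ("lj" %in% terms) out$lj <- lj_energy(core, sites, warn = FALSE)
  out$total <- out$es + out$ind + out$lj
  out
}

#' @rdname pe_energy
#' @param response Optional precomputed [assemble_response_matrix()] result
#'   (environment-only; reusable across core geometries).
#' @return `pe_gradient`: numeric vector of length 3 N_core
#'   (hartree / bohr).
#' @export
pe_gradient <- function(core, sites, terms = c("es", "ind", "lj"),
                        tol = 1e-10, response = NULL) {
  g <- numeric(3 * n_core_atoms(core))
  if ("es" %in% terms) g <- g + electrostatic_gradient(sites, core)
  if ("ind" %in% terms) {
    g <- g + induction_gradient(sites, core, tol = tol, response = response)
  }
  if ("lj" %in% terms) g <- g + lj_gradient(core, sites, warn = FALSE)
  g
}

#' @rdname pe_energy
#' @return `pe_hessian`: symmetric 3 N_core x 3 N_core matrix
#'   (hartree / bohr^2).
#' @export
pe_hessian <- function(core, sites, terms = c("es", "ind", "lj"),
                       tol = 1e-10, response = NULL) {
  N <- n_core_atoms(core)
  H <- matrix(0, 3 * N, 3 * N)
  if ("es" %in% terms) H <- H + electrostatic_hessian(sites, core)
  if ("ind" %in% terms) {
    H <- H + induction_hessian(sites, core, tol = tol, response = response)
  }
  if ("lj" %in% terms) H <- H + lj_hessian(core, sites, warn = FALSE)
  H
}
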