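#' @section Electrostatics:
#' The permanent multipoles of the environment interact with the point-charge
#' core through
#'   E_es = sum_s sum_{|a| <= K_s} (-1)^|a| / a!  M_s^[a]  sum_n Z_n T^[a](R_s, R_n)
#' where M_s^[a] are raw Cartesian multipole components (charge, dipole,
#' second moment) and T is the interaction tensor of [interaction_tensor],
#' differentiated at the nuclear position. The (-1)^|a| factor is fixed by the
#' Taylor expansion of a physical point-charge distribution: a finite dipole
#' (two opposite charges) reproduces the |a| = 1 term in the small-separation
#' limit. Because every summand involves exactly one nucleus, geometric
#' derivatives with respect to core coordinates simply raise the tensor order,
#' and the Hessian is block-diagonal over core atoms.
#' @name pe-electrostatics
#' @keywords internal
NULL

# packed symmetric order: xx, xy, xz, yy, yz, zz
QUAD_PAIRS <- cbind(i = c(1, 1, 1, 2, 2, 3), j = c(1, 2, 3, 2, 3, 3))
QUAD_WEIGHTS <- ifelse(QUAD_PAIRS[, "i"] == QUAD_PAIRS[, "j"], 0.5, 1)

# one pass over all site/atom pairs accumulating energy (split by multipole
# order), gradient and per-atom Hessian blocks up to `deriv` in {0,1,2}
es_accumulate <- function(sites, core, deriv) {
  S <- n_sites(sites); N <- n_core_atoms(core)
  e_by_order <- c(charge = 0, dipole = 0, quadrupole = 0)
  grad <- if (deriv >= 1) numeric(3 * N) else NULL
  hess <- if (deriv >= 2) matrix(0, 3 * N, 3 * N) else NULL
  E3 <- diag(3)
  for (s in seq_len(S)) {
    K <- sites$max_order[s]
    Rs <- sites$position[s, ]
    q <- sites$charge[s]; mu <- sites$dipole[s, ]; Q <- sites$quadrupole[s, ]
    for (n in seq_len(N)) {
      r <- core$position[n, ] - Rs
      Zn <- core$Z[n]
      tab <- coulomb_derivative_table(r, K + deriv)
      # multipole contraction with extra derivative indices (dx,dy,dz)
      contract <- function(dx, dy, dz) {
        v <- q * tab(dx, dy, dz)
        terms <- c(charge = v, dipole = 0, quadrupole = 0)
        if (K >= 1) {
          terms["dipole"] <-
            -(mu[1] * tab(dx + 1, dy, dz) +
              mu[2] * tab(dx, dy + 1, dz) +
              mu[3] * tab(dx, dy, dz + 1))
        }
        if (K >= 2) {
          acc <- 0
          for (p in 1:6) {
            a <- E3[QUAD_PAIRS[p, 1], ] + E3[QUAD_PAIRS[p, 2], ]
            acc <- acc + QUAD_WEIGHTS[p] * Q[p] *
              tab(dx + a[1], dy + a[2], dz + a[3])
          }
          terms["quadrupole"] <- acc
        }
        terms
      }
      e_by_order <- e_by_order + Zn * contract(0, 0, 0)
      if (deriv >= 1) {
        for (g in 1:3) {
          d <- E3[g, ]
          grad[3 * (n - 1) + g] <- grad[3 * (n - 1) + g] +
            Zn * sum(contract(d[1], d[2], d[3]))
        }
      }
      if (deriv >= 2) {
        for (g1 in 1:3) for (g2 in g1:3) {
          d <- E3[g1, ] + E3[g2, ]
          v <- Zn * sum(contract(d[1], d[2], d[3]))
          i <- 3 * (n - 1) + g1; j <- 3 * (n - 1) + g2
          hess[i, j] <- hess[i, j] + v
          if (i != j) hess[j, i] <- hess[j, i] + v
        }
      }
    }
  }
  list(energy = sum(e_by_order), by_order = e_by_order,
       gradient = grad, hessian = hess)
}

#' Electrostatic energy between environment multipoles and the core
#'
#' @param sites A [pe_sites()] environment.
#' @param core A [pe_core()] object.
#' @return Scalar energy (hartree) with attribute `by_order` giving the
#'   charge/dipole/quadrupole decomposition.
#' @export
electrostatic_energy <- function(sites, core) {
  r <- es_accumulate(sites, core, 0)
  structure(r$energy, by_order = r$by_order)
}

#' Analytic gradient of the electrostatic energy
#'
#' Derivatives are with respect to core-atom Cartesian coordinates; the
#' environment is frozen.
#'
#' @inheritParams electrostatic_energy
#' @return Numeric vector of length 3 * N_core (hartree / bohr).
#' @export
electrostatic_gradient <- function(sites, core) {
  es_accumulate(sites, core, 1)$gradient
}

#' Analytic Hessian of the electrostatic energy
#'
#' Block-diagonal over core atoms: each term of the energy involves a single
#' nucleus, so no nucleus-nucleus cross blocks arise.
#'
#' @inheritParams electrostatic_energy
#' @return Symmetric 3 N_core x 3 N_core matrix (hartree / bohr^2).
#' @export
electrostatic_hessian <- function(sites, core) {
  es_accumulate(sites, core, 2)$hessian
}

#' Full electrostatic report: energy, decomposition, gradient, Hessian
#'
#' @inheritParams electrostatic_energy
#' @return Object of class `es_report` with fields `energy`, `by_order`,
#'   `gradient`, `hessian`.
#' @export
electrostatics_report <- function(sites, core) {
  r <- es_accumulate(sites, core, 2)
  structure(r, class = "es_report")
}

#' @export
print.es_report <- function(x, ...) {
  cat("electrostatic energy (hartree):", format(x$energy, digits = 12), "\n")
  cat("  by order:", paste(names(x$by_order),
                           format(x$by_order, digits = 6), collapse = "  "), "\n")
  invisible(x)
}
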