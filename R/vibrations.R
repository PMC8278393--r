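#' @section Partial Hessian vibrational analysis:
#' The harmonic analysis works on the core-core block of the Hessian only
#' (PHVA): the environment is frozen and its masses never enter. The Hessian
#' is mass-weighted, H'_ij = H_ij / sqrt(m_i m_j), and diagonalized; each
#' eigenvalue lambda (hartree bohr^-2 amu^-1) maps to a wavenumber through a
#' single CODATA constant chain, with imaginary frequencies reported as
#' negative wavenumbers. Because the embedded core is not free, the six
#' translation/rotation modes are contaminated; projection is available as an
#' option, and a configurable low-frequency cutoff (preset 750 cm^-1,
#' matching the protocol the package is designed around) drops the
#' contaminated region.
#' @name pe-vibrations
#' @keywords internal
NULL

#' Mass-weight a Cartesian Hessian
#'
#' @param H Symmetric 3N x 3N matrix (hartree / bohr^2).
#' @param masses Length-N vector of atomic masses (amu).
#' @return Mass-weighted Hessian (hartree bohr^-2 amu^-1).
#' @export
mass_weight_hessian <- function(H, masses) {
  m3 <- rep(masses, each = 3)
  stopifnot(nrow(H) == length(m3), ncol(H) == length(m3))
  H / sqrt(outer(m3, m3))
}

#' Normal modes from a mass-weighted Hessian
#'
#' Eigenanalysis with deterministic ordering (wavenumbers ascending) and a
#' deterministic sign convention (largest-magnitude element of each
#' eigenvector positive). Negative wavenumbers encode imaginary frequencies.
#'
#' @param H_mw Symmetric mass-weighted Hessian (hartree bohr^-2 amu^-1).
#' @param masses Length-N vector (amu), stored for later normal-coordinate
#'   transformations.
#' @param geometry Optional N x 3 geometry (bohr), stored alongside.
#' @param projected,phva Bookkeeping flags recorded in the result.
#' @return Object of class `normal_modes`: list with `wavenumbers` (cm^-1,
#'   ascending), `modes` (3N x N_modes, orthonormal in mass-weighted
#'   coordinates), `masses`, `geometry`, `projected`, `phva`.
#' @export
normal_modes <- function(H_mw, masses, geometry = NULL,
                         projected = FALSE, phva = TRUE) {
  if (max(abs(H_mw - t(H_mw))) > 1e-9 * max(1, max(abs(H_mw)))) {
    stop("mass-weighted Hessian is not symmetric")
  }
  eig <- eigen((H_mw + t(H_mw)) / 2, symmetric = TRUE)
  wn <- hessian_eigenvalue_to_wavenumber(eig$values)
  ord <- order(wn)
  wn <- wn[ord]
  L <- eig$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(L))) {
    imax <- which.max(abs(L[, k]))
    if (L[imax, k] < 0) L[, k] <- -L[, k]
  }
  structure(list(wavenumbers = wn, modes = L, masses = masses,
                 geometry = geometry, projected = projected, phva = phva),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("normal modes: %d (projected: %s)\n",
              length(x$wavenumbers), x$projected))
  cat("  wavenumbers (cm^-1):",
      paste(format(x$wavenumbers, digits = 6), collapse = " "), "\n")
  invisible(x)
}

# mass-weighted translation/rotation basis; drops near-null rotations for
# linear molecules (moment-of-inertia ratio < 1e-8)
trans_rot_basis <- function(geometry, masses) {
  N <- length(masses)
  m3 <- rep(masses, each = 3)
  com <- colSums(geometry * masses) / sum(masses)
  X <- sweep(geometry, 2, com)
  vecs <- matrix(0, 3 * N, 6)
  for (a in 1:3) {
    v <- numeric(3 * N)
    v[seq(a, 3 * N, by = 3)] <- sqrt(masses)
    vecs[, a] <- v
  }
  E3 <- diag(3)
  for (a in 1:3) {
    d <- t(vapply(seq_len(N),
                  function(n) pracma_cross(X[n, ], E3[a, ]),
                  numeric(3)))
    vecs[, 3 + a] <- as.vector(t(d * sqrt(masses)))
  }
  # orthonormalize, dropping numerically null vectors (linear molecules)
  qrd <- qr(vecs)
  keep <- abs(diag(qr.R(qrd))) > 1e-8 * max(1, max(abs(vecs)))
  qr.Q(qrd)[, which(keep), drop = FALSE]
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project translations and rotations out of a mass-weighted Hessian
#'
#' Builds the six (five for linear geometries) mass-weighted rigid-body
#' vectors, orthonormalizes them, and returns P H P with P the complementary
#' projector.
#'
#' @inheritParams normal_modes
#' @param geometry N x 3 matrix (bohr).
#' @return Projected mass-weighted Hessian.
#' @export
project_translations_rotations <- function(H_mw, geometry, masses) {
  B <- trans_rot_basis(geometry, masses)
  P <- diag(nrow(H_mw)) - tcrossprod(B)
  P %*% H_mw %*% P
}

#' Drop modes below a wavenumber cutoff
#'
#' With the partial-Hessian treatment the low-frequency region is
#' contaminated by global translation/rotation; the conventional remedy is a
#' cutoff (preset [pe_phva_cutoff()] = 750 cm^-1) below which modes are
#' discarded.
#'
#' @param modes A [normal_modes()] object.
#' @param cutoff Wavenumber cutoff (cm^-1); modes with wavenumber >= cutoff
#'   are retained.
#' @return A `normal_modes` object with the retained modes and an attribute
#'   `n_dropped`.
#' @export
filter_modes <- function(modes, cutoff = pe_phva_cutoff()) {
  keep <- which(modes$wavenumbers >= cutoff)
  if (length(keep) == 0) {
    warning("mode filter at ", cutoff, " cm^-1 retains no modes")
  }
  out <- modes
  out$wavenumbers <- modes$wavenumbers[keep]
  out$modes <- modes$modes[, keep, drop = FALSE]
  attr(out, "n_dropped") <- length(modes$wavenumbers) - length(keep)
  out
}

#' Default PHVA low-frequency cutoff (cm^-1)
#' @export
pe_phva_cutoff <- function() 750

#' Transform Cartesian property gradients to normal coordinates
#'
#' dX/dQ_I = sum_i (dX/dx_i) L_iI / sqrt(m_i): columns of the Cartesian
#' gradient matrix are contracted with the mass-weighted modes.
#'
#' @param cartesian_gradient 3N x P matrix of property derivatives with
#'   respect to Cartesian coordinates.
#' @param modes A [normal_modes()] object.
#' @return N_modes x P matrix of derivatives with respect to mass-weighted
#'   normal coordinates (property units per bohr amu^1/2).
#' @export
gradient_to_normal_coordinates <- function(cartesian_gradient, modes) {
  cg <- as.matrix(cartesian_gradient)
  m3 <- rep(modes$masses, each = 3)
  stopifnot(nrow(cg) == length(m3))
  crossprod(modes$modes / sqrt(m3), cg)
}
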