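#' Environment sites of a PE potential
#'
#' Container for the classical environment: one row per site, each carrying a
#' position, fragment membership, permanent Cartesian multipoles up to
#' quadrupole, an optional dipole-dipole polarizability, a mutual exclusion
#' list, and optional Lennard-Jones parameters. All quantities are stored in
#' Hartree atomic units; quadrupoles and polarizabilities use the packed
#' component order xx, xy, xz, yy, yz, zz.
#'
#' @param position S x 3 numeric matrix (bohr).
#' @param fragment Integer vector of fragment ids (length S).
#' @param charge,dipole,quadrupole Permanent multipoles: length-S vector,
#'   S x 3 matrix, S x 6 matrix. Missing blocks default to zero.
#' @param max_order Integer vector, highest multipole order declared per site
#'   (0, 1 or 2). Defaults to 2 where a quadrupole block is given.
#' @param polarizability 3 x 3 x S array of symmetric site polarizabilities
#'   (bohr^3); an all-zero slice marks a non-polarizable site.
#' @param exclusions List (length S) of integer site indices whose classical
#'   interaction with the site is excluded; must be mutual and never contain
#'   the site itself (self-interaction is always excluded implicitly).
#' @param element Character vector of element labels.
#' @param lj_sigma,lj_epsilon Optional per-site LJ parameters (bohr, hartree);
#'   `NA` means the site carries no LJ interaction.
#' @return Object of class `pe_sites`.
#' @export
pe_sites <- function(position, fragment,
                     charge = NULL, dipole = NULL, quadrupole = NULL,
                     max_order = NULL, polarizability = NULL,
                     exclusions = NULL, element = NULL,
                     lj_sigma = NULL, lj_epsilon = NULL) {
  position <- unname(as.matrix(position))
  S <- nrow(position)
  stopifnot(ncol(position) == 3, length(fragment) == S)
  if (is.null(charge)) charge <- numeric(S)
  if (is.null(dipole)) dipole <- matrix(0, S, 3)
  if (is.null(quadrupole)) quadrupole <- matrix(0, S, 6)
  if (is.null(polarizability)) polarizability <- array(0, c(3, 3, S))
  if (is.null(exclusions)) exclusions <- rep(list(integer(0)), S)
  if (is.null(element)) element <- rep("X", S)
  if (is.null(lj_sigma)) lj_sigma <- rep(NA_real_, S)
  if (is.null(lj_epsilon)) lj_epsilon <- rep(NA_real_, S)
  if (is.null(max_order)) {
    max_order <- ifelse(rowSums(abs(as.matrix(quadrupole))) > 0, 2L,
                        ifelse(rowSums(abs(as.matrix(dipole))) > 0, 1L, 0L))
  }
  x <- structure(list(
    position = position, fragment = as.integer(fragment),
    charge = unname(as.numeric(charge)), dipole = unname(as.matrix(dipole)),
    quadrupole = unname(as.matrix(quadrupole)),
    max_order = unname(as.integer(max_order)),
    polarizability = polarizability,
    exclusions = lapply(exclusions, function(e) sort(as.integer(e))),
    element = as.character(element),
    lj_sigma = as.numeric(lj_sigma), lj_epsilon = as.numeric(lj_epsilon)
  ), class = "pe_sites")
  validate_pe_sites(x)
  x
}

validate_pe_sites <- function(x) {
  S <- n_sites(x)
  stopifnot(length(x$charge) == S, nrow(x$dipole) == S,
            nrow(x$quadrupole) == S, ncol(x$quadrupole) == 6,
            dim(x$polarizability)[3] == S || S == 0,
            length(x$exclusions) == S, length(x$element) == S)
  if (any(!x$max_order %in% 0:2)) {
    stop("multipole orders above quadrupole (K_s > 2) are not supported")
  }
  for (s in seq_len(S)) {
    a <- x$polarizability[, , s]
    if (max(abs(a - t(a))) > 1e-10 * max(1, max(abs(a)))) {
      stop("polarizability of site ", s, " is not symmetric")
    }
    if (any(a != 0) && min(eigen(a, symmetric = TRUE,
                                 only.values = TRUE)$values) < -1e-10) {
      stop("polarizability of site ", s, " has a negative eigenvalue")
    }
    ex <- x$exclusions[[s]]
    if (s %in% ex) stop("site ", s, " lists itself in its exclusion list")
    for (t in ex) {
      if (t < 1 || t > S || !(s %in% x$exclusions[[t]])) {
        stop("exclusion lists are not mutual for sites ", s, " and ", t)
      }
    }
  }
  invisible(x)
}

#' @export
print.pe_sites <- function(x, ...) {
  cat(sprintf("PE environment: %d sites in %d fragments\n",
              n_sites(x), length(unique(x$fragment))))
  cat(sprintf("  polarizable sites: %d;  max multipole order: %s\n",
              sum(polarizable_mask(x)),
              if (n_sites(x)) max(x$max_order) else "-"))
  invisible(x)
}

#' Number of environment sites
#' @param x A `pe_sites` object.
#' @export
n_sites <- function(x) nrow(x$position)

polarizable_mask <- function(sites) {
  apply(sites$polarizability, 3, function(a) any(a != 0))
}

#' Subset whole fragments of a `pe_sites` object
#'
#' Keeps the fragments listed, remapping exclusion indices. Fragments are
#' never split.
#'
#' @param sites A `pe_sites` object.
#' @param fragments Integer fragment ids to retain.
#' @return A `pe_sites` object.
#' @export
subset_fragments <- function(sites, fragments) {
  keep <- which(sites$fragment %in% fragments)
  map <- integer(n_sites(sites)); map[keep] <- seq_along(keep)
  pe_sites(
    position = sites$position[keep, , drop = FALSE],
    fragment = sites$fragment[keep],
    charge = sites$charge[keep],
    dipole = sites$dipole[keep, , drop = FALSE],
    quadrupole = sites$quadrupole[keep, , drop = FALSE],
    max_order = sites$max_order[keep],
    polarizability = sites$polarizability[, , keep, drop = FALSE],
    exclusions = lapply(sites$exclusions[keep],
                        function(e) map[e[e %in% keep]]),
    element = sites$element[keep],
    lj_sigma = sites$lj_sigma[keep], lj_epsilon = sites$lj_epsilon[keep]
  )
}

#' Core (quantum-region proxy) atoms
#'
#' The embedded molecule is represented classically by point-charge nuclei
#' with masses and optional Lennard-Jones parameters.
#'
#' @param position N x 3 numeric matrix (bohr).
#' @param Z Positive nuclear charges (e).
#' @param mass Positive masses (amu).
#' @param element Character labels.
#' @param lj_sigma,lj_epsilon LJ parameters (bohr, hartree), `>= 0` or `NA`.
#' @return Object of class `pe_core`.
#' @export
pe_core <- function(position, Z, mass, element = NULL,
                    lj_sigma = NULL, lj_epsilon = NULL) {
  position <- unname(as.matrix(position))
  N <- nrow(position)
  stopifnot(ncol(position) == 3, length(Z) == N, length(mass) == N)
  if (any(Z <= 0)) stop("nuclear charges must be positive")
  if (any(mass <= 0)) stop("masses must be positive")
  if (is.null(element)) element <- rep("X", N)
  if (is.null(lj_sigma)) lj_sigma <- rep(NA_real_, N)
  if (is.null(lj_epsilon)) lj_epsilon <- rep(NA_real_, N)
  if (any(stats::na.omit(c(lj_sigma, lj_epsilon)) < 0)) {
    stop("LJ parameters must be non-negative")
  }
  structure(list(position = position, Z = as.numeric(Z),
                 mass = as.numeric(mass), element = as.character(element),
                 lj_sigma = as.numeric(lj_sigma),
                 lj_epsilon = as.numeric(lj_epsilon)),
            class = "pe_core")
}

#' @export
print.pe_core <- function(x, ...) {
  cat(sprintf("PE core: %d point-charge atoms (%s)\n",
              n_core_atoms(x), paste(x$element, collapse = " ")))
  invisible(x)
}

#' Number of core atoms
#' @param x A `pe_core` object.
#' @export
n_core_atoms <- function(x) nrow(x$position)
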