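#' @section Induction:
#' Environment polarization is modeled by induced point dipoles on the
#' polarizable sites. Stacking site dipoles into a 3S vector, the classical
#' linear-response matrix A has inverse site polarizabilities on its diagonal
#' 3x3 blocks and minus the dipole-dipole interaction tensor on off-diagonal
#' blocks of non-excluded pairs. The induced dipoles solve A mu = F, with F
#' the electric field at each site from the core nuclei and from permanent
#' multipoles of non-excluded (foreign-fragment) sites; the induction energy
#' is E_ind = -1/2 mu . F, variational in mu. Geometric derivatives with
#' respect to core coordinates enter only through the nuclear field: the
#' permanent-multipole field does not depend on core positions.
#' @name pe-induction
#' @keywords internal
NULL

#' Assemble the classical linear-response matrix
#'
#' @param sites A [pe_sites()] environment.
#' @return Object of class `pe_response`: list with the dense symmetric
#'   matrix `A` (3S_pol x 3S_pol), the indices `pol_sites` of polarizable
#'   sites, and the per-site polarizabilities used for preconditioning.
#'   Assembly fails if a site polarizability is singular or the assembled
#'   matrix is not positive definite.
#' @export
assemble_response_matrix <- function(sites) {
  pol <- which(polarizable_mask(sites))
  P <- length(pol)
  A <- matrix(0, 3 * P, 3 * P)
  alphas <- vector("list", P)
  for (a in seq_len(P)) {
    s <- pol[a]
    as_ <- sites$polarizability[, , s]
    inv <- tryCatch(solve(as_), error = function(e) {
      stop("polarizability of site ", s, " is singular")
    })
    alphas[[a]] <- as_
    A[3 * a - 2:0, 3 * a - 2:0] <- (inv + t(inv)) / 2
  }
  if (P > 1) {
    for (a in seq_len(P - 1)) for (b in (a + 1):P) {
      s <- pol[a]; t <- pol[b]
      if (t %in% sites$exclusions[[s]]) next
      blk <- -tensor_block_matrix2(sites$position[t, ] - sites$position[s, ])
      A[3 * a - 2:0, 3 * b - 2:0] <- blk
      A[3 * b - 2:0, 3 * a - 2:0] <- blk
    }
  }
  if (P > 0) {
    ok <- tryCatch({ chol(A); TRUE }, error = function(e) FALSE)
    if (!ok) stop("response matrix is not positive definite; ",
                  "polarizable sites are too close or polarizabilities too large")
  }
  structure(list(A = A, pol_sites = pol, alphas = alphas),
            class = "pe_response")
}

#' @export
print.pe_response <- function(x, ...) {
  cat(sprintf("classical response matrix: %d polarizable sites (%d x %d)\n",
              length(x$pol_sites), nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' Static electric field at the polarizable sites
#'
#' Sums the field from all core nuclei and from the permanent multipoles of
#' all non-excluded environment sites (a site never sees its own fragment).
#'
#' @param sites A [pe_sites()] environment.
#' @param core A [pe_core()] object.
#' @return Object of class `field_vector`: numeric vector of length
#'   3 * S_pol (atomic units), with attributes `nuclear` and `multipole`
#'   holding the two contributions and `pol_sites` the site indices.
#' @export
total_site_field <- function(sites, core) {
  pol <- which(polarizable_mask(sites))
  P <- length(pol)
  Fn <- numeric(3 * P); Fm <- numeric(3 * P)
  E3 <- diag(3)
  for (a in seq_len(P)) {
    s <- pol[a]
    Rs <- sites$position[s, ]
    for (n in seq_len(n_core_atoms(core))) {
      tab <- coulomb_derivative_table(Rs - core$position[n, ], 1)
      for (j in 1:3) {
        d <- E3[j, ]
        Fn[3 * (a - 1) + j] <- Fn[3 * (a - 1) + j] -
          core$Z[n] * tab(d[1], d[2], d[3])
      }
    }
    for (t in seq_len(n_sites(sites))) {
      if (t == s || t %in% sites$exclusions[[s]]) next
      K <- sites$max_order[t]
      tab <- coulomb_derivative_table(Rs - sites$position[t, ], K + 1)
      q <- sites$charge[t]; mu <- sites$dipole[t, ]; Q <- sites$quadrupole[t, ]
      for (j in 1:3) {
        d <- E3[j, ]
        v <- q * tab(d[1], d[2], d[3])
        if (K >= 1) {
          v <- v - (mu[1] * tab(d[1] + 1, d[2], d[3]) +
                    mu[2] * tab(d[1], d[2] + 1, d[3]) +
                    mu[3] * tab(d[1], d[2], d[3] + 1))
        }
        if (K >= 2) {
          for (p in 1:6) {
            a2 <- E3[QUAD_PAIRS[p, 1], ] + E3[QUAD_PAIRS[p, 2], ] + d
            v <- v + QUAD_WEIGHTS[p] * Q[p] * tab(a2[1], a2[2], a2[3])
          }
        }
        Fm[3 * (a - 1) + j] <- Fm[3 * (a - 1) + j] - v
      }
    }
  }
  structure(Fn + Fm, nuclear = Fn, multipole = Fm, pol_sites = pol,
            class = "field_vector")
}

# preconditioned conjugate gradient; preconditioner applies the site
# polarizabilities (block Jacobi, i.e. the inverse of A's diagonal blocks)
pcg_solve <- function(A, b, alphas, tol = 1e-10, max_iter = 10000) {
  n <- length(b)
  if (n == 0) return(numeric(0))
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(numeric(n))
  apply_prec <- function(r) {
    z <- numeric(n)
    for (a in seq_along(alphas)) {
      i <- 3 * a - 2:0
      z[i] <- alphas[[a]] %*% r[i]
    }
    z
  }
  x <- numeric(n)
  r <- b
  z <- apply_prec(r)
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r * r)) / bnorm
    hist <- c(hist, res)
    if (res <= tol) {
      return(structure(x, residual = res, iterations = it))
    }
    z <- apply_prec(r)
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("induced-dipole solver did not converge in ", max_iter,
       " iterations; residual history tail: ",
       paste(format(utils::tail(hist, 3), digits = 3), collapse = ", "))
}

#' Solve for the induced dipoles
#'
#' Preconditioned conjugate-gradient solution of A mu = F with a block-Jacobi
#' (site-polarizability) preconditioner. Bitwise reproducible for fixed
#' inputs.
#'
#' @param response A [assemble_response_matrix()] result.
#' @param field A [total_site_field()] result (or numeric vector of matching
#'   length).
#' @param tol Relative residual tolerance (default 1e-10).
#' @param max_iter Iteration cap.
#' @return Object of class `induced_moments`: stacked site dipoles (e bohr)
#'   with attributes `residual` and `iterations`.
#' @export
solve_induced_moments <- function(response, field, tol = 1e-10,
                                  max_iter = 10000) {
  mu <- pcg_solve(response$A, as.numeric(field), response$alphas,
                  tol = tol, max_iter = max_iter)
  class(mu) <- "induced_moments"
  mu
}

#' Induction energy from induced dipoles and the inducing field
#'
#' E_ind = -1/2 mu . F at the solution of the response equations; always
#' non-positive for a positive-definite response matrix.
#'
#' @param moments An [solve_induced_moments()] result.
#' @param field The field vector the moments were solved against.
#' @return Scalar energy (hartree).
#' @export
induction_energy <- function(moments, field) {
  -0.5 * sum(as.numeric(moments) * as.numeric(field))
}

#' Geometric derivatives of the nuclear electrostatic potential
#'
#' Derivatives of V^\[alpha\](R_s) = sum_n Z_n d^alpha(1/|R_s - R_n|) with
#' respect to core-atom coordinates. The analogous derivative of the
#' permanent-multipole potential vanishes identically (it does not depend on
#' core positions).
#'
#' @param core A [pe_core()] object.
#' @param site_position 3-vector R_s (bohr).
#' @param alpha A [mi()] multi-index (the potential-derivative order).
#' @param d_order 1 or 2: first or second geometric derivative.
#' @return For `d_order = 1`, a vector of length 3 N_core; for `d_order = 2`,
#'   a 3 N_core x 3 N_core matrix, block-diagonal over atoms.
#' @export
nuclear_potential_derivatives <- function(core, site_position, alpha,
                                          d_order = 1) {
  stopifnot(d_order %in% 1:2)
  N <- n_core_atoms(core)
  E3 <- diag(3)
  a0 <- unclass(alpha)
  if (d_order == 1) {
    out <- numeric(3 * N)
    for (n in seq_len(N)) {
      tab <- coulomb_derivative_table(site_position - core$position[n, ],
                                      sum(a0) + 1)
      for (j in 1:3) {
        d <- a0 + E3[j, ]
        out[3 * (n - 1) + j] <- -core$Z[n] * tab(d[1], d[2], d[3])
      }
    }
    out
  } else {
    out <- matrix(0, 3 * N, 3 * N)
    for (n in seq_len(N)) {
      tab <- coulomb_derivative_table(site_position - core$position[n, ],
                                      sum(a0) + 2)
      for (j in 1:3) for (k in j:3) {
        d <- a0 + E3[j, ] + E3[k, ]
        v <- core$Z[n] * tab(d[1], d[2], d[3])
        out[3 * (n - 1) + j, 3 * (n - 1) + k] <- v
        out[3 * (n - 1) + k, 3 * (n - 1) + j] <- v
      }
    }
    out
  }
}

# d F / d g: 3 S_pol x 3 N_core matrix of nuclear-field derivatives
field_gradient_matrix <- function(sites, core, pol = which(polarizable_mask(sites))) {
  P <- length(pol); N <- n_core_atoms(core)
  G <- matrix(0, 3 * P, 3 * N)
  E3 <- diag(3)
  for (a in seq_len(P)) {
    Rs <- sites$position[pol[a], ]
    for (n in seq_len(N)) {
      tab <- coulomb_derivative_table(Rs - core$position[n, ], 2)
      for (j in 1:3) for (k in 1:3) {
        d <- E3[j, ] + E3[k, ]
        G[3 * (a - 1) + j, 3 * (n - 1) + k] <-
          core$Z[n] * tab(d[1], d[2], d[3])
      }
    }
  }
  G
}

# mu-contracted second derivative of the nuclear field, block-diagonal
field_hessian_contraction <- function(sites, core, mu,
                                      pol = which(polarizable_mask(sites))) {
  N <- n_core_atoms(core)
  out <- matrix(0, 3 * N, 3 * N)
  E3 <- diag(3)
  for (a in seq_along(pol)) {
    Rs <- sites$position[pol[a], ]
    mua <- mu[3 * a - 2:0]
    for (n in seq_len(N)) {
      tab <- coulomb_derivative_table(Rs - core$position[n, ], 3)
      for (k in 1:3) for (l in k:3) {
        v <- 0
        for (j in 1:3) {
          d <- E3[j, ] + E3[k, ] + E3[l, ]
          # d2 F_j / d R_nk d R_nl = -Z_n T^(j+k+l)
          v <- v - mua[j] * core$Z[n] * tab(d[1], d[2], d[3])
        }
        i1 <- 3 * (n - 1) + k; i2 <- 3 * (n - 1) + l
        out[i1, i2] <- out[i1, i2] + v
        if (i1 != i2) out[i2, i1] <- out[i2, i1] + v
      }
    }
  }
  out
}

#' Analytic gradient of the induction energy
#'
#' Variational shortcut: at the solution of the response equations,
#' dE_ind/dg = -mu . dF/dg, with only the nuclear field depending on core
#' coordinates.
#'
#' @inheritParams total_site_field
#' @param tol Solver tolerance passed to [solve_induced_moments()].
#' @param response Optional precomputed [assemble_response_matrix()] result;
#'   the response matrix depends only on the environment, so callers
#'   evaluating many core geometries can reuse it.
#' @return Numeric vector of length 3 N_core (hartree / bohr).
#' @export
induction_gradient <- function(sites, core, tol = 1e-10, response = NULL) {
  resp <- if (is.null(response)) assemble_response_matrix(sites) else response
  if (length(resp$pol_sites) == 0) return(numeric(3 * n_core_atoms(core)))
  field <- total_site_field(sites, core)
  mu <- solve_induced_moments(resp, field, tol = tol)
  G <- field_gradient_matrix(sites, core, resp$pol_sites)
  -as.vector(crossprod(G, as.numeric(mu)))
}

#' Analytic Hessian of the induction energy
#'
#' d2 E_ind / dg1 dg2 = -(dF/dg1)' B (dF/dg2) - mu . d2F/dg1 dg2, where the
#' response-matrix inverse B is applied through 3 N_core auxiliary solves.
#' The first term is a negative-semidefinite quadratic form.
#'
#' @inheritParams induction_gradient
#' @return Symmetric 3 N_core x 3 N_core matrix (hartree / bohr^2).
#' @export
induction_hessian <- function(sites, core, tol = 1e-10, response = NULL) {
  resp <- if (is.null(response)) assemble_response_matrix(sites) else response
  N <- n_core_atoms(core)
  if (length(resp$pol_sites) == 0) return(matrix(0, 3 * N, 3 * N))
  field <- total_site_field(sites, core)
  mu <- solve_induced_moments(resp, field, tol = tol)
  G <- field_gradient_matrix(sites, core, resp$pol_sites)
  X <- matrix(0, nrow(G), ncol(G))
  for (j in seq_len(ncol(G))) {
    X[, j] <- pcg_solve(resp$A, G[, j], resp$alphas, tol = tol)
  }
  H <- -crossprod(G, X) -
    field_hessian_contraction(sites, core, as.numeric(mu), resp$pol_sites)
  (H + t(H)) / 2
}

#' Full induction report
#'
#' @inheritParams induction_gradient
#' @param derivatives If `TRUE`, include gradient and Hessian.
#' @return Object of class `induction_report` with fields `energy`, `moments`,
#'   `field`, and optionally `gradient` and `hessian`.
#' @export
induction_report <- function(sites, core, tol = 1e-10, derivatives = TRUE) {
  resp <- assemble_response_matrix(sites)
  N <- n_core_atoms(core)
  if (length(resp$pol_sites) == 0) {
    out <- list(energy = 0, moments = numeric(0), field = numeric(0),
                gradient = numeric(3 * N), hessian = matrix(0, 3 * N, 3 * N))
    return(structure(out, class = "induction_report"))
  }
  field <- total_site_field(sites, core)
  mu <- solve_induced_moments(resp, field, tol = tol)
  out <- list(energy = induction_energy(mu, field), moments = mu,
              field = field)
  if (derivatives) {
    G <- field_gradient_matrix(sites, core, resp$pol_sites)
    out$gradient <- -as.vector(crossprod(G, as.numeric(mu)))
    X <- matrix(0, nrow(G), ncol(G))
    for (j in seq_len(ncol(G))) {
      X[, j] <- pcg_solve(resp$A, G[, j], resp$alphas, tol = tol)
    }
    H <- -crossprod(G, X) -
      field_hessian_contraction(sites, core, as.numeric(mu), resp$pol_sites)
    out$hessian <- (H + t(H)) / 2
  }
  structure(out, class = "induction_report")
}

#' @export
print.induction_report <- function(x, ...) {
  cat("induction energy (hartree):", format(x$energy, digits = 12), "\n")
  invisible(x)
}
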