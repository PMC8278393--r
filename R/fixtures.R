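#' @section Synthetic fixtures:
#' Deterministic toy embedded systems for exercising every pipeline stage
#' without external data: a point-charge core molecule (chain geometry,
#' harmonic pair springs as its internal force field) surrounded by
#' water-like three-site fragments carrying charges, small site dipoles and
#' quadrupoles, and slightly anisotropic polarizabilities. Fragments are
#' placed on a shell around the core with a minimum site-core separation so
#' no interaction is near its singularity. All randomness flows through an
#' explicit seed and the global RNG state is restored afterwards.
#' @name pe-fixtures
#' @keywords internal
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

element_mass <- function(el) {
  tbl <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, X = 10.0)
  m <- tbl[el]
  m[is.na(m)] <- 10.0
  unname(m)
}

# water-like fragment template in its local frame (bohr, a.u. throughout)
water_like_template <- function() {
  pos <- rbind(O  = c(0, 0, 0),
               H1 = c(1.43, 0, 1.11),
               H2 = c(-1.43, 0, 1.11))
  list(
    position = pos,
    element = c("O", "H", "H"),
    charge = c(-0.670, 0.335, 0.335),
    dipole = rbind(c(0, 0, 0.10), c(0.02, 0, 0.02), c(-0.02, 0, 0.02)),
    quadrupole = rbind(c(-0.30, 0.01, 0.00, -0.25, 0.00, -0.20),
                       c(0.05, 0.00, 0.01, 0.04, 0.00, 0.05),
                       c(0.05, 0.00, -0.01, 0.04, 0.00, 0.05)),
    polarizability = list(diag(c(6.0, 5.5, 5.6)), diag(3) * 2.0,
                          diag(3) * 2.0),
    lj_sigma_ang = c(3.166, 0, 0),
    lj_eps_kjmol = c(0.650, 0, 0)
  )
}

#' Specification of a synthetic embedded fixture
#'
#' @param n_fragments Number of water-like environment fragments.
#' @param n_core_atoms Number of core point-charge atoms (2 to 10).
#' @param shell Inner and outer placement radii for fragment centers (bohr).
#' @param min_core_dist Minimum allowed site-core distance (bohr).
#' @param seed Integer seed; every placement decision derives from it.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_fragments = 8, n_core_atoms = 3,
                         shell = c(7, 14), min_core_dist = 3,
                         seed = 1) {
  if (n_core_atoms < 1 || n_core_atoms > 10) {
    stop("n_core_atoms must be between 1 and 10")
  }
  structure(list(n_fragments = n_fragments, n_core_atoms = n_core_atoms,
                 shell = shell, min_core_dist = min_core_dist, seed = seed),
            class = "fixture_spec")
}

# zig-zag chain core with alternating charges/masses and OPLS-scale LJ
core_template <- function(n_atoms) {
  pos <- matrix(0, n_atoms, 3)
  for (k in seq_len(n_atoms)[-1]) {
    step <- if (k %% 2 == 0) c(1.68, 0, 1.18) else c(1.68, 0, -1.18)
    pos[k, ] <- pos[k - 1, ] + step
  }
  pos <- sweep(pos, 2, colMeans(pos))
  Zs <- rep(c(1.0, 0.8, 1.2), length.out = n_atoms)
  ms <- rep(c(12.011, 1.008, 15.999), length.out = n_atoms)
  el <- rep(c("C", "H", "O"), length.out = n_atoms)
  k_bohr <- pe_constants$bohr_per_angstrom
  core <- pe_core(position = pos, Z = Zs, mass = ms, element = el,
                  lj_sigma = rep(3.5 * k_bohr, n_atoms),
                  lj_epsilon = rep(0.3 * pe_constants$hartree_per_kjmol,
                                   n_atoms))
  # internal force field: harmonic springs on all pairs, stiff for chain
  # neighbours, soft otherwise, at the template distances
  bonds <- NULL
  if (n_atoms > 1) {
    for (a in seq_len(n_atoms - 1)) for (b in (a + 1):n_atoms) {
      r0 <- sqrt(sum((pos[a, ] - pos[b, ])^2))
      kk <- if (b - a == 1) 0.35 else 0.06
      bonds <- rbind(bonds, c(i = a, j = b, k = kk, r0 = r0))
    }
    bonds <- as.data.frame(bonds)
  }
  list(core = core, bonds = bonds)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed; uniform enough for fixtures
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_packed_sym <- function(packed, R) {
  m <- matrix(0, 3, 3)
  m[1, 1] <- packed[1]; m[1, 2] <- m[2, 1] <- packed[2]
  m[1, 3] <- m[3, 1] <- packed[3]; m[2, 2] <- packed[4]
  m[2, 3] <- m[3, 2] <- packed[5]; m[3, 3] <- packed[6]
  m2 <- R %*% m %*% t(R)
  c(m2[1, 1], m2[1, 2], m2[1, 3], m2[2, 2], m2[2, 3], m2[3, 3])
}

#' Build a deterministic embedded toy system
#'
#' @param spec A [fixture_spec()].
#' @return Object of class `pe_fixture`: list with `core` ([pe_core()]),
#'   `sites` ([pe_sites()]), `bonds` (the core's internal spring table) and
#'   `spec`.
#' @export
make_fixture <- function(spec) {
  ct <- core_template(spec$n_core_atoms)
  tmpl <- water_like_template()
  with_seed(spec$seed, {
    pos <- NULL; frag <- integer(0); el <- character(0)
    charge <- numeric(0); dip <- NULL; quad <- NULL
    pols <- list()
    placed_sites <- matrix(0, 0, 3)
    for (f in seq_len(spec$n_fragments)) {
      for (attempt in 1:500) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u * u))
        rad <- stats::runif(1, spec$shell[1], spec$shell[2])
        R <- random_rotation()
        fpos <- t(R %*% t(tmpl$position)) +
          matrix(rad * u, 3, 3, byrow = TRUE)
        dmin_core <- min(apply(fpos, 1, function(p) {
          min(sqrt(rowSums(sweep(ct$core$position, 2, p)^2)))
        }))
        dmin_sites <- if (nrow(placed_sites)) {
          min(apply(fpos, 1, function(p) {
            min(sqrt(rowSums(sweep(placed_sites, 2, p)^2)))
          }))
        } else Inf
        if (dmin_core >= spec$min_core_dist && dmin_sites >= 2.5) break
        if (attempt == 500) stop("fragment placement failed; widen the shell")
      }
      pos <- rbind(pos, fpos)
      placed_sites <- rbind(placed_sites, fpos)
      frag <- c(frag, rep(f, 3))
      el <- c(el, tmpl$element)
      charge <- c(charge, tmpl$charge)
      dip <- rbind(dip, t(R %*% t(tmpl$dipole)))
      quad <- rbind(quad, t(apply(tmpl$quadrupole, 1, rotate_packed_sym, R = R)))
      pols <- c(pols, lapply(tmpl$polarizability,
                             function(a) R %*% a %*% t(R)))
    }
    S <- length(frag)
    pol_arr <- array(0, c(3, 3, S))
    for (s in seq_len(S)) pol_arr[, , s] <- pols[[s]]
    excl <- lapply(seq_len(S), function(s) {
      setdiff(which(frag == frag[s]), s)
    })
    k_bohr <- pe_constants$bohr_per_angstrom
    sites <- if (S > 0) {
      pe_sites(position = pos, fragment = frag, charge = charge,
               dipole = dip, quadrupole = quad,
               max_order = rep(2L, S), polarizability = pol_arr,
               exclusions = excl, element = el,
               lj_sigma = rep(tmpl$lj_sigma_ang * k_bohr,
                              spec$n_fragments),
               lj_epsilon = rep(tmpl$lj_eps_kjmol *
                                  pe_constants$hartree_per_kjmol,
                                spec$n_fragments))
    } else {
      pe_sites(position = matrix(0, 0, 3), fragment = integer(0))
    }
    sites$lj_sigma[sites$lj_sigma == 0] <- NA
    sites$lj_epsilon[sites$lj_epsilon == 0] <- NA
    structure(list(core = ct$core, sites = sites, bonds = ct$bonds,
                   spec = spec),
              class = "pe_fixture")
  })
}

#' @export
print.pe_fixture <- function(x, ...) {
  cat(sprintf("synthetic fixture: %d core atoms, %d fragments (seed %d)\n",
              n_core_atoms(x$core), length(unique(x$sites$fragment)),
              x$spec$seed))
  invisible(x)
}

#' Keep whole fragments whose center of mass lies within a cutoff
#'
#' @param sites A [pe_sites()] object.
#' @param center 3-vector (bohr).
#' @param cutoff Radius (bohr); `Inf` keeps everything.
#' @return A [pe_sites()] object; fragments are never split.
#' @export
shell_filter <- function(sites, center, cutoff) {
  frs <- unique(sites$fragment)
  keep <- frs[vapply(frs, function(f) {
    idx <- which(sites$fragment == f)
    m <- element_mass(sites$element[idx])
    com <- colSums(sites$position[idx, , drop = FALSE] * m) / sum(m)
    sqrt(sum((com - center)^2)) <= cutoff
  }, logical(1))]
  subset_fragments(sites, keep)
}

#' Internal core force field: energy, gradient, Hessian of the pair springs
#'
#' V = sum_bonds k/2 (r - r0)^2 over the fixture's spring table; translation
#' and rotation invariant, so a free core at its template geometry has six
#' zero modes.
#'
#' @param core A [pe_core()] object.
#' @param bonds Spring table (columns `i`, `j`, `k`, `r0`).
#' @return List with `energy`, `gradient` (3N), `hessian` (3N x 3N).
#' @export
core_spring_terms <- function(core, bonds) {
  N <- n_core_atoms(core)
  e <- 0; g <- numeric(3 * N); H <- matrix(0, 3 * N, 3 * N)
  I3 <- diag(3)
  for (b in seq_len(NROW(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]; kk <- bonds$k[b]; r0 <- bonds$r0[b]
    d <- core$position[i, ] - core$position[j, ]
    r <- sqrt(sum(d * d)); u <- d / r
    e <- e + 0.5 * kk * (r - r0)^2
    gi <- kk * (r - r0) * u
    g[3 * i - 2:0] <- g[3 * i - 2:0] + gi
    g[3 * j - 2:0] <- g[3 * j - 2:0] - gi
    blk <- kk * tcrossprod(u) + kk * (r - r0) / r * (I3 - tcrossprod(u))
    ii <- 3 * i - 2:0; jj <- 3 * j - 2:0
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  list(energy = e, gradient = g, hessian = H)
}

#' Toy dipole surface of the embedded core
#'
#' mu(R) = sum_n Z_n R_n plus the total induced dipole of the environment;
#' the analytic Cartesian gradient includes the response of the induced
#' dipoles to core motion (through the nuclear field only).
#'
#' @param core A [pe_core()] object.
#' @param sites Optional [pe_sites()] environment; omit for a vacuum core.
#' @param tol Induced-dipole solver tolerance.
#' @return List with `dipole` (3-vector, e bohr) and `gradient` (3N x 3
#'   matrix, e; rows are core Cartesian coordinates, columns dipole
#'   components).
#' @export
toy_dipole_surface <- function(core, sites = NULL, tol = 1e-10) {
  N <- n_core_atoms(core)
  mu <- colSums(core$position * core$Z)
  grad <- matrix(0, 3 * N, 3)
  for (n in seq_len(N)) {
    grad[3 * n - 2:0, ] <- diag(3) * core$Z[n]
  }
  if (!is.null(sites) && any(polarizable_mask(sites))) {
    resp <- assemble_response_matrix(sites)
    field <- total_site_field(sites, core)
    m <- solve_induced_moments(resp, field, tol = tol)
    P <- length(resp$pol_sites)
    mu <- mu + colSums(matrix(as.numeric(m), nrow = P, byrow = TRUE))
    G <- field_gradient_matrix(sites, core, resp$pol_sites)
    X <- matrix(0, nrow(G), ncol(G))
    for (j in seq_len(ncol(G))) {
      X[, j] <- pcg_solve(resp$A, G[, j], resp$alphas, tol = tol)
    }
    for (a in 1:3) {
      rows <- seq(a, 3 * P, by = 3)
      grad[, a] <- grad[, a] + colSums(X[rows, , drop = FALSE])
    }
  }
  list(dipole = mu, gradient = grad)
}

#' Toy bond-polarizability surface of the core
#'
#' alpha(R) = sum_n iso I + sum_bonds \[ a_T(r) I + (a_L(r) - a_T(r))
#' u u' \] with longitudinal/transverse components linear in the bond length,
#' a_L(r) = aL0 + aL1 (r - r0) and likewise for a_T. Rotation equivariant by
#' construction; the gradient is analytic.
#'
#' @param core A [pe_core()] object.
#' @param bonds Spring/bond table as in [core_spring_terms()] (chain bonds
#'   are the polarizable ones: rows with `k >= 0.2`).
#' @param params List with `iso`, `aL0`, `aL1`, `aT0`, `aT1` (bohr^3 scale).
#' @return List with `alpha` (3 x 3, bohr^3), `alpha_packed` (length 6) and
#'   `gradient` (3N x 6 packed xx xy xz yy yz zz).
#' @export
toy_polarizability_surface <- function(core, bonds = NULL,
                                       params = list(iso = 1.2, aL0 = 2.0,
                                                     aL1 = 1.5, aT0 = 1.0,
                                                     aT1 = 0.5)) {
  N <- n_core_atoms(core)
  alpha <- diag(3) * params$iso * N
  grad <- matrix(0, 3 * N, 6)
  if (!is.null(bonds)) bonds <- bonds[bonds$k >= 0.2, , drop = FALSE]
  for (b in seq_len(NROW(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]; r0 <- bonds$r0[b]
    d <- core$position[i, ] - core$position[j, ]
    r <- sqrt(sum(d * d)); u <- d / r
    aL <- params$aL0 + params$aL1 * (r - r0)
    aT <- params$aT0 + params$aT1 * (r - r0)
    alpha <- alpha + aT * diag(3) + (aL - aT) * tcrossprod(u)
    for (c_ in 1:3) {
      duc <- (diag(3)[c_, ] - u[c_] * u) / r     # d u / d R_ic
      dA <- params$aT1 * u[c_] * diag(3) +
        (params$aL1 - params$aT1) * u[c_] * tcrossprod(u) +
        (aL - aT) * (outer(duc, u) + outer(u, duc))
      pk <- c(dA[1, 1], dA[1, 2], dA[1, 3], dA[2, 2], dA[2, 3], dA[3, 3])
      grad[3 * (i - 1) + c_, ] <- grad[3 * (i - 1) + c_, ] + pk
      grad[3 * (j - 1) + c_, ] <- grad[3 * (j - 1) + c_, ] - pk
    }
  }
  list(alpha = alpha,
       alpha_packed = c(alpha[1, 1], alpha[1, 2], alpha[1, 3],
                        alpha[2, 2], alpha[2, 3], alpha[3, 3]),
       gradient = grad)
}

#' Jittered snapshot ensemble of a fixture
#'
#' Independent Gaussian displacements of the core atoms plus rigid-body
#' translations of each fragment, emulating configurational sampling.
#'
#' @param fixture A [make_fixture()] result.
#' @param n Number of snapshots.
#' @param jitter_scale Standard deviation of the displacements (bohr).
#' @param seed Integer seed.
#' @return List of `pe_fixture` objects (length `n`).
#' @export
make_snapshots <- function(fixture, n, jitter_scale, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n), function(j) {
      snap <- fixture
      N <- n_core_atoms(snap$core)
      snap$core$position <- snap$core$position +
        matrix(stats::rnorm(3 * N, sd = jitter_scale), N, 3)
      for (f in unique(snap$sites$fragment)) {
        idx <- which(snap$sites$fragment == f)
        shift <- stats::rnorm(3, sd = jitter_scale)
        snap$sites$position[idx, ] <-
          sweep(snap$sites$position[idx, , drop = FALSE], 2, -shift)
      }
      snap
    })
  })
}
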