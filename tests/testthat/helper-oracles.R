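# Independent oracles and small builders shared across the suite.

# independent oracle for d^alpha (1/|Ri - Rj|) w.r.t. Rj: hand-written
# closed forms up to order 3, then O(h^4) five-point differencing of the
# next-lower oracle for orders 4+ (never touches the package recurrence)
tensor_oracle <- function(R_i, R_j, alpha, h = 0.12) {
  a <- as.integer(alpha)
  k <- sum(a)
  x <- R_j - R_i
  r <- sqrt(sum(x * x))
  if (k <= 3) {
    axes <- rep(1:3, times = a)
    if (k == 0) return(1 / r)
    if (k == 1) return(-x[axes[1]] / r^3)
    if (k == 2) {
      i <- axes[1]; j <- axes[2]
      return((3 * x[i] * x[j] - (i == j) * r^2) / r^5)
    }
    i <- axes[1]; j <- axes[2]; l <- axes[3]
    return(-15 * x[i] * x[j] * x[l] / r^7 +
             3 * ((i == j) * x[l] + (i == l) * x[j] + (j == l) * x[i]) / r^5)
  }
  ax <- which(a > 0)[1]
  a2 <- a; a2[ax] <- a2[ax] - 1L
  f <- function(p) tensor_oracle(R_i, p, a2, h = h)
  e <- c(0, 0, 0); e[ax] <- 1
  d4 <- function(s) {
    (8 * (f(R_j + s * e) - f(R_j - s * e)) -
       (f(R_j + 2 * s * e) - f(R_j - 2 * s * e))) / (12 * s)
  }
  (16 * d4(h / 2) - d4(h)) / 15   # Richardson: O(h^6)
}

# explicit Coulomb energy of a point-charge cluster against the core charges
explicit_coulomb_energy <- function(charges, positions, core) {
  e <- 0
  for (k in seq_along(charges)) {
    for (n in seq_len(n_core_atoms(core))) {
      e <- e + charges[k] * core$Z[n] /
        sqrt(sum((positions[k, ] - core$position[n, ])^2))
    }
  }
  e
}

# Cartesian multipoles of a charge cluster about a center: M^[a] = sum q d^a
cluster_multipoles <- function(charges, positions, center) {
  d <- sweep(positions, 2, center)
  list(
    charge = sum(charges),
    dipole = colSums(charges * d),
    quadrupole = c(sum(charges * d[, 1]^2), sum(charges * d[, 1] * d[, 2]),
                   sum(charges * d[, 1] * d[, 3]), sum(charges * d[, 2]^2),
                   sum(charges * d[, 2] * d[, 3]), sum(charges * d[, 3]^2))
  )
}

# single-site environment builder
one_site <- function(position, charge = 0, dipole = c(0, 0, 0),
                     quadrupole = rep(0, 6), alpha = NULL, max_order = NULL) {
  pol <- array(0, c(3, 3, 1))
  if (!is.null(alpha)) pol[, , 1] <- if (length(alpha) == 1) diag(3) * alpha else alpha
  pe_sites(position = matrix(position, 1), fragment = 1L,
           charge = charge, dipole = matrix(dipole, 1),
           quadrupole = matrix(quadrupole, 1),
           max_order = max_order, polarizability = pol)
}

point_core <- function(position, Z = 1, mass = 1) {
  pe_core(position = matrix(position, ncol = 3, byrow = TRUE),
          Z = Z, mass = rep_len(mass, length(Z)))
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# energy function of flattened core coordinates, environment response matrix
# held fixed (it does not depend on core positions); dense direct solve so
# the finite-difference path shares no solver code with the analytic one
total_energy_fun <- function(fixture, terms = c("es", "ind", "lj")) {
  sites <- fixture$sites
  resp <- if ("ind" %in% terms) assemble_response_matrix(sites) else NULL
  function(x) {
    core <- fixture$core
    core$position <- matrix(x, ncol = 3, byrow = TRUE)
    e <- 0
    if ("es" %in% terms) e <- e + as.numeric(electrostatic_energy(sites, core))
    if ("ind" %in% terms && length(resp$pol_sites) > 0) {
      f <- as.numeric(total_site_field(sites, core))
      mu <- solve(resp$A, f)
      e <- e - 0.5 * sum(mu * f)
    }
    if ("lj" %in% terms) e <- e + lj_energy(core, sites, warn = FALSE)
    e
  }
}

core_coords <- function(core) as.vector(t(core$position))
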