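test_that("response matrix has inverse polarizabilities and exclusion zeros", {
  s1 <- one_site(c(0, 0, 0), alpha = 8)
  r1 <- assemble_response_matrix(s1)
  expect_equal(r1$A, diag(3) / 8)

  # two sites in one fragment: excluded, off-diagonal blocks exactly zero
  pol <- array(0, c(3, 3, 2)); pol[, , 1] <- diag(3) * 4; pol[, , 2] <- diag(3) * 2
  same_frag <- pe_sites(position = rbind(c(0, 0, 0), c(0, 0, 4)),
                        fragment = c(1L, 1L), polarizability = pol,
                        exclusions = list(2L, 1L))
  A <- assemble_response_matrix(same_frag)$A
  expect_equal(A[1:3, 4:6], matrix(0, 3, 3))

  # two foreign sites on the z axis at separation 4: zz coupling -2/4^3
  two <- pe_sites(position = rbind(c(0, 0, 0), c(0, 0, 4)),
                  fragment = c(1L, 2L), polarizability = pol)
  A2 <- assemble_response_matrix(two)$A
  expect_equal(A2[3, 6], -2 / 64)
  expect_equal(A2[4:6, 1:3], A2[1:3, 4:6])
  zz <- tensor_oracle(c(0, 0, 0), c(0, 0, 4), c(0, 0, 2))
  expect_equal(A2[3, 6], -zz, tolerance = 1e-9)

  sing <- one_site(c(0, 0, 0), alpha = matrix(0, 3, 3) + diag(c(1, 1, 0)))
  expect_error(assemble_response_matrix(sing), "singular|negative")
})

test_that("site fields have the right nuclear part and exclusion behavior", {
  s <- one_site(c(0, 0, 0), alpha = 3)
  core <- point_core(c(0, 0, 3), Z = 1)
  f <- total_site_field(s, core)
  expect_equal(as.numeric(f), c(0, 0, -1 / 9), tolerance = 1e-12)

  # a site is blind to its own fragment's permanent dipole
  pol <- array(0, c(3, 3, 2)); pol[, , 1] <- diag(3) * 3
  pair <- pe_sites(position = rbind(c(0, 0, 0), c(0, 0, 2)),
                   fragment = c(1L, 1L),
                   dipole = rbind(c(0, 0, 0), c(0, 0, 0.5)),
                   max_order = c(0L, 1L), polarizability = pol,
                   exclusions = list(2L, 1L))
  f2 <- total_site_field(pair, pe_core(matrix(c(50, 0, 0), 1), 1e-6, 1))
  expect_equal(attr(f2, "multipole"), rep(0, 3))

  # nuclear part equals minus the numerical gradient of the nuclear potential
  fx <- make_fixture(fixture_spec(n_fragments = 3, n_core_atoms = 3, seed = 4))
  pol_idx <- which(polarizable_mask(fx$sites))[1]
  Rs <- fx$sites$position[pol_idx, ]
  vn <- function(p) sum(fx$core$Z / sqrt(rowSums(sweep(fx$core$position, 2, p)^2)))
  f_num <- -fd_gradient(vn, Rs, h = 1e-4)
  f_pkg <- attr(total_site_field(fx$sites, fx$core), "nuclear")[1:3]
  expect_equal(f_pkg, f_num, tolerance = 1e-8)
})

test_that("iterative induced dipoles match closed forms and dense solves", {
  s <- one_site(c(0, 0, 0), alpha = 5)
  core <- point_core(c(0, 0, 3), Z = 2)
  resp <- assemble_response_matrix(s)
  f <- total_site_field(s, core)
  mu <- solve_induced_moments(resp, f)
  expect_equal(as.numeric(mu), 5 * as.numeric(f), tolerance = 1e-12)
  expect_equal(induction_energy(mu, f), -0.5 * 5 * sum(as.numeric(f)^2),
               tolerance = 1e-12)

  # doubling the core charge quadruples the induction energy
  core2 <- point_core(c(0, 0, 3), Z = 4)
  f2 <- total_site_field(s, core2)
  mu2 <- solve_induced_moments(resp, f2)
  expect_equal(induction_energy(mu2, f2), 4 * induction_energy(mu, f),
               tolerance = 1e-12)

  expect_equal(as.numeric(solve_induced_moments(resp, rep(0, 3))), rep(0, 3))

  for (seed in c(3, 8)) {
    fx <- make_fixture(fixture_spec(n_fragments = 6, n_core_atoms = 4,
                                    seed = seed))
    resp <- assemble_response_matrix(fx$sites)
    f <- total_site_field(fx$sites, fx$core)
    mu_it <- as.numeric(solve_induced_moments(resp, f))
    mu_dense <- solve(resp$A, as.numeric(f))
    expect_lt(max(abs(mu_it - mu_dense)) / max(abs(mu_dense)), 1e-9)
    expect_lt(induction_energy(mu_it, f), 0)
  }
})

test_that("induction energy is the minimum of the polarization functional", {
  pol <- array(0, c(3, 3, 2)); pol[, , 1] <- diag(3) * 4; pol[, , 2] <- diag(3) * 6
  chain <- pe_sites(position = rbind(c(0, 0, 0), c(0, 0, 5)),
                    fragment = c(1L, 2L), polarizability = pol)
  core <- point_core(c(4, 0, 2), Z = 1.5)
  resp <- assemble_response_matrix(chain)
  f <- as.numeric(total_site_field(chain, core))
  mu <- as.numeric(solve_induced_moments(resp, f))
  functional <- function(m) 0.5 * sum(m * (resp$A %*% m)) - sum(m * f)
  opt <- optim(rep(0, 6), functional, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(functional(mu), opt$value, tolerance = 1e-8)
  expect_equal(induction_energy(mu, f), functional(mu), tolerance = 1e-12)
  # perturbing away from the solution only raises the functional
  set.seed(2)
  for (k in 1:5) {
    expect_gt(functional(mu + rnorm(6, sd = 0.01)), functional(mu))
  }
})

test_that("nuclear-potential derivatives are FD-consistent and decay", {
  core <- point_core(rbind(c(0, 0, 2), c(1, -1, 3)), Z = c(1, 1.5), mass = 1)
  Rs <- c(5, 1, -2)
  for (alpha in list(mi(0, 0, 0), mi(1, 0, 0), mi(0, 1, 1))) {
    vfun <- function(x) {
      c2 <- core; c2$position <- matrix(x, ncol = 3, byrow = TRUE)
      sum(vapply(1:2, function(n) {
        c2$Z[n] * tensor_oracle(c2$position[n, ], Rs, unclass(alpha))
      }, numeric(1)))
    }
    d1 <- nuclear_potential_derivatives(core, Rs, alpha, 1)
    d1_fd <- fd_gradient(vfun, core_coords(core), h = 1e-3)
    expect_equal(d1, d1_fd, tolerance = 1e-6)
    d2 <- nuclear_potential_derivatives(core, Rs, alpha, 2)
    expect_equal(d2, t(d2))
    d2_fd <- fd_jacobian(function(x) {
      c2 <- core; c2$position <- matrix(x, ncol = 3, byrow = TRUE)
      nuclear_potential_derivatives(c2, Rs, alpha, 1)
    }, core_coords(core), h = 1e-3)
    expect_equal(d2, (d2_fd + t(d2_fd)) / 2, tolerance = 1e-6)
  }
  # scaling decay: moving the site out scales derivatives by r^-(|a|+d+1)
  core1 <- point_core(c(0, 0, 0), Z = 1)
  for (k in c(2, 4)) {
    a <- mi(0, 0, 1)
    v1 <- nuclear_potential_derivatives(core1, c(0, 0, 4), a, 1)[3]
    v2 <- nuclear_potential_derivatives(core1, c(0, 0, 4 * k), a, 1)[3]
    expect_equal(v2 / v1, k^-(1 + 1 + 1), tolerance = 1e-12)
  }
})

test_that("induction gradient and Hessian match finite differences", {
  fx <- make_fixture(fixture_spec(n_fragments = 5, n_core_atoms = 3, seed = 6))
  efun <- total_energy_fun(fx, terms = "ind")
  x0 <- core_coords(fx$core)
  g <- induction_gradient(fx$sites, fx$core)
  g_fd <- fd_gradient(efun, x0, h = 1e-3)
  expect_lt(max(abs(g - g_fd)), 1e-7)

  H <- induction_hessian(fx$sites, fx$core)
  expect_equal(H, t(H), tolerance = 1e-10)
  H_fd <- fd_jacobian(function(x) {
    c2 <- fx$core; c2$position <- matrix(x, ncol = 3, byrow = TRUE)
    induction_gradient(fx$sites, c2)
  }, x0, h = 1e-3)
  expect_lt(max(abs(H - (H_fd + t(H_fd)) / 2)), 1e-6)

  # the B-contraction part is a negative-semidefinite quadratic form
  resp <- assemble_response_matrix(fx$sites)
  G <- polembed:::field_gradient_matrix(fx$sites, fx$core, resp$pol_sites)
  M <- -crossprod(G, solve(resp$A, G))
  expect_lt(max(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 1e-12)
})

test_that("degenerate induction cases behave structurally", {
  # no polarizable sites: all induction quantities vanish
  bare <- pe_sites(position = matrix(c(0, 0, 5), 1), fragment = 1L,
                   charge = -0.3)
  core <- point_core(rbind(c(0, 0, 0), c(2, 0, 0)), Z = c(1, 1), mass = 1)
  expect_equal(induction_report(bare, core)$energy, 0)
  expect_equal(induction_gradient(bare, core), rep(0, 6))
  expect_equal(induction_hessian(bare, core), matrix(0, 6, 6))

  # with zero permanent multipoles E_ind is even in the core charges
  s <- one_site(c(0, 0, 6), alpha = 4)
  rep1 <- induction_report(s, core)
  core_fl <- core; core_fl$Z <- core$Z  # magnitudes only; sign flip below
  f_fl <- -as.numeric(total_site_field(s, core))
  resp <- assemble_response_matrix(s)
  mu_fl <- solve_induced_moments(resp, f_fl)
  expect_equal(induction_energy(mu_fl, f_fl), rep1$energy, tolerance = 1e-12)
})

test_that("energies are invariant under fragment relabeling", {
  fx <- make_fixture(fixture_spec(n_fragments = 4, n_core_atoms = 3, seed = 12))
  s <- fx$sites
  perm <- c(3, 1, 4, 2)
  ord <- order(match(s$fragment, perm))
  inv <- integer(n_sites(s)); inv[ord] <- seq_len(n_sites(s))
  s2 <- pe_sites(position = s$position[ord, ], fragment = s$fragment[ord],
                 charge = s$charge[ord], dipole = s$dipole[ord, ],
                 quadrupole = s$quadrupole[ord, ],
                 max_order = s$max_order[ord],
                 polarizability = s$polarizability[, , ord],
                 exclusions = lapply(s$exclusions[ord],
                                     function(e) inv[e]),
                 element = s$element[ord],
                 lj_sigma = s$lj_sigma[ord], lj_epsilon = s$lj_epsilon[ord])
  e1 <- pe_energy(fx$core, s)
  e2 <- pe_energy(fx$core, s2)
  expect_equal(e2$total, e1$total, tolerance = 1e-11)
  expect_equal(e2$ind, e1$ind, tolerance = 1e-11)
})
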