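# 6x6 Cartesian Hessian of a harmonic diatomic along the x axis
diatomic_hessian <- function(k) {
  u <- c(1, 0, 0)
  blk <- k * outer(u, u)
  H <- matrix(0, 6, 6)
  H[1:3, 1:3] <- blk; H[4:6, 4:6] <- blk
  H[1:3, 4:6] <- -blk; H[4:6, 1:3] <- -blk
  H
}

test_that("mass weighting divides by sqrt(m_i m_j) per coordinate", {
  H <- matrix(rnorm(36), 6, 6); H <- H + t(H)
  expect_equal(mass_weight_hessian(H, c(1, 1)), H)
  m <- c(2, 8)
  Hm <- mass_weight_hessian(H, m)
  expect_equal(Hm[1, 4], H[1, 4] / 4)
  expect_equal(Hm[4, 6], H[4, 6] / 8)
  # scaling all masses by 4 scales eigenvalues by 1/4
  e1 <- eigen(mass_weight_hessian(H, m), only.values = TRUE)$values
  e2 <- eigen(mass_weight_hessian(H, 4 * m), only.values = TRUE)$values
  expect_equal(e2, e1 / 4, tolerance = 1e-12)
})

test_that("diatomic frequency matches the reduced-mass closed form through
           an independent SI constant chain", {
  k_au <- 1; masses <- c(1, 1)
  nm <- normal_modes(mass_weight_hessian(diatomic_hessian(k_au), masses),
                     masses)
  got <- max(nm$wavenumbers)
  # independent arithmetic: k in N/m, mu in kg, nu = sqrt(k/mu)/(2 pi c)
  k_si <- k_au * 4.3597447222071e-18 / (5.29177210903e-11)^2
  mu_si <- 0.5 * 1.66053906660e-27
  ref <- sqrt(k_si / mu_si) / (2 * pi * 2.99792458e10)
  expect_equal(got, ref, tolerance = 1e-9)
  # five zero modes accompany the single vibration (an exactly zero
  # eigenvalue appears as ~sqrt(machine eps) after the wavenumber map)
  expect_equal(sum(abs(nm$wavenumbers) < 1e-3), 5)
})

test_that("degenerate and sign cases of the eigenanalysis", {
  expect_equal(normal_modes(matrix(0, 6, 6), c(1, 1))$wavenumbers, rep(0, 6))
  wn <- normal_modes(-diag(3) * 0.1, 16)$wavenumbers
  expect_true(all(wn < 0))
  expect_error(normal_modes(matrix(rnorm(9), 3, 3), 1), "not symmetric")
  # orthonormal modes, deterministic sign: largest element positive
  H <- diatomic_hessian(0.7)
  nm <- normal_modes(mass_weight_hessian(H, c(1, 2)), c(1, 2))
  expect_equal(crossprod(nm$modes), diag(6), tolerance = 1e-10)
  for (k in 1:6) {
    expect_gt(nm$modes[which.max(abs(nm$modes[, k])), k], 0)
  }
  expect_equal(nm$wavenumbers, sort(nm$wavenumbers))
})

test_that("translation/rotation projection removes rigid-body modes", {
  geom <- rbind(c(-1.05, 0, 0), c(1.05, 0, 0))
  masses <- c(12, 12)
  H_mw <- mass_weight_hessian(diatomic_hessian(0.5), masses)
  P_H <- project_translations_rotations(H_mw, geom, masses)
  wn <- normal_modes(P_H, masses)$wavenumbers
  # free diatomic at equilibrium of a pair potential: 5 exact zeros remain
  expect_equal(sum(abs(wn) < 1e-2), 5)
  expect_gt(max(wn), 100)
  B <- polembed:::trans_rot_basis(geom, masses)
  expect_equal(ncol(B), 5)  # linear molecule
  P <- diag(6) - tcrossprod(B)
  expect_lt(max(abs(P %*% P - P)), 1e-12)

  # nonlinear 3-atom geometry gives a rank-6 rigid-body space
  geom3 <- rbind(c(0, 0, 0), c(1.8, 0, 0), c(0.5, 1.6, 0))
  B3 <- polembed:::trans_rot_basis(geom3, c(16, 1, 1))
  expect_equal(ncol(B3), 6)

  # on an embedded (PHVA) Hessian projection moves low modes most
  fx <- make_fixture(fixture_spec(n_fragments = 5, n_core_atoms = 4, seed = 10))
  dump <- snapshot_properties(fx)
  Hmw <- mass_weight_hessian(dump$hessian, dump$masses)
  wn_raw <- normal_modes(Hmw, dump$masses)$wavenumbers
  wn_prj <- normal_modes(project_translations_rotations(Hmw, dump$position,
                                                        dump$masses),
                         dump$masses)$wavenumbers
  n <- length(wn_raw)
  shift_low <- mean(abs(wn_raw[1:6] - wn_prj[1:6]))
  shift_high <- mean(abs(wn_raw[(n - 2):n] - wn_prj[(n - 2):n]))
  expect_gt(shift_low, shift_high)
})

test_that("mode filtering respects the cutoff bookkeeping", {
  masses <- c(1, 1)
  nm <- normal_modes(mass_weight_hessian(diatomic_hessian(1), masses), masses)
  all_modes <- filter_modes(nm, cutoff = -Inf)
  expect_length(all_modes$wavenumbers, 6)
  kept <- filter_modes(nm, cutoff = pe_phva_cutoff())
  expect_length(kept$wavenumbers, 1)
  expect_equal(attr(kept, "n_dropped"), 5)
  expect_warning(none <- filter_modes(nm, cutoff = 1e6), "retains no modes")
  expect_length(none$wavenumbers, 0)
  expect_equal(pe_phva_cutoff(), 750)
})

test_that("property gradients transform linearly to normal coordinates", {
  masses <- c(2, 3)
  H <- diatomic_hessian(0.9)
  nm <- normal_modes(mass_weight_hessian(H, masses), masses)
  m3 <- rep(masses, each = 3)
  # gradient parallel to one mass-weighted mode maps onto that mode alone
  v <- nm$modes[, 4] * sqrt(m3)
  q <- gradient_to_normal_coordinates(matrix(v, ncol = 1), nm)
  expect_equal(as.numeric(q), c(0, 0, 0, 1, 0, 0), tolerance = 1e-10)
  # orthogonal gradient maps to zero on that mode
  w <- nm$modes[, 2] * sqrt(m3)
  q2 <- gradient_to_normal_coordinates(matrix(w, ncol = 1), nm)
  expect_equal(q2[4], 0, tolerance = 1e-12)

  # hand-computed diatomic dipole derivative: charges +q/-q moving along x
  # with dmu_x/dx_1 = q, dmu_x/dx_2 = -q projects onto the stretch as
  # q (L11/sqrt(m1) - L12/sqrt(m2))
  qch <- 0.4
  dmu <- matrix(0, 6, 3)
  dmu[1, 1] <- qch; dmu[4, 1] <- -qch
  stretch <- which.max(nm$wavenumbers)
  qn <- gradient_to_normal_coordinates(dmu, nm)
  hand <- qch * (nm$modes[1, stretch] / sqrt(masses[1]) -
                   nm$modes[4, stretch] / sqrt(masses[2]))
  expect_equal(qn[stretch, 1], hand, tolerance = 1e-12)
})
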