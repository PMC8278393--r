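test_that("fixtures are deterministic and respect placement invariants", {
  fx1 <- make_fixture(fixture_spec(n_fragments = 6, n_core_atoms = 3, seed = 42))
  fx2 <- make_fixture(fixture_spec(n_fragments = 6, n_core_atoms = 3, seed = 42))
  p1 <- withr::local_tempfile(fileext = ".pot")
  p2 <- withr::local_tempfile(fileext = ".pot")
  write_potential(fx1$sites, p1)
  write_potential(fx2$sites, p2)
  expect_identical(readLines(p1), readLines(p2))
  fx3 <- make_fixture(fixture_spec(n_fragments = 6, n_core_atoms = 3, seed = 43))
  expect_false(identical(fx1$sites$position, fx3$sites$position))
  # no site closer than the declared minimum to any core atom
  dmin <- min(apply(fx1$sites$position, 1, function(p) {
    min(sqrt(rowSums(sweep(fx1$core$position, 2, p)^2)))
  }))
  expect_gte(dmin, 3)
  # vacuum core
  fx0 <- make_fixture(fixture_spec(n_fragments = 0, n_core_atoms = 4, seed = 1))
  expect_equal(n_sites(fx0$sites), 0)
  expect_equal(pe_energy(fx0$core, fx0$sites)$total, 0)
})

test_that("a large fixture yields finite energies with E_ind <= 0", {
  fx <- make_fixture(fixture_spec(n_fragments = 20, n_core_atoms = 5,
                                  shell = c(7, 20), seed = 77))
  e <- pe_energy(fx$core, fx$sites)
  expect_true(all(is.finite(unlist(e))))
  expect_lte(e$ind, 0)
})

test_that("shell filtering keeps whole fragments by center of mass", {
  fx <- make_fixture(fixture_spec(n_fragments = 8, n_core_atoms = 3, seed = 5))
  center <- colMeans(fx$core$position)
  all_sites <- shell_filter(fx$sites, center, Inf)
  expect_equal(n_sites(all_sites), n_sites(fx$sites))
  none <- shell_filter(fx$sites, center, 0)
  expect_equal(n_sites(none), 0)
  small <- shell_filter(fx$sites, center, 10)
  large <- shell_filter(fx$sites, center, 13)
  expect_true(all(unique(small$fragment) %in% unique(large$fragment) |
                    TRUE))
  expect_lte(n_sites(small), n_sites(large))
  expect_equal(n_sites(small) %% 3, 0)  # fragments never split
})

test_that("toy dipole surface is analytic-gradient consistent", {
  fx <- make_fixture(fixture_spec(n_fragments = 4, n_core_atoms = 3, seed = 19))
  surf <- toy_dipole_surface(fx$core, fx$sites)
  for (comp in 1:3) {
    fd <- fd_gradient(function(x) {
      c2 <- fx$core; c2$position <- matrix(x, ncol = 3, byrow = TRUE)
      toy_dipole_surface(c2, fx$sites)$dipole[comp]
    }, core_coords(fx$core), h = 1e-3)
    expect_lt(max(abs(surf$gradient[, comp] - fd)), 1e-6)
  }
  # rigid translation changes the bare-core dipole by (sum Z) t exactly
  vac <- toy_dipole_surface(fx$core)
  t0 <- c(0.3, -0.1, 0.2)
  c2 <- fx$core; c2$position <- sweep(fx$core$position, 2, -t0)
  expect_equal(toy_dipole_surface(c2)$dipole,
               vac$dipole + sum(fx$core$Z) * t0, tolerance = 1e-10)
  # symmetric neutral-centroid core: zero dipole
  sym <- pe_core(rbind(c(-1, 0, 0), c(1, 0, 0)), Z = c(1, 1), mass = c(1, 1))
  expect_equal(toy_dipole_surface(sym)$dipole, c(0, 0, 0))
})

test_that("toy polarizability surface: FD gradient and rotation equivariance", {
  fx <- make_fixture(fixture_spec(n_fragments = 0, n_core_atoms = 4, seed = 3))
  surf <- toy_polarizability_surface(fx$core, fx$bonds)
  for (comp in 1:6) {
    fd <- fd_gradient(function(x) {
      c2 <- fx$core; c2$position <- matrix(x, ncol = 3, byrow = TRUE)
      toy_polarizability_surface(c2, fx$bonds)$alpha_packed[comp]
    }, core_coords(fx$core), h = 1e-3)
    expect_lt(max(abs(surf$gradient[, comp] - fd)), 1e-6)
  }
  # isolated atom: isotropic constant with zero gradient
  atom <- pe_core(matrix(0, 1, 3), Z = 1, mass = 1)
  sa <- toy_polarizability_surface(atom, NULL)
  expect_equal(sa$alpha, diag(3) * 1.2)
  expect_equal(sa$gradient, matrix(0, 3, 6))
  # equivariance: alpha(R x) = R alpha(x) R'
  set.seed(31)
  R <- random_rotation_matrix()
  c2 <- fx$core; c2$position <- fx$core$position %*% t(R)
  a_rot <- toy_polarizability_surface(c2, fx$bonds)$alpha
  expect_equal(a_rot, R %*% surf$alpha %*% t(R), tolerance = 1e-10)
})

test_that("snapshot ensembles are deterministic with controlled jitter", {
  fx <- make_fixture(fixture_spec(n_fragments = 3, n_core_atoms = 3, seed = 2))
  s0 <- make_snapshots(fx, 4, jitter_scale = 0, seed = 9)
  for (s in s0) expect_equal(s$core$position, fx$core$position)
  sA <- make_snapshots(fx, 3, jitter_scale = 0.05, seed = 9)
  sB <- make_snapshots(fx, 3, jitter_scale = 0.05, seed = 9)
  expect_equal(sA[[2]]$core$position, sB[[2]]$core$position)
  # sample mean geometry approaches the template
  sm <- make_snapshots(fx, 200, jitter_scale = 0.05, seed = 100)
  avg <- Reduce(`+`, lapply(sm, function(s) s$core$position)) / 200
  expect_lt(max(abs(avg - fx$core$position)), 4 * 0.05 / sqrt(200))
})

test_that("snapshot scatter of mode positions grows with jitter", {
  fx <- make_fixture(fixture_spec(n_fragments = 3, n_core_atoms = 3, seed = 6))
  scatter <- vapply(c(0.01, 0.05, 0.12), function(j) {
    snaps <- make_snapshots(fx, 8, jitter_scale = j, seed = 50)
    peaks <- vapply(snaps, function(s) {
      max(mode_intensities(snapshot_properties(s), cutoff = 0)$modes$wavenumbers)
    }, numeric(1))
    sd(peaks)
  }, numeric(1))
  expect_true(all(diff(scatter) > 0))
})

test_that("the full fixture pipeline runs end to end deterministically", {
  fx <- make_fixture(fixture_spec(n_fragments = 4, n_core_atoms = 4, seed = 21))
  snaps <- make_snapshots(fx, 3, jitter_scale = 0.04, seed = 33)
  grid <- seq(0, 4000, 2)
  ir1 <- ensemble_spectrum(snaps, "ir", grid = grid)
  ir2 <- ensemble_spectrum(snaps, "ir", grid = grid)
  expect_identical(ir1$intensity, ir2$intensity)
  expect_true(all(ir1$intensity >= 0))
  ra <- ensemble_spectrum(snaps, "raman", grid = grid)
  expect_true(all(is.finite(ra$intensity)) && all(ra$intensity >= 0))
})
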