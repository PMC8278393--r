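#' @section Double-harmonic intensities:
#' IR band strengths are squared dipole gradients with respect to
#' mass-weighted normal coordinates, mu_I^Q = sum_a (d mu_a / d Q_I)^2; the
#' molar decadic attenuation coefficient follows as
#'   eps_I(nu) = N_A / (12 ln10 eps0 c^2) mu_I^Q f(nu; nu_I, gamma_I)
#' so the band integral over wavenumber equals A_I / ln10 with
#' A_I = N_A mu_I^Q / (12 eps0 c^2) the Napierian integrated molecular
#' attenuation coefficient. Raman intensities combine the isotropic and
#' anisotropic invariants of the polarizability gradient as
#' k_a a_I^2 + k_b b_I^2 (k_a = 45, k_b = 7 for the standard perpendicular
#' polarized setup) inside the absolute differential scattering cross
#' section. Broadening uses a normalized Cauchy profile whose damping
#' parameter is the half-width at half-maximum.
#' @name pe-spectra
#' @keywords internal
NULL

#' Default lineshape half-width at half-maximum (cm^-1)
#' @export
pe_default_hwhm <- function() 3.0

#' IR band strength per mode
#'
#' Sum of squared Cartesian dipole-gradient components per normal mode;
#' invariant under rotations of the molecular frame.
#'
#' @param dipole_gradient_normal N_modes x 3 matrix d mu_a / d Q_I.
#' @return Numeric vector mu_I^Q (input units squared).
#' @export
ir_mode_strength <- function(dipole_gradient_normal) {
  m <- as.matrix(dipole_gradient_normal)
  stopifnot(ncol(m) == 3)
  rowSums(m^2)
}

#' Normalized Cauchy lineshape
#'
#' f(nu; nu_I, gamma) = (1/pi) gamma / ((nu - nu_I)^2 + gamma^2): unit
#' integral over nu, peak value 1/(pi gamma), half maximum at nu_I +/- gamma.
#'
#' @param nu Wavenumber grid (cm^-1).
#' @param nu_I Band center (cm^-1).
#' @param gamma HWHM (cm^-1), positive.
#' @return Density per cm^-1 on the grid.
#' @export
cauchy_lineshape <- function(nu, nu_I, gamma) {
  if (gamma <= 0) stop("lineshape HWHM must be positive")
  (gamma / pi) / ((nu - nu_I)^2 + gamma^2)
}

#' Molar decadic attenuation coefficient of one band on a grid
#'
#' @param mu_q Band strength mu_I^Q in SI (C^2 kg^-1).
#' @param nu_I Band center (cm^-1).
#' @param gamma HWHM (cm^-1).
#' @param grid Wavenumber grid (cm^-1).
#' @return eps_I(nu) in m^2 mol^-1 on the grid. The integral over the grid
#'   (in m^-1) equals A_I / ln(10) with A_I in m mol^-1.
#' @export
ir_epsilon <- function(mu_q, nu_I, gamma, grid) {
  A <- pe_unit_factors()$napierian_per_mu_q * mu_q          # m mol^-1
  # lineshape normalized per cm^-1; per m^-1 needs the factor 1/100
  (A / log(10)) * cauchy_lineshape(grid, nu_I, gamma) / 100
}

#' Raman invariants of a polarizability gradient
#'
#' a = (a_xx + a_yy + a_zz) / 3 and
#' b^2 = 1/2 \[(a_xx - a_yy)^2 + (a_yy - a_zz)^2 + (a_zz - a_xx)^2\] +
#'       3 (a_xy^2 + a_yz^2 + a_zx^2), both rotation invariant.
#'
#' @param alpha_gradient_normal N_modes x 6 matrix of packed symmetric
#'   polarizability gradients (xx, xy, xz, yy, yz, zz) per mode, or a single
#'   3 x 3 symmetric matrix.
#' @return Data frame with columns `a` and `b2` per mode.
#' @export
raman_invariants <- function(alpha_gradient_normal) {
  x <- alpha_gradient_normal
  if (is.matrix(x) && nrow(x) == 3 && ncol(x) == 3) {
    x <- matrix(c(x[1, 1], x[1, 2], x[1, 3], x[2, 2], x[2, 3], x[3, 3]),
                nrow = 1)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 6)
  xx <- x[, 1]; xy <- x[, 2]; xz <- x[, 3]
  yy <- x[, 4]; yz <- x[, 5]; zz <- x[, 6]
  a <- (xx + yy + zz) / 3
  b2 <- 0.5 * ((xx - yy)^2 + (yy - zz)^2 + (zz - xx)^2) +
    3 * (xy^2 + yz^2 + xz^2)
  data.frame(a = a, b2 = b2)
}

#' Raman measurement settings
#'
#' @param wavelength_nm Incident wavelength (default 514.5 nm, an argon-ion
#'   laser line).
#' @param temperature Kelvin (default 298); `0` removes the thermal factor.
#' @param k_a,k_b Invariant combination coefficients; 45 and 7 correspond to
#'   light polarized perpendicular to the observation direction.
#' @return Object of class `raman_settings` with `nu0` (cm^-1) precomputed.
#' @export
raman_settings <- function(wavelength_nm = 514.5, temperature = 298,
                           k_a = 45, k_b = 7) {
  if (wavelength_nm <= 0) stop("wavelength must be positive")
  if (temperature < 0) stop("temperature must be non-negative")
  structure(list(nu0 = 1e7 / wavelength_nm, temperature = temperature,
                 k_a = k_a, k_b = k_b),
            class = "raman_settings")
}

#' Absolute differential Raman scattering cross section of one mode
#'
#' sigma'_I = h / (8 eps0^2 c nu_I) (nu0 - nu_I)^4
#'            (k_a a^2 + k_b b^2) / 45 \[1 - exp(-h c nu_I / k T)\]^-1
#' with wavenumbers in m^-1 inside the constant chain and the invariants in
#' SI (derivatives with respect to mass-weighted normal coordinates).
#'
#' @param a,b2 Raman invariants in SI (a in C^2 m J^-1 kg^-1/2; b2 its
#'   square-scale).
#' @param nu_I Mode wavenumber (cm^-1), positive.
#' @param settings A [raman_settings()] object.
#' @return Cross section (SI; reported per unit solid angle and scatterer).
#' @export
raman_cross_section <- function(a, b2, nu_I, settings = raman_settings()) {
  if (any(nu_I <= 0)) stop("Raman cross section needs positive mode wavenumbers")
  if (any(settings$nu0 <= nu_I)) {
    warning("incident wavenumber below a mode wavenumber: ",
            "anti-Stokes regime is not modeled")
  }
  k <- pe_constants
  nu_I_m <- nu_I * 100
  nu0_m <- settings$nu0 * 100
  boltz <- if (settings$temperature == 0) {
    1
  } else {
    1 / (1 - exp(-k$h * k$c * nu_I_m / (k$k_B * settings$temperature)))
  }
  k$h / (8 * k$eps0^2 * k$c * nu_I_m) * (nu0_m - nu_I_m)^4 *
    (settings$k_a * a^2 + settings$k_b * b2) / 45 * boltz
}

#' Spectrum container
#'
#' @param wavenumber Strictly increasing grid (cm^-1).
#' @param intensity Intensities on the grid.
#' @param unit Mandatory unit tag.
#' @param snapshots Provenance: snapshot identifiers.
#' @return Object of class `spectrum_grid`.
#' @export
spectrum_grid <- function(wavenumber, intensity, unit, snapshots = NA) {
  if (any(diff(wavenumber) <= 0)) stop("wavenumber grid must be strictly increasing")
  stopifnot(length(wavenumber) == length(intensity))
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 unit = unit, snapshots = snapshots),
            class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("spectrum: %d points, %.1f..%.1f cm^-1, unit %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$unit))
  invisible(x)
}

#' Default wavenumber grid: 0 to 4000 cm^-1 at 0.5 cm^-1
#' @export
pe_default_grid <- function() seq(0, 4000, by = 0.5)

#' Broadened IR spectrum of one snapshot
#'
#' @param wavenumbers Mode positions (cm^-1).
#' @param mu_q Band strengths in SI (C^2 kg^-1), same length.
#' @param gamma HWHM (cm^-1), scalar or per mode.
#' @param grid Wavenumber grid (cm^-1).
#' @param snapshot Provenance id.
#' @return [spectrum_grid()] in m^2 mol^-1.
#' @export
ir_spectrum <- function(wavenumbers, mu_q, gamma = pe_default_hwhm(),
                        grid = pe_default_grid(), snapshot = NA) {
  stopifnot(length(wavenumbers) == length(mu_q))
  gamma <- rep_len(gamma, length(wavenumbers))
  y <- numeric(length(grid))
  for (i in seq_along(wavenumbers)) {
    y <- y + ir_epsilon(mu_q[i], wavenumbers[i], gamma[i], grid)
  }
  spectrum_grid(grid, y, unit = "m2/mol", snapshots = snapshot)
}

#' Broadened Raman spectrum of one snapshot
#'
#' @inheritParams ir_spectrum
#' @param cross_sections Per-mode [raman_cross_section()] values.
#' @return [spectrum_grid()] in cross-section units per cm^-1.
#' @export
raman_spectrum <- function(wavenumbers, cross_sections,
                           gamma = pe_default_hwhm(),
                           grid = pe_default_grid(), snapshot = NA) {
  stopifnot(length(wavenumbers) == length(cross_sections))
  gamma <- rep_len(gamma, length(wavenumbers))
  y <- numeric(length(grid))
  for (i in seq_along(wavenumbers)) {
    y <- y + cross_sections[i] * cauchy_lineshape(grid, wavenumbers[i], gamma[i])
  }
  spectrum_grid(grid, y, unit = "sigma'/cm^-1", snapshots = snapshot)
}

#' Average spectra over snapshots
#'
#' Pointwise mean of per-snapshot spectra sharing one grid and unit.
#'
#' @param spectra List of [spectrum_grid()] objects.
#' @return A [spectrum_grid()] carrying all snapshot ids.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  g <- spectra[[1]]$wavenumber
  u <- spectra[[1]]$unit
  for (s in spectra) {
    if (!identical(s$wavenumber, g)) stop("spectra must share a common grid")
    if (!identical(s$unit, u)) stop("spectra must share a common unit")
  }
  y <- Reduce(`+`, lapply(spectra, `[[`, "intensity")) / length(spectra)
  spectrum_grid(g, y, unit = u,
                snapshots = unlist(lapply(spectra, `[[`, "snapshots")))
}

#' Write a spectrum or per-mode stick table to CSV
#'
#' The unit tag is embedded in the header comment and the column name.
#'
#' @param spectrum A [spectrum_grid()] object.
#' @param path Output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", spectrum$unit), con)
  utils::write.csv(data.frame(wavenumber_cm1 = spectrum$wavenumber,
                              intensity = spectrum$intensity),
                   con, row.names = FALSE)
  invisible(path)
}
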