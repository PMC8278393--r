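# polembed

Classical polarizable-embedding (PE) energies, analytic geometric
derivatives, and double-harmonic IR/Raman spectra in R.

## What it is for

When a molecule sits in a structured environment — a solvent shell, a
protein pocket — the environment can be represented classically by
fragment-distributed permanent multipoles (charges, dipoles, quadrupoles),
dipole–dipole polarizabilities, and Lennard-Jones parameters. `polembed`
implements the classical core of that model for a point-charge central
molecule, together with everything needed to turn its Hessian and property
gradients into broadened vibrational spectra:

- **Multi-index interaction tensors** `T^[α](R_i, R_j) = ∂^α/∂R_j^α (1/|R_i − R_j|)`
  of arbitrary order, via a stable auxiliary-kernel recurrence.
- **Electrostatics**: `E_es = Σ_s Σ_{|α|≤K_s} (−1)^{|α|}/α! · M_s^[α] · Σ_n Z_n T^[α](R_s, R_n)`
  with analytic first and second geometric derivatives with respect to the
  core coordinates.
- **Induction**: induced site dipoles solving `A μ = F`, where `A` carries
  inverse site polarizabilities on its diagonal blocks and dipole–dipole
  interaction tensors between non-excluded sites off-diagonal;
  `E_ind = −½ μ·F`, solved by preconditioned conjugate gradients, with
  analytic gradient `−μ·∂F/∂g` and Hessian
  `−(∂F/∂g₁)ᵀ A⁻¹ (∂F/∂g₂) − μ·∂²F/∂g₁∂g₂`.
- **Lennard-Jones** 6-12 terms with Lorentz–Berthelot combination and
  analytic derivatives.
- **Partial Hessian vibrational analysis** (PHVA): mass weighting,
  eigenanalysis, optional translation/rotation projection, a configurable
  low-frequency cutoff (preset 750 cm⁻¹).
- **Spectra**: IR strengths `μ_I^Q = Σ_α (∂μ_α/∂Q_I)²`, molar decadic
  attenuation `ε_I(ν̄) = N_A/(12 ln10 ε₀ c²) μ_I^Q f(ν̄)`, Raman invariants
  `a, b²` combined as `45a² + 7b²` inside the absolute differential
  scattering cross section, Cauchy broadening (HWHM preset 3.0 cm⁻¹), and
  pointwise snapshot averaging. Unit conversions between the commonly
  reported IR/Raman intensity conventions are derived from CODATA 2018
  constants at call time.
- **I/O**: the Dalton-style `.pot` embedding-potential dialect, XYZ
  geometries, LJ parameter tables, plain-text property dumps.
- **Synthetic fixtures**: deterministic toy solvated systems (water-like
  fragments around a point-charge chain core) so the whole pipeline runs
  with no external data, plus a thin command-line wrapper
  (`inst/cli/polembed.R`).

## Worked example

```r
library(polembed)

fx <- make_fixture(fixture_spec(n_fragments = 5, n_core_atoms = 4, seed = 3))
unlist(pe_energy(fx$core, fx$sites))
#>            es           ind            lj         total
#> -0.1172560571 -0.0623953915  0.0001734218 -0.1794780267

dump <- snapshot_properties(fx)       # Hessian + property gradients
mi_ <- mode_intensities(dump, cutoff = 750)
mi_$stick
#>   wavenumber_cm1      mu_q_si raman_cross_section
#> 1       1234.307 2.127063e-14        2.303520e-36
#> 2       2608.929 6.504435e-12        7.336652e-36
#> 3       3796.701 8.145691e-12        5.465258e-37

snaps <- make_snapshots(fx, 3, jitter_scale = 0.03, seed = 11)
sp <- ensemble_spectrum(snaps, "ir", grid = seq(0, 4000, 1))
sp
#> spectrum: 4001 points, 0.0..4000.0 cm^-1, unit m2/mol
```

The energies are in hartree (the `es`/`ind`/`lj` split is the
electrostatic, induction and Lennard-Jones decomposition; induction is
always ≤ 0). The stick table lists retained normal modes with their IR band
strength in C² kg⁻¹ and absolute differential Raman cross section; the
averaged spectrum is a molar decadic attenuation coefficient on a
wavenumber grid. Unit conversions:

```r
convert_ir_units(1, "C2/kg", "D2/A2/amu")   # 1.492418e12
convert_raman_units(1, "C4m2/J2kg", "A4/amu")  # 1.341318e33
```

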