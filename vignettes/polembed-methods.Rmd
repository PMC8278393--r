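---
title: "Classical polarizable embedding and harmonic spectra: models, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classical polarizable embedding and harmonic spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polembed)
```

## The model

Polarizable embedding (PE) represents the surroundings of a central
molecule by fragments (solvent molecules, protein residues) carrying
atom-centered permanent Cartesian multipoles up to quadrupole,
dipole–dipole polarizabilities, and Lennard-Jones parameters. `polembed`
implements the classical part of this model: the central region is a set
of point-charge nuclei, and every energy term, together with its first and
second geometric derivatives with respect to the core coordinates, is
evaluated analytically. The environment is rigid throughout; derivatives
with respect to environment coordinates are deliberately out of scope,
matching the partial-Hessian treatment used downstream.

All internal computation is in Hartree atomic units. Unit conversion
happens only at the file boundaries (XYZ and LJ tables in angstrom /
kJ mol⁻¹) and in the spectroscopic unit chain, and every conversion factor
descends from a single CODATA-2018 constants table (`pe_constants`). We
note for the record that the frequently quoted literal
1.8897261254578281 bohr/Å corresponds to the CODATA-2014 Bohr radius; with
the 2018 value the factor is 1.8897261246..., and the package derives it
from the constant rather than hard-coding either literal.

### Interaction tensors and sign conventions

Every electrostatic quantity is built from Cartesian derivatives of the
Coulomb kernel, indexed by a multi-index $\alpha = (\alpha_x, \alpha_y,
\alpha_z)$:

$$T^{[\alpha]}(\mathbf R_i, \mathbf R_j) \;=\;
  \frac{\partial^{|\alpha|}}{\partial \mathbf R_j^{\alpha}}
  \frac{1}{|\mathbf R_i - \mathbf R_j|}.$$

The derivative-at-the-second-argument convention and the sign factor
$(-1)^{|\alpha|}/\alpha!$ multiplying multipole components in the energy
are *not* free choices here: they are pinned by the physical limit in
which a multipole is replaced by a cluster of point charges. The Taylor
expansion $\sum_k q_k/|\mathbf r - \mathbf d_k| = \sum_\alpha
(-1)^{|\alpha|} M^{[\alpha]}/\alpha! \, \partial^\alpha (1/r)$ with raw
moments $M^{[\alpha]} = \sum_k q_k \mathbf d_k^\alpha$ fixes everything,
and the test suite enforces it with finite-dipole and finite-quadrupole
oracles. Quadrupoles are stored as raw second moments in the packed order
xx, xy, xz, yy, yz, zz.

Components are generated by a recurrence on auxiliary kernels
$R^m(\mathbf r) = (-1)^m (2m-1)!!\, r^{-(2m+1)}$, for which
$\partial_x R^m = x\,R^{m+1}$ and hence

$$R^m_{t+1,u,v} = x\,R^{m+1}_{t,u,v} + t\,R^{m+1}_{t-1,u,v},$$

the analogue of the McMurchie–Davidson scheme specialized to the bare
$1/r$ kernel. This is numerically stable well past order 6 and avoids
symbolic differentiation; the tests compare it against an independent
oracle (hand-written closed forms to order 3, high-order finite
differencing of those above).

### Electrostatics

$$E_\text{es} = \sum_s \sum_{|\alpha| \le K_s}
  \frac{(-1)^{|\alpha|}}{\alpha!}\, M_s^{[\alpha]}
  \sum_n Z_n\, T^{[\alpha]}(\mathbf R_s, \mathbf R_n).$$

Each summand involves exactly one nucleus, so geometric differentiation
simply raises the tensor order, and the Hessian is block-diagonal over
core atoms — the inter-atom blocks are exactly zero by structure, which
the tests assert. Site–atom contacts below $10^{-6}$ bohr are a hard
error: the model uses no short-range damping, and silently damped values
would corrupt derivative checks.

### Induction

Polarizable sites carry induced point dipoles $\boldsymbol\mu$ solving
$\mathbf A \boldsymbol\mu = \mathbf F$: $\mathbf A$ has inverse site
polarizabilities on its diagonal $3\times3$ blocks and
$-T^{[2]}(\mathbf R_s, \mathbf R_t)$ off-diagonal for non-excluded pairs;
$\mathbf F$ collects the fields from the core nuclei and from permanent
multipoles of non-excluded sites. Exclusions are whatever the potential
file's EXCLISTS declare (normally the site's own fragment); the reader
symmetrizes them and reconstructs fragment membership as connected
components of the exclusion graph. The induction energy is the variational
minimum $E_\text{ind} = -\tfrac12 \boldsymbol\mu \cdot \mathbf F \le 0$.

The linear system is solved by preconditioned conjugate gradients with a
block-Jacobi preconditioner (each block applies the site polarizability),
a fixed iteration cap of 10 000, and a relative-residual tolerance of
$10^{-10}$ by default — bitwise reproducible for fixed inputs, and
cross-checked against dense direct solves in the tests. Because the
energy is variational in $\boldsymbol\mu$, the gradient needs no response
solve, $\partial E_\text{ind}/\partial g = -\boldsymbol\mu \cdot
\partial \mathbf F/\partial g$, while the Hessian contracts the field
derivatives through $\mathbf A^{-1}$ via $3N_\text{core}$ auxiliary CG
solves. Only dipole–dipole polarizabilities are supported; higher-order
site polarizabilities are a declared extension point, not implemented.
Since $\mathbf A$ depends only on the environment, the derivative
functions accept a precomputed response matrix, which callers evaluating
many core geometries (finite-difference sweeps, snapshot loops) should
reuse.

### Lennard-Jones

The 6-12 potential with Lorentz–Berthelot combination
($\sigma_{sn} = \tfrac12(\sigma_s + \sigma_n)$,
$\varepsilon_{sn} = \sqrt{\varepsilon_s \varepsilon_n}$) acts pairwise
between core atoms and those environment sites that carry parameters;
sites without parameters contribute nothing and trigger a single warning.
No cutoff or switching is applied at the model level. Parameters live in
a separate whitespace table keyed by element, with units declared in its
header, because the embedding-potential format does not carry them.

## Vibrational analysis

The harmonic analysis operates on the core–core Hessian block only
(PHVA); environment masses never enter. Mass weighting divides by
$\sqrt{m_i m_j}$ per Cartesian coordinate, eigenvalues map to wavenumbers
through $\tilde\nu = \operatorname{sign}(\lambda)
\sqrt{|\lambda| E_h/(a_0^2\, m_u)}/(2\pi c)$, with imaginary frequencies
reported as negative wavenumbers. Eigenvector sign is fixed by making the
largest-magnitude element positive, so mode matrices are reproducible.

Because an embedded core is not free to translate or rotate, its
low-frequency modes are contaminated by global motion. The package
exposes both remedies and leaves the comparison to the user: an optional
projection $P H P$ with $P$ complementary to the orthonormalized
mass-weighted rigid-body vectors (five for linear geometries, detected by
a moment-of-inertia ratio below $10^{-8}$), and a wavenumber cutoff below
which modes are dropped. The cutoff preset is 750 cm⁻¹, the value used by
the protocol this pipeline mirrors; it is an argument everywhere.

Property gradients transform to normal coordinates as
$\partial X/\partial Q_I = \sum_i (\partial X/\partial x_i)
L_{iI}/\sqrt{m_i}$.

## Intensities, units, and lineshape

IR band strengths are $\mu_I^Q = \sum_\alpha (\partial\mu_\alpha/\partial
Q_I)^2$; the molar decadic attenuation coefficient is

$$\varepsilon_I(\tilde\nu) = \frac{N_A}{12 \ln 10\, \varepsilon_0 c^2}
  \mu_I^Q f(\tilde\nu; \tilde\nu_I, \gamma_I),$$

so the band integral over wavenumber equals $A_I/\ln 10$ with $A_I =
N_A \mu_I^Q / (12 \varepsilon_0 c^2)$ the Napierian integrated molecular
attenuation coefficient. Raman intensities combine the invariants
$a_I$ (isotropic mean) and $b_I^2$ (anisotropy) of the polarizability
gradient as $k_a a_I^2 + k_b b_I^2$ with defaults $k_a = 45$, $k_b = 7$
(incident light polarized perpendicular to the observation direction)
inside

$$\sigma_I' = \frac{h}{8 \varepsilon_0^2 c\, \tilde\nu_I}
  (\tilde\nu_0 - \tilde\nu_I)^4 \frac{k_a a_I^2 + k_b b_I^2}{45}
  \left[1 - e^{-hc\tilde\nu_I/k_B T}\right]^{-1},$$

with presets 514.5 nm excitation and 298 K. The $T \to 0$ limit removes
the thermal factor exactly, and the anti-Stokes regime
($\tilde\nu_0 \le \tilde\nu_I$) is flagged, not modeled. These prefactors
are validated indirectly but stringently: the package must reproduce the
printed conversion factors $1\,\mathrm{C^2\,kg^{-1}} = 1.4924\times10^{12}\,
\mathrm{D^2\,\mathring A^{-2}\,amu^{-1}}$ and
$1\,\mathrm{C^4\,m^2\,J^{-2}\,kg^{-1}} = 1.3413\times10^{33}\,
\mathrm{\mathring A^4\,amu^{-1}}$ from the constants table to five
significant figures, and the band-integral identity above to 0.1 %. A
prefactor inconsistent with those anchors would fail both.

The commonly reported IR units fall into two families — band strengths
(C² kg⁻¹, D² Å⁻² amu⁻¹, m mol⁻¹, km mol⁻¹), which are linear multiples of
$\mu_I^Q$, and wavenumber-dependent attenuation coefficients (m² mol⁻¹,
L mol⁻¹ cm⁻¹). A bare number converts freely within a family; across
families the link is the band integral and requires the lineshape, so the
conversion engine raises an informative error instead of inventing a
factor. Decimal steps (km vs m; L mol⁻¹ cm⁻¹ vs m² mol⁻¹) are stored as
powers of ten so those identities are exact in floating point. We also
note that the conventional unit string printed for $\sigma'$
(C⁴ s² J⁻¹ m⁻² kg⁻¹) does not dimensionally reduce to an area; the
package reports the standard prefactor result and tags outputs with the
unit string without asserting their equality.

Broadening uses a normalized Cauchy profile whose damping parameter is
the half-width at half-maximum (preset 3.0 cm⁻¹), and snapshot ensembles
are averaged pointwise on a common grid (default 0–4000 cm⁻¹ at
0.5 cm⁻¹).

## The synthetic fixtures

The generator builds what the pipeline needs and nothing more: a
point-charge chain core (2–10 atoms, alternating charges 0.8–1.2 e and
masses 1–16 amu, OPLS-scale LJ parameters, harmonic pair springs at the
template geometry as its internal force field) surrounded by water-like
three-site fragments — net charge exactly zero (−0.670/+0.335/+0.335 e),
small site dipoles and quadrupoles, slightly anisotropic oxygen
(≈ 5.5–6.0 bohr³) and isotropic hydrogen (2.0 bohr³) polarizabilities,
values in the range of distributed solvent parametrizations. Fragments
are placed with random orientation on a shell (default 7–14 bohr) with a
minimum site–core distance of 3 bohr, so no interaction approaches its
singularity and the response matrix stays comfortably positive definite.
Snapshot ensembles apply independent Gaussian displacements to core atoms
and rigid translations to fragments; every random choice flows through an
explicit seed and the global RNG state is restored.

Property surfaces are likewise toy but analytic: the dipole is
$\sum_n Z_n \mathbf R_n$ plus the environment's induced dipoles
(including their response to core motion), and the polarizability is a
bond model with longitudinal/transverse components linear in the bond
length — rotation equivariant by construction. What the fixtures emulate
is the *structure* of the real problem (fragment exclusions, mixed
multipole orders, anisotropic response, solvent-shell geometry, snapshot
scatter); what they do not emulate is chemistry — no real force field,
no quantum charge distribution, no configurational Boltzmann sampling.
A passing suite therefore certifies the algebra, the derivative stack,
and the spectral bookkeeping, not the accuracy of any particular solvent
model.

## Numerical choices

- Finite-difference verification uses central differences with Richardson
  extrapolation, step $10^{-3}$ bohr; agreement thresholds are $10^{-6}$
  relative on randomized systems (observed deviations are
  $\sim 10^{-10}$).
- Degenerate geometry (site–atom contact $< 10^{-6}$ bohr), singular site
  polarizabilities, and non-positive-definite response matrices are
  errors, never silently repaired values.
- Eigen-decompositions are deterministic: ascending wavenumber order and
  positive largest eigenvector component.
- Acceptance-scale problem sizes: the derivative sweep uses ten systems
  of up to 10 fragments and 6 core atoms (tests) and five freshly
  randomized systems in the acceptance script — large enough to mix all
  multipole orders, exclusion patterns, and anisotropy, small enough to
  run interactively.

## Design notes

- The configuration file format is YAML; the structure (paths, model
  switches, solver tolerances, seed) is validated before any computation,
  and every CLI run writes its resolved configuration plus a JSON log with
  package version and seed.
- Property dumps are a documented plain-text matrix container (geometry,
  masses, Hessian, optional dipole and packed polarizability gradients)
  with symmetry and dimension checks on read.
- Fragment membership is not stored separately in potential files; it is
  reconstructed from the exclusion lists. Cross-fragment exclusions, if a
  file declares them, are honored as written (they must be mutual).
- Parsers fail on unknown sections rather than warning: an embedding
  potential with unrecognized content is more likely corrupt than
  extended.

## Known limitations

- No electronic-structure coupling of any kind: fields from electrons,
  Fock-matrix contributions, and self-consistent core↔environment
  polarization are outside this package's scope by design.
- No Thole-style damping or screened tensors; closely spaced polarizable
  sites can make the response matrix ill-conditioned, which is reported
  as an error.
- Environment geometry is frozen: no forces on sites, no environment
  contribution to the vibrational problem beyond its effect on the core
  block.
- Anharmonicity, resonance Raman, anti-Stokes branches, and local-field
  corrections are not modeled.
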