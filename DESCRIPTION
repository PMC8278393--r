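Package: polembed
Title: Classical Polarizable-Embedding Energies, Derivatives, and Harmonic IR/Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical core of the polarizable-embedding (PE) environment model:
    Cartesian multi-index interaction tensors of arbitrary order, permanent-multipole
    electrostatics between an embedded point-charge core and a fragment-distributed
    environment (charges, dipoles, quadrupoles), induced-dipole environment
    polarization through a classical linear-response matrix, 6-12 Lennard-Jones
    interactions with Lorentz-Berthelot combination, and fully analytic first- and
    second-order geometric derivatives of every term. On top of the derivative stack
    it provides partial Hessian vibrational analysis (mass weighting, eigenanalysis,
    optional translation/rotation projection, mode filtering), double-harmonic IR and
    Raman intensities in the commonly reported unit conventions, Cauchy lineshape
    broadening, and snapshot averaging, together with readers and writers for the
    Dalton-style PE potential (.pot) dialect, XYZ geometries, Lennard-Jones parameter
    tables and plain-text property dumps, plus deterministic synthetic fixtures and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
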