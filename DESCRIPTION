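Package: memrod
Title: Meshless Membrane Simulation of Chiral Crescent Protein Rods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained, implicit-solvent simulation of fluid membranes as
    self-assembling particles with orientation vectors, together with embedded
    crescent-shaped protein rods of tunable spontaneous curvature and
    chirality (BAR-domain-like scaffolds). Provides Langevin-thermostat
    molecular dynamics with a zero-tension area ensemble, Hamiltonian replica
    exchange over the rod curvature, builders for membrane tubes, tensionless
    flat patches and tubulation protocols, observables (azimuthal and
    longitudinal Fourier shape and rod-density modes, helical-assembly radius,
    rod cluster statistics, vertical membrane span, tube-shape
    classification), and a calibration suite that measures and tunes the
    membrane's emergent elastic constants (bending rigidity, area per
    particle, area compression modulus, edge line tension).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'params.R'
    'core-geometry.R'
    'potentials.R'
    'rod-builder.R'
    'dynamics.R'
    'system-setup.R'
    'calibration.R'
    'observables.R'
    'fixtures.R'
    'io.R'
    'cli.R'
    'memrod-package.R'
    'remd.R'
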