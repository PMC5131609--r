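Package: coophyd
Title: Cooperative Hydration, Contact Energetics and Hydration-Site
    Thermodynamics from Simulation Snapshot Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses why a folded protein state is energetically favoured
    over an extended one, using snapshot ensembles from molecular dynamics
    (or synthetic stand-ins).  Provides a pairwise non-bonded energy kernel
    with CHARMM-style Lennard-Jones switching and minimum-image
    electrostatics, per-atom and per-group energy decompositions between
    states, geometric detection of direct hydrogen bonds, non-polar
    contacts and water-bridged (cooperatively hydrated) interactions with
    molecular-symmetry resolution and replicate persistence filtering, and
    inhomogeneous fluid solvation theory (IFST) hydration-site free
    energies via a nearest-neighbour entropy estimator in the combined
    translational-orientational space.  Seeded synthetic-snapshot
    generators with known statistical structure make every stage testable
    without trajectory downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
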