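Package: lipoplexr
Title: Physicochemical Design and Characterization of GapmeR-Loaded
    Catanionic Lipid Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk calculators and instrument-data analysis for the design of
    catanionic lipoplex nanoparticles assembled in tunable Bligh-Dyer
    (water/methanol/chloroform) solvents. Implements Bjerrum-length and
    Manning counterion-condensation design rules under composition-dependent
    dielectric permittivity, coarse-grained geometry and stoichiometry of the
    oligonucleotide/cationic-lipid lamellar phase, ternary solvent mixing and
    monophasic/biphasic classification against a binodal, synthesis-recipe
    mole accounting, dynamic light scattering cumulant analysis with
    Stokes-Einstein sizing, Smoluchowski zeta-potential conversion, and
    fitting of a damped-oscillatory lamellar structure-factor model to radial
    intensity profiles extracted from transmission electron micrographs.
    Seeded generators provide synthetic micrographs, correlograms and
    replicate tables with ground-truth records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    tiff,
    png,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
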