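Package: bridgestab
Title: Salt-Bridge Hallmarks and Thermal Stability of Bacterial Lipolytic Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Geometric detection of salt bridges in protein structures at a
    distance cutoff, Shrake-Rupley solvent-accessible surface area and burial
    classification, hallmark salt-bridge pattern profiling and subfamily
    assignment of bacterial lipolytic enzymes (family XV N-prime versus family
    XIII N and LipS-like), Poisson-corrected neighbor-joining phylogenies, and
    two-state thermal and chemical denaturation thermodynamics (melting
    temperature, van't Hoff enthalpy, Gibbs-Helmholtz extrapolation,
    linear-extrapolation chemical midpoints, and variant comparisons).
    Includes seeded synthetic-data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
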