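Package: puckermc
Title: Ring Puckering Coordinates and Monte Carlo Conformer Generation for
    5-, 6-, and 7-Membered Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the conformational analysis of small saturated ring
    molecules such as furanose-, pyranose- and septanose-like monosaccharides.
    Implements the Cremer-Pople puckering transform (amplitudes q_m, phases
    phi_m, and the Q/theta/phi polar coordinates of six-membered rings),
    catalogs of canonical ring conformers with IUPAC-style labels and
    nearest-conformer classification, construction of three-dimensional ring
    geometries and Gaussian Z-matrices for multifunctionalized rings, seedable
    pseudo-random (Monte Carlo) generation of conformer batches over ring
    conformations and exocyclic rotamers, and writers for Gaussian input, XYZ
    and PDB structure files plus AutoDock Vina docking-preparation manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
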