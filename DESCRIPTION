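Package: calmbind
Title: Binding Geometry and Spectroscopy of Calmodulin-Target Peptide
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of calmodulin (CaM)-target peptide
    complex structures and supporting biophysics. Reads multi-model PDB
    ensembles, computes least-squares (Kabsch) superpositions and
    RMSD-to-mean ensemble statistics, fits helix axes and inter-helical
    kink angles, decomposes rigid transforms into screw (axis, angle,
    pitch) form to quantify the pseudo-C2 arrangement of the two CaM
    domains about the bound peptide helix, maps intermolecular
    hydrophobic contacts and salt bridges, classifies hydrophobic-anchor
    binding modes (1-10, 1-14, 1-16, 1-18 families), computes normalized
    amide chemical-shift perturbations, and calibrates dynamic light
    scattering (hydrodynamic radius to molecular weight, double-log) and
    circular dichroism (two-state 222 nm helicity) measurements. Includes
    a deterministic synthetic-data module generating ideal and kinked
    helices, pseudo-symmetric toy complexes, shift tables and spectra
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
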