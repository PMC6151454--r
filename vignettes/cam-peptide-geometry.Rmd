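---
title: "Quantifying calmodulin-peptide binding geometry with calmbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calmodulin-peptide binding geometry with calmbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmbind)
```

## The problem

Calcium-loaded calmodulin (CaM) recognizes short amphipathic target
segments of its client enzymes — among them the CaM-binding peptide of
the phosphatase calcineurin (CaNp, residues 391-414 of the catalytic
subunit). In the canonical 1:1 complexes the peptide folds into an
alpha helix clamped between CaM's two EF-hand domains, and the
complexes are classified by (i) the spacing of the bulky hydrophobic
*anchor* residues buried in the two domain pockets (binding-mode
families 1-10, 1-14, 1-16, 1-18), (ii) the orientation of the peptide
relative to the domains, and (iii) the near-two-fold (pseudo-C2)
arrangement of the two homologous domains about the peptide helix.
`calmbind` implements the quantitative toolbox needed to make these
statements from multi-model solution-NMR coordinates, together with
the two desk-top biophysical calibrations that accompany such studies
(DLS size estimation and CD helicity estimation), and a synthetic-data
module that generates structures and spectra with exactly known ground
truth so that every stage is testable without any download.

## Ensemble statistics

`superpose()` computes the least-squares rigid superposition of paired
coordinate sets by the Kabsch/SVD construction with reflection
correction; it refuses fewer than three points or collinear sets.
`ensemble_rmsd_to_mean()` implements the standard iterative
mean-structure procedure: all models are fitted onto model 1,
averaged, then refitted onto the running mean until the mean moves by
less than 1e-6 Angstrom (50-iteration cap, warning on
non-convergence). The report is the per-model RMSD to the final mean,
its mean, and the n-1 standard deviation. Because model 1 seeds the
iteration, the result is deterministic. For independent copies of a
structure carrying isotropic Gaussian coordinate noise of sd sigma,
the expected RMSD-to-mean is `sigma * sqrt(3) * sqrt((m-1)/m)` for m
models; the test suite checks the implementation against this closed
form. A per-coordinate sd of 0.39 Angstrom therefore emulates a
20-model ensemble with a backbone RMSD-to-mean of about 0.66 Angstrom
— the precision class of a well-refined solution-NMR deposition — and
that value is what the acceptance script uses for its
ensemble-precision demonstration.

Calcium ions (HETATM records) are retained by the parser and are
selectable, but are excluded from RMSD selections unless
`include_het = TRUE`: published "all atom" ensemble statistics for
these complexes are heavy-atom statistics over the polypeptide ranges,
and the ion positions are restrained rather than measured. "Backbone"
expands to N, CA, C, O.

## Helix axes, kinks, and the screw description

`fit_helix_axis()` smooths the CA trace with the (1, 2, 1)/4 kernel —
`p_i = (CA_{i-1} + 2 CA_i + CA_{i+1}) / 4` — and takes the principal
axis of the centre points, oriented N-to-C. Two numerical points are
worth recording. First, the smoothing shrinks the helix radius by
`(1 + cos(100 deg)) / 2 ~ 0.41`, so for an ideal alpha helix (CA
radius ~2.3 Angstrom) the centre points still sit ~0.95 Angstrom from
the axis; `fit_rms` reports exactly this quantity and is not expected
to approach zero on perfect helices. Second, a plain line fit through
a helical arc covering a non-integer number of turns is tilted by the
unbalanced circular component — up to 1-2 degrees for 10-12 residue
segments, which matters when two such fits are subtracted to form a
kink angle. The fit therefore applies an exact de-biasing step: for an
ideal helix the *second differences* of the centre points are purely
centripetal (the axial coordinate is linear in residue index), so the
axis is recovered as the normal of their span whenever at least four
centre points exist and the points are not collinear. On ideal
geometry this recovers axis directions, and hence constructed kink
angles, to machine precision; under coordinate noise it degrades
gracefully because the normal is estimated by least squares over all
second-difference vectors.

`kink_angle()` fits independent axes to the CA runs on either side of
a nominated tether residue (the tether belongs to neither segment, by
convention) and reports the angle between the N-to-C directions.
`screw_decompose()` expresses any proper rigid transform in Chasles
form — rotation angle from the trace, axis from the rotation's fixed
direction, axis point chosen so the residual translation is parallel
to the axis — with near-identity rotations treated as pure
translations and the 180-degree case handled through the symmetric
part of the matrix. Decompose-then-recompose round-trips random
transforms to 1e-6, which the acceptance suite exercises 1000 times.

## Pseudo-C2 deviation of the two CaM domains

The two CaM domains are internally homologous, so a fixed
residue-number offset (default 73, pairing residues 5-72 with 78-145)
gives a deterministic CA correspondence without any structure
alignment; `interdomain_transform()` returns the least-squares
transform mapping the N-domain onto the C-domain through that
correspondence, and lists missing pairs when the correspondence is
broken. `c2_deviation()` then factors out an ideal two-fold: with
`R_ideal` the 180-degree rotation about the measured peptide helix
axis, the deviation is the rotation angle of `R_t * t(R_ideal)` — the
additional rotation, beyond the ideal C2, needed to superpose one
domain onto the other. This is the most literal quantitative reading
of "an additional rotation about the peptide axis". The simpler
alternative metric `|screw angle - 180|` is reported alongside for
transparency; when the screw axis coincides with the peptide axis the
two agree exactly, and the synthetic complex (below) is built so that
they do. Which peptide segment defines "the" helix axis of a kinked
peptide is genuinely open; the default uses the whole-peptide fit
(the kink is modest, 17 degrees, and the whole-peptide axis is the
stabler estimator), and per-segment fits remain available through
`fit_helix_axis()` on any CA subset. For ensembles the deviation is
computed per model and summarized as mean and sd
(`c2_deviation_ensemble()`). Angle estimates under coordinate noise
are non-negatively biased (axis errors of eta degrees on a 180-degree
rotation compose as 2*eta perturbations), so noisy-ensemble means run
1-2 degrees above the clean-geometry value at a 0.3 Angstrom noise
level; the package reports what it measures and does not correct for
this.

## Contacts, anchors, and binding modes

`heavy_atom_contacts()` aggregates heavy-atom pairs within a cutoff
(default 4.5 Angstrom, the standard proxy for NOE-observable
distances) into per-residue-pair records; `find_salt_bridges()`
restricts to Arg/Lys side-chain nitrogens against Glu/Asp side-chain
oxygens at a 4.0 Angstrom default. Both are checked exactly against
O(N^2) brute-force oracles in the tests. `identify_anchors()` calls a
peptide residue an anchor when a side-chain heavy atom of a
hydrophobic residue (Ile, Leu, Val, Phe, Met, Trp, Tyr, Ala —
alanine and methionine included because pocket inventories count
them) touches a hydrophobic receptor side chain; the number of
distinct receptor residues contacted ranks anchors major (>= 5 by
default) or minor. Contact counting is a documented proxy for the
NOE-abundance ranking used in spectroscopic work; the threshold is a
parameter, not a constant. `spacing_pattern()` turns anchor numbers
into one-based spacing indices (396/400/410/413 become 1-5-15-18),
labels the mode "1-K" from the last index, and reads the orientation
from which domain buries the first anchor (N-domain: parallel,
CaMKK-like; C-domain: antiparallel, M13-like). The ASCII hyphen is
used in labels for portability of the JSON and TSV outputs.

## Chemical-shift perturbation mapping

`compute_csp()` evaluates the standard normalized amide perturbation
`sqrt((dHN^2 + (dN/5)^2) / 2)` per residue, with the nitrogen
difference scaled by exactly 1/5 (the convention used in the source
shift analysis; gyromagnetic-ratio-based alternatives near 1/6.5
exist but are deliberately not substituted). The mean over all
doubly-assigned residues defines the 2x and 3x flagging thresholds.
`perturbed_regions()` reports maximal runs of consecutive flagged
residues, bridging a gap of exactly one residue only when that
residue is absent from the records — unassigned prolines and
overlapped peaks routinely punch one-residue holes in amide maps, and
a present-but-cold residue must break a run. The bridging is
switchable. Reproducing a particular published mean perturbation
requires the exact free-state peak list used there, which is not part
of public depositions; the module therefore treats the mean as
data-dependent output, not as a constant to match.

## DLS and CD calibrations

`fit_loglog_calibration()` performs ordinary least squares of
log10(Mr) on log10(RH) over all standards; `estimate_mr()` evaluates
the line and warns outside the standards' radius range. The full-fit
line is used rather than piecewise interpolation between bracketing
standards: on the four standards printed for this system (BSA 6.75 nm
/ 67 kDa, CaM 2.44 / 16.7, lysozyme 2.20 / 14.7, ubiquitin 1.7 / 8.4)
the full fit evaluated at 2.61 nm gives 17.4 kDa, consistent with the
published 17.2 kDa estimate, while bracketing interpolation gives
about 18.3 kDa; the choice is recorded in the report.

`estimate_helix_fraction()` is a deliberate two-state replacement for
web-service spectrum deconvolution (which cannot be reimplemented from
a methods section): the helix fraction is read linearly from the
222 nm molar CD coefficient between a full-helix and a full-coil
reference (defaults -11.1 and -0.3 per residue, common literature
conventions), clamped to [0, 1]. Spectra recorded per mole of protein
are converted with the user-supplied residue count. The two-state
estimate carries the usual caveats (no beta/turn classes, chain-length
dependence of the helix limit is ignored); it is exact on synthetic
two-state mixtures, which is what the tests assert, and it reproduces
the ~71% / 17-residue helicity arithmetic of a 24-residue peptide.

## The synthetic-data module

`build_ideal_helix()` places N, CA, C, O and CB from ideal internal
coordinates (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; trans
peptide; phi/psi configurable per residue), so fixtures are
bit-reproducible. `build_kinked_helix()` applies an exact rigid
rotation of the C-terminal part about an axis through the tether CA
perpendicular to the N-segment axis — the constructed bend is the
ground truth that `kink_angle()` must recover. `make_toy_complex()`
assembles the full study geometry: a kinked anchor-bearing peptide,
one Leu pocket residue placed 3.8 Angstrom outside each anchor CB, a
spectator Ser helix completing a 30-residue domain A, and domain B as
the exact image of domain A under a screw of 180 + `c2_twist` degrees
about the fitted peptide axis (pockets for C-half anchors are
pre-imaged through that screw so they end up lining the C-half). By
construction the interdomain transform *is* the screw, so the
pseudo-C2 deviation equals the twist exactly at zero noise — the
strongest possible oracle for the symmetry analysis. Per-model
Gaussian coordinate noise is the only stochastic element; all
generators are pure functions of (parameters, seed), with the RNG
stream order documented.

What the toy deliberately does not emulate: EF-hand chemistry, real
side chains beyond CB, anisotropic or position-dependent coordinate
uncertainty (real NMR ensembles are tighter in the core than at
termini, and looser in side chains than backbone — the toy's
heavy-atom and backbone RMSDs coincide), or physically packed
interfaces. Passing tests on the toy therefore demonstrate the
correctness of the geometry, contact and classification code, not the
biology of any particular deposition. Analyses of deposited
ensembles (e.g. the solution structure of the CaM/CaNp complex and
its crystal-form counterpart) run through exactly the same module
surface via `parse_structure()`, but require the coordinate files to
be supplied by the user; no network access is assumed anywhere.

`simulate_shift_tables()` draws free-state amide shifts from typical
ranges and adds background noise (sd 0.02 ppm in HN, five-fold in N)
plus fixed-magnitude random-sign offsets (six-fold background by
default) inside nominated hotspot ranges; at these defaults the
separation between hotspot and background perturbations is large
enough that 3x-mean region recovery is essentially seed-independent.
`simulate_cd_spectrum()` mixes Gaussian-band helix and coil basis
spectra rescaled so their 222 nm values equal the two-state reference
coefficients exactly, making mixture recovery an identity check.

## Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| contact cutoff | 4.5 | Angstrom | heavy-atom proxy for NOE-observable distances (< ~5) |
| salt-bridge cutoff | 4.0 | Angstrom | conventional N-O limit |
| anchor major threshold | 5 | receptor residues | separates pocket-filling from grazing anchors |
| helix phi window | [-100, -30] | degrees | permissive, keeps curved solution helices |
| helix psi window | [-80, -5] | degrees | idem |
| minimum helical run | 4 | residues | one turn |
| correspondence offset | 73 | residues | pairs the homologous EF-hand cores 5-72 / 78-145 |
| mean-structure tolerance | 1e-6 | Angstrom | deterministic convergence |
| N shift scaling | 1/5 | — | source convention for normalized amide perturbation |
| CD references at 222 nm | -11.1 / -0.3 | M^-1 cm^-1 per residue | literature two-state conventions |
| ensemble-emulation noise | 0.39 | Angstrom | reproduces ~0.66 Angstrom backbone RMSD-to-mean at 20 models |

## Problem sizes

The test suite and the acceptance script run entirely at desk scale:
24-residue peptides, 30-residue toy domains, ensembles of up to 20
models, 148-residue shift tables, 100 superposition oracle cases and
1000 screw round-trips — a few seconds end to end. These sizes are the
package's own choice of demonstration scale; all operations are
vectorized over atoms and run comfortably on full-size complexes
(a CaM/peptide complex is ~2500 atoms).

## Known limitations

- mmCIF, NMR restraint files and full NMR-STAR are out of scope; the
  shift reader accepts simple delimited tables only.
- Insertion codes are rejected rather than handled (none occur in the
  depositions this toolbox targets).
- The two-state CD estimator is not a substitute for multi-basis
  deconvolution when beta content is non-negligible.
- The fixed-offset domain correspondence presumes the two-domain
  EF-hand architecture; it is a parameter, not a detected quantity.
- Validation against deposited coordinate ensembles is an
  integration-level exercise requiring user-supplied files; the
  packaged tests validate against constructed ground truth instead.

## Worked example

```{r example}
params <- toy_complex_params(c2_twist = 17, n_models = 1L)
ens <- make_toy_complex(params)
report <- analyze_complex(ens, receptor_chain = "R", peptide_chain = "P",
                          n_domain_range = c(1, 30),
                          c_domain_range = c(101, 130),
                          peptide_range = c(1, 24),
                          split_residue = 13, offset = 100)
report$symmetry$c2_deviation
report$binding_mode$mode_label
report$kink$mean
```
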