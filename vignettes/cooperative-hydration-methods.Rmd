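---
title: "Contact energetics and hydration-site thermodynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact energetics and hydration-site thermodynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coophyd)
```

# The scientific question

Why is the folded (native) state of a small protein such as the villin
headpiece subdomain energetically favoured over an extended conformation?
The classical answer weighs two kinds of intramolecular interaction —
direct hydrogen bonds and hydrophobic (non-polar) contacts — against the
protein–water interactions they displace.  `coophyd` implements an
analysis of a third mechanism alongside those two: *cooperative
hydration*, in which a single surface water simultaneously hydrates two
polar protein atoms that are too far apart for a direct hydrogen bond.
The package decomposes non-bonded energies between two states of the same
system, detects and filters the three contact classes geometrically, and
quantifies individual hydration sites with inhomogeneous fluid solvation
theory (IFST).

The analysis operates on snapshot ensembles.  In production use those come
from molecular dynamics; here every stage is exercised end-to-end on
seeded synthetic ensembles with known statistical structure, which is what
the test suite and the acceptance script run on.

# Energy model

All energies are non-bonded pairwise sums in kcal/mol:

$$E_{ij} = \frac{C\,q_i q_j}{r_{ij}} +
  \varepsilon_{ij}\!\left[\left(\frac{r^{min}_{ij}}{r_{ij}}\right)^{12}
  - 2\left(\frac{r^{min}_{ij}}{r_{ij}}\right)^{6}\right] S(r_{ij})$$

with $C = 332.0636$ kcal·Å/mol/e², Lorentz–Berthelot combination
($\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$,
$r^{min}_{ij} = r^{min}_i/2 + r^{min}_j/2$), and $S(r)$ the CHARMM-style
switching function taking the Lennard-Jones term smoothly to zero between
9.0 and 11.0 Å (switching applies to dispersion only).  Distances use the
minimum image convention in orthorhombic boxes.  All 1–2, 1–3 and 1–4
bonded pairs are excluded, derived from the bond graph at topology
construction.

**Electrostatics are direct pairwise sums, not mesh Ewald.**  Attributing
energy to individual atoms or atom groups is only well defined for a
pairwise-decomposable form; a reciprocal-space term has no per-pair
attribution.  Dynamics engines use PME to *generate* ensembles — the
decomposition analysing them uses the direct sum, optionally with a hard
electrostatic cutoff (`energy_options(elec_scheme = "direct_cutoff")`).
The scheme is recorded in output metadata.

The central kernel is the half-weighted group energy

$$E_{\mathrm{group}} = \tfrac12 \sum_{i \in \mathrm{set}}
  \sum_{j \neq i}^{N} E_{ij},$$

used for whole-state totals (set = all atoms), per-atom energies (a
singleton set), and per-contact energies (the contact's atom set).  With
the ½ convention, pairs internal to the set count once and pairs with the
environment count at half weight; summing the singleton energies over all
atoms recovers the system total exactly, which the tests assert at
relative tolerance 1e-9.

Per-atom differences between states are partitioned into polar and
non-polar atoms at $|q| \ge 0.3\,e$.  The absolute value matters: carbonyl
oxygens carry $q \approx -0.51\,e$ and must classify polar for the
partition to separate hydrogen-bonding groups from aliphatic/aromatic
ones.  The partition is exhaustive and exclusive by construction.

Bonded terms (harmonic bonds and angles, periodic dihedrals, harmonic
impropers; CHARMM k-convention without ½ prefactors) are provided for
internal-consistency bookkeeping only; cross-terms such as CMAP are not
implemented, so absolute bonded magnitudes of real force fields are out of
scope.

# Contact definitions

All boundaries are inclusive exactly as worded ("3.2 Å or less", "130° or
more"), with a numerical guard of 1e-9 Å / 1e-6° so geometries constructed
exactly on a boundary classify inclusively regardless of floating-point
rounding — far below the ±1e-3 Å / ±0.1° resolution at which the
boundaries are probed.

* **Hydrogen bond**: donor heavy atom (N/O with a bonded hydrogen) and
  acceptor (N/O with a declared available lone pair) within 3.2 Å, with a
  donor–H–acceptor angle ≥ 130° for some donor hydrogen.  Acceptor status
  cannot be derived from the element alone (histidine tautomers, proline
  backbone nitrogen), so the topology declares it.
* **Non-polar contact**: two carbon/sulfur atoms, neither bonded to
  oxygen or nitrogen, within 4.5 Å — approximately the distance at which
  the pair dispersion well is at 75 % of its depth.  Same-residue and
  1–2/1–3/1–4 pairs are excluded.
* **Cooperatively hydrated interaction**: two donor/acceptor atoms
  separated by 3.2–6.0 Å (the floor keeps direct-hydrogen-bond territory
  out), a single water oxygen within 4.0 Å of both, a donor–H–waterO
  angle ≥ 90° for each donor partner, and an acceptor-side angle ≥ 90°
  for each acceptor partner.

The acceptor-side angle involves three atoms — the acceptor, the heavy
atom bonded to it, and the water oxygen — and its vertex had to be fixed
by a design decision.  With the vertex at the bonded heavy atom, carbonyl
geometries give angles of 20–40° and the criterion would essentially
never pass; with the vertex at the *acceptor* (the angle between the
acceptor→bonded-heavy bond and the acceptor→water direction), typical
bridging geometries give 100–130°, and a symmetric two-carbonyl
construction (partners 5.0 Å apart, water equidistant at 3.0 Å) gives
≈123°.  The package uses the acceptor vertex: the water must sit on the
lone-pair side, which is also where acceptors are chemically hydrated.

When several waters satisfy the bridge distances, the water minimising the
sum of the two oxygen distances defines the record for that frame and the
angle criteria are evaluated with that water only; a pair therefore counts
at most once per frame.

## Molecular symmetry and persistence

Chemically indistinguishable atoms (carboxylate OD1/OD2 and OE1/OE2,
guanidinium NH1/NH2 and its four hydrogens, ammonium HZ1/HZ2/HZ3,
aromatic CD and CE ring pairs, LEU/VAL methyl pairs, C-terminal OT1/OT2,
water H1/H2) are grouped by built-in residue templates.  A contact's
identity is the unordered pair of symmetry slots (hydrogen bonds stay
directional: donor slot, acceptor slot); it exists in a frame if *any*
alternative passes, and the alternative with the shortest defining
heavy-atom distance names the atoms for that frame.

*Persistence* is the mean count per frame, averaged over replicate
ensembles, with the sample standard deviation across replicates.  For
hydrogen-bonded and water-bridged contacts the frame count is 0 or 1; for
non-polar contacts it is the number of alternative pairs passing
simultaneously, so persistence can exceed 1 (two ring carbons both inside
4.5 Å count twice).  A contact is *persistent* when its mean is strictly
greater than 0.5.  Persistent contacts are selected on the native-state
replicates only and then evaluated — same atom sets, per-frame symmetry
resolution — in both states; the energy difference
$\Delta E = E_{\mathrm{native}} - E_{\mathrm{extended}}$ is negative when
the contact favours the native state.

The atom sets entering the group-energy kernel are: donor + its passing
hydrogen + acceptor + the atoms bonded to the acceptor (hydrogen bonds);
the two heavy atoms plus their bonded hydrogens (non-polar); per polar
partner, donor heavy atom + its hydrogen, or acceptor heavy atom + its
first bonded heavy atom (water-bridged).  The bridging water itself is
excluded from the set — it is part of the environment in both states, and
including it would make the extended-state reference ill-defined.

# IFST hydration sites

Hydration sites are found by greedy density clustering of water-oxygen
positions over a fixed-solute ensemble: observations are ranked by their
neighbour count within 1.0 Å (minimum image); the densest is accepted as
a site center and its members removed; accepted centers must lie ≥ 2.4 Å
apart; clustering stops when the best remaining candidate would be
occupied in fewer than half the frames.  Only sites within 4.1 Å of a
protein heavy atom are kept when a protein is present.  Site membership
uses the same 1.0 Å radius, so a site holds at most one water per frame
and the effective occupation $n$ equals the occupied-frame fraction.

Per site, with a bulk reference $(E_{\mathrm{bulk}},\,-TS_{\mathrm{bulk}})$
for the matching water model and salt concentration:

$$\Delta E = E_{\mathrm{site}} - n\,E_{\mathrm{bulk}}, \qquad
  \Delta S = S_{sw} - n\,S_{\mathrm{bulk}}, \qquad
  \Delta G = \Delta E - T\,\Delta S,$$

where $E_{\mathrm{site}}$ is the mean *full* water–environment interaction
of the occupying water (no half-weighting, matching the bulk convention),
the water–water correlation term is assigned zero, and $T = 300$ K with
$R = 1.9872 \times 10^{-3}$ kcal/mol/K.  The bundled bulk table covers
TIP3P at 0–200 mM NaCl and TIP4P-2005 at 0 mM; each row satisfies
$G = E - TS$ within the 0.15 kcal/mol that three values printed at 0.1
resolution can accumulate (one row differs by exactly 0.1).

## The nearest-neighbour entropy estimator

$S_{sw}$ uses a k-nearest-neighbour estimator (k = 1) in the combined
translational–orientational space.  Each water observation is a position
(Å, minimum image) plus an orientation quaternion relative to a fixed
reference water (oxygen at origin, H–O–H bisector along +z, molecular
plane xz, H1 on +x); the metric is

$$d_{\mathrm{total}}^2 = d_{\mathrm{trans}}^2 + d_{\mathrm{orient}}^2,
\qquad d_{\mathrm{orient}} = 2\arccos |q_1 \cdot q_2|,$$

and

$$S_{sw} = n R \left[\frac{1}{nF}\sum_{i,j}
  \ln\!\frac{\pi\, d^6_{\mathrm{total}}\, nF}{48\, V_i} + \gamma\right].$$

The constant 48 encodes an orientation-space volume convention: writing
the 6-ball volume $\pi^3 d^6/6$ against a total space volume
$V_i \cdot \Omega$, the formula corresponds to $\Omega = 8\pi^2$ — the
volume of the full rotation group under the $2\arccos|\cdot|$ metric.
Two consequences follow and are enforced by tests rather than assumed:

* **Water-symmetry folding is off by default.**  Folding the H1/H2
  exchange (a π rotation about the bisector) into the metric halves the
  orientation volume and would shift a uniform sample to $-R\ln 2$
  instead of zero.  The homogeneous zero point is the authoritative
  calibration, and it selects the unfolded metric.
* **The estimator is exactly the zero of a homogeneous sample** (uniform
  positions, Haar-uniform orientations) up to two finite-sample effects:
  the usual $O(M^{-1/2})$ noise, and a positive curvature bias because a
  geodesic ball in the rotation group is smaller than its Euclidean
  6-ball approximation when nearest-neighbour distances are of order 1
  radian.  The calibration tests therefore sample 5000 single-water
  frames in a 6 Å box, a density at which combined nearest-neighbour
  distances stay well inside the locally-Euclidean regime; the measured
  zero point is ≈ 0.02–0.07 R, asserted at |S| ≤ 0.1 R.  At hydration-site
  confinement (sub-ångström scatter) the bias is negligible, which the
  Gaussian closed-form check confirms at < 1 % error.

Same-frame observations are excluded from the neighbour search (two
waters in one frame are correlated); zero-distance neighbours (duplicated
observations) are dropped with a warning rather than propagating
$-\infty$; fewer than two usable observations is an error.  For k > 1 the
Euler-constant bias correction generalises to $-\psi(k)$.

Three closed forms calibrate the estimator end-to-end: the homogeneous
zero point; an isotropic Gaussian ($\sigma = 0.25$ Å) against the analytic
entropy $R[\tfrac32\ln(2\pi e\sigma^2) - \ln V]$ within 5 %; and the
$-R\ln 2$ shift when the accessible volume is halved at fixed system
volume.  The volume-halving check realises "half the volume" as a periodic
half-box with the frame volume held at the full box: a sharp sub-slab of a
larger box would add a density-discontinuity boundary bias (~0.07 R at
these sample sizes) that the periodic construction removes.

# The synthetic generators

The generators produce the study conditions under which the pipeline is
validated; their defaults are fixed once and are not tuned to test
outcomes.

* `gen_uniform_water_box()` — rigid waters (exact TIP3P or TIP4P-2005
  geometry: O–H 0.9572 Å, H–O–H 104.52°, lone-pair site 0.1546 Å at
  52.26°) with uniform positions and Haar-uniform orientations
  (Shoemake's subgroup algorithm).  The entropy zero point and the
  Poisson spacing check run on this.
* `gen_gaussian_sites()` — one water per planted site per frame with
  isotropic Gaussian scatter; the clustering-recovery and closed-form
  entropy oracles.  Site centers closer than 2.4 Å are rejected.
* `gen_two_state_toy()` — a 16-atom solute with a planted hydrogen bond
  (amide N–H to carbonyl O at 2.9 Å, collinear), a planted non-polar
  contact (two neutral methyl groups at 4.0 Å, hydrogen fans aligned so
  the group dipoles interact head-to-tail), and a planted water bridge
  (two carbonyl oxygens 5.0 Å apart, the bridging water oriented to
  donate a hydrogen toward each).  The extended conformation separates
  the same groups by ~10 Å or more with an identical particle inventory;
  free waters are placed uniformly, rejected within 4.0 Å of the solute.
  Per-frame Gaussian jitter (0.02 Å) keeps frames distinct without
  crossing any criterion boundary.  All three planted contacts lower the
  compact-state group energies by construction.
* `gen_bernoulli_contacts()` — donor/acceptor pairs rendered in-criteria
  with probability *p* per frame across independent replicates (default
  40 × 100 frames, the study's replicate structure); the persistence
  filter's oracle, with binomial concentration setting the tolerance
  (3σ ≈ 0.023 at 4000 frame-observations).

What the synthetics deliberately do *not* emulate: thermodynamically
realistic water structure (no equilibration — synthetic site energies sit
near zero, so synthetic ΔG values are dominated by the bulk-reference
offsets and are not comparable to real hydration sites), protein
flexibility, and correlated contact dynamics.  Passing tests demonstrate
the correctness of the machinery — kernels, detectors, estimators,
bookkeeping — not the realism of any force field.

# Reference tables and worked aggregates

The package ships curated per-contact and per-state reference values for
the villin headpiece subdomain (N68H, PDB 1YRF) under
`inst/extdata/villin_*.tsv`: state-energy components, the atom-energy
partition for four force-field/water/salt treatments, the fifteen most
persistent contacts of each class for the CHARMM22/TIP3P/NaCl treatment,
the contact census, hydration-site summaries, the GLU45/LYS48
bridged-site free energies, and folding calorimetry (ΔH = −31 kcal/mol at
Tm = 74.4 °C, Cp = 0.374 kcal/mol/K).  The aggregation layer reproduces
their printed summaries — mean ΔE of −1.1 (hydrogen bonds), −0.5
(non-polar), −0.2 (water-bridged) kcal/mol, a total state-energy
difference of −36.1 kcal/mol, and a 25 °C folding enthalpy of
−12.5 ≈ −13 kcal/mol — as arithmetic on bundled inputs.  Regenerating the
absolute magnitudes would require the original 40 × 10 ns trajectories,
which is why they are inputs here, not outputs.

# Problem sizes and determinism

The test suite and acceptance script run at sizes chosen to make every
statistical tolerance comfortable on a single CPU: 5000 observations for
entropy calibrations, 40 × 100 frames for persistence recovery, 400
frames for site clustering, 15-frame/10-water toys for contact
energetics.  All randomness flows through explicit seeds; identical
configurations produce byte-identical outputs, which the pipeline tests
assert file-by-file.

# Known limitations

* Direct-sum electrostatics mean decomposed totals need not match a PME
  engine's totals term-for-term; only pairwise-attributable quantities
  are reported.
* The entropy estimator's rotation-group curvature bias is positive and
  density-dependent; at very sparse sampling (nearest-neighbour
  orientation distances approaching π/2) the zero point drifts upward.
  Site-level confinement is far from that regime.
* S_ww is assigned zero throughout; solute entropy and protein motion are
  out of scope (fixed-solute ensembles).
* Multiple simultaneous bridging waters count as one interaction per
  polar pair per frame; the alternative (counting each bridge) is not
  implemented.
* Acceptor lone-pair availability must be declared in the topology; no
  protonation-state or tautomer assignment is attempted.
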