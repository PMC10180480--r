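---
title: "Models and methods behind sheetkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sheetkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetkit)
```

`sheetkit` models a DNA nanosheet assembled from a three-strand F-unit:
one core duplex (default 21 bp, strands A:B), four arm duplexes (16 bp,
against copies of strand C) and four 10-nt sticky ends that crosslink
units into a porous two-dimensional lattice.  This vignette explains the
models, the tunable parameters and the numerical and design choices, in
the order a user meets them.

## The F-unit and its strand architecture

The package fixes a canonical strand layout: strand A reads
5′–SE1–arm–core–arm–SE2–3′, strand B reads 5′–SE1\*–arm–core\*–arm–SE2\*–3′
(asterisks are reverse complements), and the four identical C strands are
the reverse complement of the common arm segment.  This layout yields
exactly one core, four arms and four sticky ends per unit, and puts the
C-strand 3′ termini — the cholesterol attachment points — at the *distal*
end of one arm per junction and at the *proximal* (junction) end of the
other, which is what makes the lattice's minimum and maximum anchor
spacings differ (sticky-end bridge ≈ 3.4 nm versus arm–SE–arm bridge ≈
14.3 nm for the defaults).  `validateDesign()` checks all domain
complementarities and the stoichiometry rule m = n = p/10 (four C strands
serve each A:B pair, supplied in excess), reporting failures rather than
throwing, so designs under construction can be inspected.

No reference sequences ship with the package; `makeDesignSequences()`
draws GC-balanced placeholder domains deterministically from a seed.
Every sequence-dependent result in the documentation uses such
placeholders, and the tests assert only sequence-independent structure
(complementarity, melting-temperature *ordering*) rather than absolute
values tied to any particular sequence.

## Melting temperatures and assembly order

`duplexTm()` implements the two-state nearest-neighbor model with the
unified SantaLucia-type DNA parameter table (dinucleotide
enthalpies/entropies plus terminal initiation terms and a symmetry
correction for self-complementary duplexes):

$$T_m = \frac{1000\,\Delta H}{\Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]_{eq} + R \ln(C_T/4)} - 273.15$$

with $\Delta H$ in kcal/mol, $\Delta S$ in cal/(mol K), $C_T$ the total
strand concentration (default 1 µM) and $R$ = 1.987 cal/(mol K).
Divalent cations fold into an equivalent monovalent concentration by the
common heuristic $[\mathrm{Na^+}]_{eq} = [\mathrm{Na^+}] +
120\sqrt{[\mathrm{Mg^{2+}}]\,(\mathrm{mM})}$ mM — adequate for ordering
questions, not for high-accuracy prediction in strongly Mg-dominated
buffers.  The tests pin the implementation to reference values computed
with an independent implementation of the same table, to 0.1 °C.

Hybridization is modelled as a sharp threshold: a domain binds at the
first moment the annealing schedule reaches its $T_m$.  There are no
kinetics; the model exists to express the design's hierarchy (core →
arms → sticky ends) against the five built-in schedules.  Ramps written
as "−1 °C / 5 min" expand into 1-degree 5-minute holds, which preserves
total protocol time exactly.

## Junction geometry: why (80°, 150°, 120°) cannot be planar

`buildIdealFUnit()` realizes three unit arm vectors per junction with
*exact* pairwise angles via Gram-matrix factorization: e3 is the core
direction, e1 lies in the sheet plane at α₁₃ from it, and e2's
out-of-plane component follows from the two remaining constraints.  A
planar vector triple must have sector angles summing to 360°; the default
angles (80, 150, 120) — the equilibrium values a relaxed junction adopts —
sum to 350° and therefore admit *no* planar realization.  The builder
honors the angles exactly and accepts the small out-of-plane pucker they
imply: the resulting junction has planarity `d_p ≈ 0.159`, consistent
with the `d_p ≈ 0.2` a relaxed unit fluctuates around.  Planar-consistent
angle sets (e.g. (90, 150, 120)) produce an exactly planar model with
`d_p = 0`.  Angle sets with no unit-vector realization raise an error.

The planarity metric itself, `planarityDp()`, is the distance from the
junction point to the plane through the tips of the three unit arm
vectors.  It is dimensionless by construction, zero for coplanar arms,
and equals sin(φ) exactly when all three arms share an out-of-plane
elevation φ — the identity the test grid checks to 1e-9 against an
independently coded plane-solve oracle.

Two junction-point definitions are provided because the metric
literature leaves the choice open: the **centroid** of the three proximal
base-pair midpoints (default for `junctionPosition()`; simple, robust to
missing arms, biased by ~0.1 nm toward the arm bisector) and the
least-squares **intersection of the three arm axes** (default for
`poreQuadrilateral()`; recovers idealized corner points exactly, which is
why pore diagonals on synthetic data match closed forms to 1e-6 nm).
Arm axes are total-least-squares lines through base-pair midpoints with
no end-trimming; fraying is not modelled, so users analyzing real
trajectories may want to drop terminal pairs from the index maps.

## Pore lattice closed forms

With side contours `arm + SE + core + arm` = 63 bp and `arm + SE + arm` =
42 bp, a rise of 0.34 nm/bp, and junction angle θ, the pore parallelogram
has diagonals $\sqrt{a^2+b^2\pm 2ab\cos\theta}$ — 27.73 and 23.59 nm at
θ = 80°.  Corner-plane planarity follows the neighbor-triple
construction: the plane of corner X passes through (W, X, Y), and the six
pairwise angles between unit normals (unsigned, folded to [0°, 90°],
computed with atan2 to stay accurate near coplanarity) are all zero for
a planar quadrilateral.  The neighbor-triple plane is one of several
possible readings of "the plane through each corner"; it is the one that
makes a planar quadrilateral give exactly 0° and a regular tetrahedron
give arccos(1/3) ≈ 70.5° for every pair, both of which are frozen tests.

Porosity uses a strip-ownership argument: each unit cell (area
$ab\sin\theta$) owns one strip of duplex of width w along a long side and
one along a short side, minus their corner overlap, giving
$\varphi = 1 - ((a+b-w)\,w)/(ab\sin\theta)$ — 77.6 % for the default
design at θ = 80° and w = 2 nm.  This counts the outward arms' area as
belonging to neighboring cells' strips and ignores sticky-end
single-strandedness; it is an idealized upper-tier estimate whose role is
the qualitative bound (φ well above 40 %), not a segmentation of AFM
images.

## Interfacial mechanics

The extrapolation `E = 2(1+ν)·G′/t` is the standard isotropic
shear-to-Young relation applied to an interfacial modulus spread through
a sheet of thickness t.  The package defaults ν = 0.5 (incompressible)
and t = 2 nm (one duplex diameter, the single-layer AFM thickness), which
maps 300 mN/m to 450 MPa; these two values are a reconstruction — the
chain they form is unique among standard relations in reproducing that
mapping — and both are explicit `ExtrapolationParams` a user can change.
The porosity correction `E/(1−φ)` rescales by the load-bearing area
fraction and is reported as a lower bound ("at least"), because real
load paths through a porous lattice are less efficient than uniform
dilution assumes.  Phase plateaus of a time sweep are trailing-window
means (default last 25 % of each phase), since published staging reports
single plateau values without a windowing rule.

## What the synthetic generators emulate — and what they do not

The generators exist so the analysis code can be tested against known
ground truth at desk scale; they are statistical emulations, not
simulators — no forces, no thermostat, no sequence-dependent mechanics.

* **F-unit snapshots** place each base pair's two beads on a helix
  (34.3°/bp, 0.7 nm pair separation) about straight duplex center-lines,
  so pair midpoints lie exactly on the axis, paired a1 versors are
  exactly anti-aligned, and neighboring pairs differ by the helical
  twist.  The twist matters: it is what lets geometric base-pairing
  (centers within 1.2 nm *and* a1 anti-alignment within 30°) distinguish
  true partners from offset-by-one neighbors, as it does in the real
  coarse-grained geometry.  Sticky ends are single-stranded center-line
  beads with axis-aligned a1, so they can never satisfy the
  anti-alignment criterion — the pairing tests' negatives.
* **Uniform tilt** raises each junction's three arm directions onto a
  cone at elevation ±φ (positive at one junction, negative at the other,
  keeping the shared core direction consistent), so the injected tilt is
  recoverable exactly as `d_p = sin φ`.  A naive rotation of arms about
  the core axis would not have this property.
* **Relaxation trajectories** follow
  $\varphi_k = \varphi_{eq} + (\varphi_0 - \varphi_{eq})e^{-t_k/\tau} +
  \varepsilon_k$ with defaults φ₀ = 60°, φ_eq = arcsin(0.2) ≈ 11.5°,
  τ = 10 τ_B, 200 frames at 1 τ_B spacing and 1° tilt noise — an
  equilibrium-approach shape with realistic late-time fluctuation, *not*
  dynamics.  Frame 0 sits at φ₀ for any τ because exp(0) = 1.
* **Pore snapshots** are geometry-first: four corner junctions in a
  parallelogram, each side one straight duplex chain of the correct
  contour, plus outward arms, using a per-segment strand decomposition
  rather than the full strand architecture of four interlocked units.
  All pore metrics consume index maps and midpoints, so this
  simplification is invisible to them.  Distortion folds the sheet about
  the X–Z diagonal (whole base pairs move together), which perturbs the
  corner-plane normals in a closed-form-checkable way.
* **Height profiles** are plateau segments at integer multiples of the
  2 nm duplex layer height with Gaussian pore dips at fixed spacing plus
  height noise; **rheology sweeps** are piecewise plateaus with sigmoidal
  transitions (2 % of phase duration) and multiplicative log-normal
  noise.

Passing recovery tests on these artifacts demonstrates that the analysis
chain is correct and unbiased under its own assumptions.  It does not
demonstrate robustness to what real data add: junction fraying,
sequence-dependent flexibility, drift and tip convolution in AFM scans,
or instrument drag in rheology.

## Numerical choices and degenerate inputs

* Angles are computed with atan2 of cross/dot magnitudes (accurate near
  0° and 180°); outputs are degrees, internals radians.
* oxDNA files are written at full double precision (`%.17g`), so
  read/write round trips are bit-stable; velocities are optional on read
  (9- or 15-column rows) and written as zeros when absent.
* Nucleotide indices are 1-based in R objects and 0-based in files
  (−1 = no neighbor), converted at I/O.
* Degenerate inputs error early with named locations: collinear arm tips
  ("degenerate plane"), coincident midpoints, truncated trajectory
  frames (by frame index), ambiguous geometric pairings (by nucleotide
  indices), empty sweep phases.
* Peak detection uses local maxima with a prominence criterion (default
  half a duplex layer, 1 nm); pores are detected as dips by running the
  detector on the inverted profile.  Plateau heights are medians over
  the central 40 % of each segment, keeping pore walls out of the layer
  quantization.
* Every generator runs on a private RNG stream seeded explicitly; the
  caller's RNG state is untouched and identical seeds give byte-identical
  files.

## Problem sizes in the test suite

The suite runs at desk scale by design: single F-units are 210
nucleotides and pores 548; relaxation recovery uses 200-frame
trajectories over 10 seeds; oracle-equivalence loops use 1000 random
tripods; melting-order and monotonicity properties use 100 random
GC-balanced designs; rheology recovery uses 3–4 phases of 360 samples
over 10 seeds.  These sizes make every property statistically meaningful
while keeping the full suite near a minute on one CPU.

## Known limitations

* The melting model is two-state and salt-heuristic; no mismatches,
  dangling ends, or secondary-structure competition (sequence design
  itself — partition-function tools — is out of scope).
* The lattice closed forms assume straight duplexes; a 63-bp side is
  about half a persistence length, so real sides bow and measured
  diagonals sit slightly below the rigid-geometry values.
* Porosity and the modulus corrections are area-fraction arguments, not
  finite-element mechanics.
* No 2-D image processing: AFM input is a 1-D extracted profile.
* The oxDNA reader handles the classic text dialect only (no oxView
  JSON, no binary trajectories) and no energies/forces are interpreted.
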