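---
title: "Methods: NMR restraints and micelle-bound ensemble analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR restraints and micelle-bound ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmicelle)
```

## Scope and model

`pepmicelle` analyses conformational ensembles of small disulfide-bridged
peptides — vasopressin-like nonapeptides and their d-residue analogues — in
membrane-mimetic micelle environments.  It consumes ensembles (multi-model
PDB or XYZ, optionally with a cubic periodic box); it does not propagate
dynamics.  The pipeline has three stages: conversion of NMR observables into
restraints and classifications, conformational statistics over the ensemble,
and solvation/micelle-contact statistics in the periodic box.

Chirality is a first-class concept throughout.  d-amino acids occupy the
mirror region of the Ramachandran map (φ, ψ → −φ, −ψ), so every rule that
depends on backbone geometry — coupling-constant inversion, turn templates,
the synthetic builder — carries an explicit l/d tag per residue, and every
mirror property is tested (the all-d build of a sign-negated torsion set is
the *exact* reflection of the l build; turn typing commutes with reflection
through the primed-type partner map).

## NMR observables to restraints

**Couplings.**  ³J(HN–Hα) reports on φ through the Karplus relation; rather
than inverting a curve, the field uses interval rules, which we encode
exactly: J < 6 Hz → φ ∈ [−90°, −30°]; 6 ≤ J < 8 → [−120°, −60°];
8 ≤ J < 9 → [−160°, −80°]; J ≥ 9 → [−140°, −100°], for l-residues; the
d-interval is the l-interval negated with endpoints swapped.  The source
rules are written with strict inequalities on both sides, leaving J = 6, 8,
9 Hz unassigned; we close each bin on the left (a boundary coupling falls
into the higher-J rule), which is the conservative choice — higher J maps to
more extended φ.  Default force constant 2 kcal/(mol·rad²); trans peptide
bonds, when requested, are enforced at ω = 180° ± 10° with 50 kcal/(mol·rad²).
Gly couplings are excluded from φ restraints by default: with two degenerate
Hα protons whose couplings are equal within error, the measurement does not
identify φ.

**NOE volumes.**  Cross-peak volume scales approximately as r⁻⁶.  The
original class-calibration machinery of dedicated assignment programs is not
public in any form we could reimplement faithfully, so distance bounds use
the isolated-spin-pair relation d = d_ref·(V_ref/V)^(1/6) anchored on one
reference pair (default 1.78 Å, a geminal Hβ pair; user-overridable), with
pseudo-atom padding (+1.0 Å methyl, +0.9 Å degenerate aromatic pair) and a
6.0 Å ceiling.  Every output is flagged `"ISPA stand-in"` so downstream users
know the bounds are not class-calibrated.  The calibration is scale-invariant
in the volumes and strictly monotone, both asserted as properties.  Duplicate
restraints on one atom pair keep the tighter bound.

**Temperature coefficients.**  Δδ/ΔT is the OLS slope of the amide shift
(ppb) against T (K).  Classes: (−3, 0] ppb/K strong (solvent-shielded),
(−5, −3] weak, ≤ −5 none; boundaries fall into the weaker class because the
published ranges are open on the strong side.  Positive coefficients are
outside the usual rules; we map them to "strong/shielded" with a warning
rather than failing, since shielding by the micelle produces the same sign
pattern.

**Proline isomer.**  Δδ(Cβ−Cγ) separates trans (≈ 4.5 ppm) from cis
(≈ 9.6 ppm) X-Pro bonds; the decision threshold 7.0 ppm sits midway between
those literature anchors.  A missing shift yields "undetermined", never a
guess — the d-Arg8 analogue's Pro7 Cγ is a real example of an unobserved
resonance.

## Conformational statistics

**Turns.**  A β-turn at start residue i requires Cα(i)–Cα(i+3) < 7.0 Å and a
match of (φ, ψ)(i+1, i+2) to a Lewis template with at most three deviations
within 30° and at most one within 45°; the template with the smallest maximum
deviation wins.  These tolerances follow the classical
Venkatachalam/Lewis convention; the source material states none, so they are
exposed as arguments (and CLI flags).  Type VII has no four-angle template
and is scored on its constrained pair only (|ψ(i+1)| ≈ 180° with
|φ(i+2)| < 60°, or the converse); type IV is the fallback for chain reversals
matching no template, which is the only reading under which "β IV"
assignments are reproducible at all.  Occupancy is the fraction of frames
assigned; per-frame assignments are retained as an attribute.

**Hydrogen bonds.**  Donor-heavy–acceptor-heavy distance ≤ 3.5 Å and
D–H⋯A angle ≥ 120°.  Amide hydrogens absent from the input are rebuilt
1.01 Å from N along the negated bisector of the two N bonds; side-chain and
C-terminal amide donors use a virtual H along the antecedent→donor extension,
an adequate directional proxy for synthetic and idealised geometry.  The
report is ranked by occupancy; the conventional "most popular" listing keeps
bonds at ≥ 0.3 occupancy.

**Ring descriptors.**  Dis is the distance between the two aromatic ring
centroids; Ang the dihedral over (centroid_a, Cα_a, Cα_b, centroid_b).  Ring
centres use the C1/C3/C5 carbons of the IUPAC ring numbering, which in PDB v3
naming are CG, CE1, CE2 — C1 is the ring carbon bonded to Cβ and C3/C5 are
the meta carbons.  Those three positions are the alternating vertices of the
hexagon, so their centroid is the exact ring centre, and with equal carbon
masses the mass-weighted and geometric centres coincide.  Ensemble summaries
use the arithmetic mean for Dis and the circular mean (with the mean
resultant length R as dispersion) for Ang, since Ang lives on a circle.

**Ensemble spread.**  The RMSD statistic is the mean RMSD of each frame to
the unweighted mean structure, after least-squares superposition
(Kabsch, via base `svd`) of every frame on the stated selection; the mean is
refined over two rounds.  Whether historical reports averaged pairwise RMSDs
or referenced a mean structure is not stated in the sources this convention
descends from; both are implemented behind one argument
(`method = "mean_structure"` default, `"pairwise"` as the one-line switch).
For frames that are a reference plus iid Gaussian noise σ per coordinate the
statistic is σ√3·√((F−1)/F) up to the six fitted degrees of freedom, which
the tests verify by simulation.

## Solvation

RDFs use minimum-image distances in a cubic box (non-cubic boxes are
rejected; the target systems are cubic), normalised by shell volume 4πr²dr,
the B-group number density N_B/V and the frame × A-site count, so a uniform
fluid gives g = 1 — asserted against a generated ideal gas.  The running
integral n(r) is the cumulative mean raw count, whose density-weighted
consistency with g(r) is asserted to quadrature accuracy.  Hydration numbers
count water *molecules* via their oxygen positions (molecule-count semantics,
no triple-counting of H) within 3.8 Å of any selection atom, union-counted;
the two standard report sets are side-chain heavy atoms and backbone carbonyl
O per residue.

The contact classifier combines the side-chain hydration number, expressed as
a fraction of the bulk expectation (probe union volume × water density in the
water-accessible volume), with the first-peak positions of the side-chain
RDFs against the micelle core and head groups: fraction < 0.25 with the core
peak at or inside the head peak → buried; ≥ 0.75 → exposed; otherwise
interfacial.  The 0.25/0.75 terciles and the RDF grid live in
`contact_config()`.  "Head groups" are the SDS sulfur and DPC
phosphorus/choline-nitrogen sites; the "core" is the terminal methyl plus the
last three tail carbons per detergent — the sources never define these
selections, so they are fixed here and documented.

## What the generator emulates — and what it does not

`build_peptide()` constructs backbones from fixed internal coordinates
(N–Cα 1.458, Cα–C′ 1.525, C′–N 1.329 Å, standard valence angles) by NeRF
chain extension, so planted φ/ψ/ω round-trip exactly; Cβ placement is
resolved per residue so the improper dihedral Cα–N–C′–Cβ is positive for l
and negative for d; aromatic rings are ideal hexagons.  There are *no*
sterics and no energetics: an impossible torsion request is built literally.
This is deliberate — the package analyses ensembles, the dynamics engine is
out of scope, and exact analytic ground truth is the entire value of the
generator for validation.

`make_box()` places head-group sites on a spherical shell, core sites inside
it, and water oxygens uniformly in the remaining volume, Poisson-distributed
in count.  Defaults mirror the canonical mixed-micelle system: an 85 Å cubic
box, 10 SDS + 50 DPC (the 1:5 anionic:zwitterionic ratio), and a water
density of 0.02325 Å⁻³ chosen so the default box holds ≈ 13,500 waters
outside the 20 Å micelle sphere.  Real water (0.0334 Å⁻³) is denser; the
default reflects a box whose volume is shared with detergent tails that the
toy geometry does not model as excluded volume.  Water positions are
resampled each frame (independent Monte-Carlo draws), while peptide and
micelle sites are jittered — good for estimator statistics, wrong for
dynamics, which is fine because no time-correlated quantity is computed.

Consequently, passing tests demonstrate correctness of the *estimators*
(turn typing, occupancies, g(r) normalisation, hydration counting, RMSD
statistics) on ensembles with known truth.  They do not demonstrate that real
micelle-bound ensembles have any particular structure: the headline
structural numbers of real systems derive from long restrained-MD
trajectories that are not redistributable, so those quantities are validated
here property-wise, not numerically.

## Numerical choices and degenerate inputs

Angles are degrees on (−180°, 180°], residues are 1-based, coordinates are Å.
Degenerate dihedrals (coincident or collinear points) raise errors rather
than returning NaN; collinear superposition selections are rejected via a
rank check; the Kabsch reflection case is handled by the determinant sign.
Angle comparisons are circular throughout (so ω = −180° equals 180°).
Boundary behaviours — J-bin edges, the −3/−5 ppb/K class edges, the 7 ppm
proline threshold — are each fixed by a documented rule, and RDF tests avoid
placing point masses exactly on bin edges, where floating-point ties are
unavoidable.

Test problem sizes are chosen for tight statistics at interactive runtimes:
250-frame ensembles for I/O and descriptor recovery, 60–120 frames for
occupancy and hydration recovery, 30–44 Å boxes at liquid-like densities for
the solvation oracles.

## Known limitations

* NOE bounds are stand-in calibrated (ISPA), not class-calibrated.
* The hydrogen-bond donor geometry for side-chain/terminal amides uses a
  virtual H; on experimental structures with explicit hydrogens those are
  used where present (backbone) but side-chain donor hydrogens are not read.
* Only cubic boxes; no triclinic minimum image.
* The proline ring is built open (three chain atoms curled toward N), which
  is irrelevant to the analyses but visible in rendered structures.
* `contact_profile()` thresholds were fixed against the toy geometry; real
  detergent boxes with explicit tails may need the exposed knobs.
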