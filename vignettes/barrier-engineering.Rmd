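---
title: "Barrier engineering of BHET hydrolases: models, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barrier engineering of BHET hydrolases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barriereng)
```

## The problem and the method

Enzymatic PET recycling needs a hydrolase that clears the intermediate
BHET. In the two BHETases this package models, rigid segments near the
substrate binding cleft act as *barriers*: unlike the mobile lid of
classical lipases they do not open, so the bulky BHET rarely reaches the
catalytic serine, while water does. Barrier engineering removes a
candidate segment outright and bridges the junction with a flexible
Gly-Gly linker, then triages the candidate variants *in silico* before
any cloning.

The triage is a weighted min–max score over four docking-derived factors
per variant: binding energy **A** (kcal/mol, more negative is better,
ingested from an external docking run), hydrogen-bond count **B** between
the docked BHET and surrounding residues (more is better), serine attack
distance **C** (Å, shorter is better), and the cavity volume **D** formed
between BHET and the residues within 4 Å (larger is better). Each column
is min–max rescaled to [0, 1] within the table, A and C are inverted, and
the weighted sum 10% A + 30% B + 40% C + 20% D ranks the variants. The
attack distance carries the largest weight because it is the direct
geometric proxy for nucleophilic attack on the ester carbonyl; with both
carbonyl carbons (C7, C10) present in BHET, the scoring consumes the
smaller of the two OG distances — attack proceeds on whichever carbonyl
presents itself.

Validation on the wet-lab side is modelled by the assay equations:
first-order inactivation `E_t = E0·exp(−k·t)` with half-life `ln 2 / k`,
Michaelis–Menten kinetics for `K_M`, `k_cat` and `k_cat/K_M`, DSC percent
crystallinity `(ΔHm − ΔHc)/ΔH_ref × 100`, and the glycolysis-side BHET
purity, BHET yield and theoretical maximum hydrolysis yield.

## Design choices where the method left room

**Normalization scope.** Min–max normalization is computed per input
table. Scoring the five variants of each enzyme separately (the default
of the analysis scripts) asks "which truncation of *this* enzyme is
best"; pooling both enzymes into one table would mix scales of unrelated
receptors. A degenerate column (all variants equal) carries no
information and contributes a neutral 0.5 to every variant rather than a
0/0.

**Tie-breaking.** Equal composite scores are broken by the smaller raw
attack distance (mirroring its 40% weight), then lexicographic variant
id, so rankings are deterministic and permutation-invariant.

**Hydrogen-bond criterion.** Docking poses and predicted structures
usually lack hydrogens, so the default criterion is distance-only: a
protein N/O heavy atom within 3.5 Å of a ligand N/O heavy atom. When a
donor carries an explicit hydrogen, a D–H···A angle threshold (120°)
additionally applies. Both numbers are the community defaults and are
config-exposed (`hbond_criteria()`).

**Cavity definition.** The cavity between the docked ligand and its 4 Å
residue shell is computed with a dual-probe grid (`cavity_grid()`):
voxels whose centers clear every atom's van der Waals sphere by more than
the small probe (1.4 Å, water-sized) are *accessible*; the large probe
(4.0 Å) is rolled in from the box boundary and everything within its
sweep is *bulk*; accessible minus bulk is cavity, and volume is voxel
count × spacing³. Van der Waals radii come from a fixed internal table
(C 1.70, N 1.55, O 1.52, S 1.80, default 1.70 Å) for determinism.

**Truncation bookkeeping.** Variants are renumbered sequentially 1..N;
the old→new map (`map_residue()`) is the bridge for locating the
catalytic serine and any other annotated residue after truncation.
Variant *structures* are not rebuilt — no loop modelling — so geometric
factors for a variant expect an externally predicted structure or the
synthetic builder. Two region pairs overlap by construction (the nested
candidates over the same structural element); both are generated as
listed.

**Site definition.** The substrate binding site for occupancy counting is
a 6 Å sphere around the catalytic Ser OG — a simple, reproducible proxy
for the substrate binding cleft; a molecule occupies the site when at
least one heavy atom is inside. Analysis windows filter frames by time,
not index, so "the last 40 ns" maps onto any storage interval.

**Inactivation fitting.** The default is log-linear least squares on
`ln(activity)` (the model is a single exponential, so the log-transform
is exact and robust); a nonlinear option exists for noisy tails.
Reported fold-changes use half-up rounding at the requested decimals.
Kinetic ratios (`k_cat`, `k_cat/K_M` fold changes) are always computed
from the input table, never quoted.

## Numerical choices

* **Superposition** is closed-form Kabsch (SVD with reflection
  correction); the tests cross-check against an independent quaternion
  implementation (agreement 1e-8) and against bio3d (whose RMSD prints
  at 3 decimals, hence a 1e-3 comparison there).
* **RMSF** superposes frames onto the analysis-window average (one
  fit–average refinement pass) before measuring per-residue fluctuations;
  a `fit = FALSE` path serves fixtures already in a common frame, where
  closed-form expectations apply exactly.
* **SASA** is Shrake–Rupley with a deterministic golden-spiral lattice
  (default 960 points; quadrature error on an isolated atom < 2%).
  Exactly coincident equal-radius atoms are deduplicated first: they
  describe one sphere, and counting both would double the shared surface.
* **Cavity grid numerics.** The bulk sweep dilates the exterior region by
  the large-probe radius using alternating 6- and 26-connected unit
  steps, a standard ball approximation that keeps the sweep O(radius)
  per voxel. Volumes are exactly translation-invariant (the grid is
  anchored to the atom bounding box) but re-discretize under rotation;
  rotational agreement is a few percent at the default 0.6 Å spacing,
  not one voxel, and the tests reflect that. On an enclosing-shell
  fixture the estimate converges to the analytic ball volume
  (errors 2.6% → 0.7% → 0.04% over spacings 1.0/0.6/0.3 Å).
* **Zero-residual fits.** `nls` convergence on noise-free data uses
  `scaleOffset`, so exact synthetic datasets are recovered to machine
  accuracy rather than erroring on a perfect fit.

## What the synthetic generators emulate — and what they do not

The generators (`generator_config()` and friends) reproduce the study
*conditions*: 30 substrate copies in a box with a 10 Å margin, frames
stored every 0.5 ns over 100 ns, a late analysis window, decay sampled
every 0.5 h, a kinetics design spanning 0.8–15 mM, and multiplicative
log-normal noise (keeping activities positive for log-linear fitting).
The toy protein is a parametric α-helix (1.5 Å rise, 100°/residue) wound
into a horseshoe enclosing a pocket, with one serine whose OG points into
the mouth — enough for every geometric operation, which needs only
heavy-atom positions, names and numbering. Ligand dynamics are seeded
random walks with reflective boundaries; during a scheduled window the
specified number of ligands is held inside the site sphere and all others
are excluded at a direction-dependent clearance, so occupancy series
equal the schedule *exactly* and closed-loop tests are sharp.

None of this is physics: there are no forces, no water structure, no
realistic docking poses, and the idealized BHET (18 heavy atoms, C7–C10
para span 5.76 Å) is a rigid template. Passing tests therefore
demonstrate that the *measurement and scoring machinery* is correct and
deterministic — not that any particular real variant will rank first on
real docking data. The analysis scripts use trimmed problem sizes (e.g.
30 ns trajectories, 60-residue toy proteins) as their documented study
size; the generator defaults record the full conditions.

## Known limitations

* PDB only (no mmCIF/compressed transport); a ligand is exactly one
  residue; altloc handling keeps the highest-occupancy conformer.
* Binding energies are inputs; no docking or scoring-function physics.
* The cavity tool's reference parameters are not published, so the
  dual-probe parameters here are package defaults, all config-exposed;
  absolute cavity volumes depend on them, rankings much less so. A snug
  pose can legitimately yield a near-zero interstitial cavity.
* `k_cat` is reported only when an enzyme concentration is supplied;
  otherwise the fit returns `Vmax` and `Vmax/K_M`.
* With a substrate design far above `K_M` (e.g. `K_M` ≈ 0.1 mM under a
  0.8–15 mM design), `K_M` is recovered but with a large standard error —
  an experimental-design property the tests assert rather than hide.
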