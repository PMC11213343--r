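---
title: "hingescan: model, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hingescan: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingescan)
```

## The model

Hinge-type binding proteins (the periplasmic binding protein family being
the canonical case) interconvert between a ligand-bound closed state and a
ligand-free open state by rigid-ish rotation of two lobes about inter-lobe
loops. The premise of this package is that the residue pairs whose
*contacts* change across that transition mark the regions where an inserted
effector protein (e.g. circularly permuted GFP) will experience a changed
environment upon ligand binding — and hence the regions where an insertion
is most likely to yield a working biosensor.

The pipeline has four stages, each exposed as ordinary functions and tied
together by `run_metrics()`, `run_hotspots()`, `run_design()` and
`run_assay()`:

1. **State classification.** Per-replicate C-alpha RMSD against the
   starting structure (Kabsch superposition per frame). A replicate is
   *closed* when the mean RMSD over the final window is strictly below the
   threshold, *open* otherwise. A mean exactly equal to the threshold is
   called open: the closed rule is a strict inequality, and of the two ways
   to close the gap this is the conservative one for the downstream
   analysis (a replicate must clearly stay near the start to count as
   closed).
2. **Contact-change matrix.** For each residue pair, the per-frame
   closest-atom distance; a hysteresis contact state machine (enter below
   `r_start`, leave above `r_end`); and, for pairs ever in contact, the
   Pearson correlation of the truncated distance `min(d, r_end)` with
   time. Per-replicate matrices from the *open* (transition) replicates are
   averaged pixel-wise.
3. **Hotspot clustering.** Same-sign 8-connected components of the nonzero
   upper-triangle pixels; per-cluster mean, median and max-|pixel|;
   percentile filter requiring all three simultaneously, peaks and valleys
   ranked separately; insertion sites enumerated across each retained
   cluster's residue union at a fixed stride.
4. **Construct assembly and assay scoring.** The duplicated-residue linker
   rule (below) and the dF/F0 pipeline (technical means, background
   subtraction, ratio, replicate aggregation, viability call).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `rmsd_threshold` | 2.5 | Å | open/closed boundary on the final-window mean RMSD |
| `window_ns` | 50 | ns | final-window length for state calls and difference profiles |
| `r_start` | 5.0 | Å | contact formation cutoff |
| `r_end` | 8.0 | Å | contact termination cutoff; also the distance truncation level |
| `neighbor_exclusion` | 2 | residues | pairs with \|i−j\| ≤ 2 are skipped |
| `percentile` | 99 | — | cluster filter level (mean, median and max-abs simultaneously) |
| `insertion_stride` | 3 | residues | spacing of enumerated insertion sites |
| `viability_threshold` | 0.25 | — | \|dF/F0\| above which a sensor is called viable |
| `selection_mode` | heavy | — | atoms entering minimum distances |

**Contact cutoffs.** Published descriptions of this contact criterion
sometimes print the two cutoffs as 0.5 and 0.8 Å. Those are physically
impossible closest-atom distances (they sit far inside van der Waals
contact), and the contact-analysis tools this criterion descends from work
in nanometres; the values are treated here as 0.5/0.8 **nm** and the
defaults are 5.0/8.0 Å. Both remain fully configurable.

**What is correlated with time.** The per-pair quantity entering the
correlation is the truncated distance, not the raw distance and not the
binary contact flag. Truncation at `r_end` keeps far-apart excursions
(where the exact distance carries no contact information) from dominating
the coefficient; the resulting sign convention — positive means the contact
exists early, i.e. in the closed state — is exactly the convention the
hotspot interpretation needs. A binary-indicator variant
(`cor_method = "indicator"`: the hysteresis in-contact flag, sign-flipped
to preserve the convention) is provided because the two readings are both
defensible; the distance reading is the default because it degrades
gracefully for contacts that loosen without fully breaking.

**RMSD/RMSF/dihedrals on C-alpha atoms.** Lobe-scale motion is what the
method is after; C-alpha selections are the standard way to measure it
without side-chain noise, and they match the C-alpha-based pseudo-dihedral
metric. Minimum distances for contacts default to heavy atoms instead —
contacts are an all-atom notion — with `calpha` available for single-atom
toy systems.

**Difference profiles.** The per-residue pseudo-dihedral of residue *i* is
the torsion of C-alphas *i−1..i+2* (undefined for the first residue and
last two). Per-replicate values are averaged over the final window with
*circular* means — arithmetic means of angles near ±180° are meaningless —
and the closed-minus-open difference is wrapped into (−180°, 180°] with the
absolute value reported. Whether the absolute value should be taken before
or after ensemble averaging is genuinely ambiguous; taking it after (as
here) preserves cancellation between replicates that disagree in direction,
which is the more conservative reading. Both states use the same
final-window convention. RMSF uses the plain arithmetic mean and a
superposition onto the window-mean structure (one fit-to-first pass to
build the mean, then a refit), so rigid-body drift does not register as
fluctuation.

**Percentile filter.** The filter is "at or above the interpolated
percentile" (R's type-7 quantile) rather than strictly above: with a
handful of clusters a strict rule on a singleton group would retain
nothing, which contradicts the filter's purpose. Valleys are ranked on
|mean| and |median| so that "top" means *most extreme* for both signs.
Raising the percentile can only remove clusters (tested as a property).

**Clusters are 8-connected.** "Contiguous" is implemented as 8-connectivity
(diagonal adjacency joins pixels) because that is how blobs group visually
on a heatmap; clustering runs on the strict upper triangle to avoid
mirrored duplicates. Connected components are computed with igraph; the
test suite checks the result against an independent flood-fill
implementation on random matrices.

**The linker rule.** "Insertion at residue *i*" places the effector
cassette between scaffold positions *i* and *i+1*, with the N-terminal
linker `res(i+1)-Ala-Ser` and the C-terminal linker `Ala-Ser-res(i)`:

```
scaffold[1..i] | res(i+1) A S | effector | A S res(i) | scaffold[i+1..n]
```

Residues *i* and *i+1* each occur twice; the full length is always
scaffold + effector + 6. This is the only arrangement consistent with both
linker definitions simultaneously, and it is reversible (the tests
reconstruct the scaffold from the fusion).

**dF/F0.** The ratio is computed per biological replicate and then
averaged (`method = "replicate"`, the default), so the reported SD is a
true replicate scatter; `method = "pooled"` — ratio of the
across-replicate means — matches the convention behind published
single-number tables, and the two agree exactly in the noiseless limit.
Published raw triplets like 22/31/72 giving a printed dF/F0 near 4 rather
than the naive 2.27 are what the pooled/background-subtracted order
produces; with a near-zero baseline the ratio is unstable either way, which
is why `F0 = 0` is reported as missing rather than infinite. The SD is the
sample (n−1) standard deviation.

## The synthetic generator

`generate_hinge_trajectory()` builds a toy hinge protein of one C-alpha
pseudo-atom per residue: a static lobe, a moving lobe rotating about the
shared hinge, and a short static "latch" segment placed just past the final
opening angle, so that opening simultaneously *breaks* the hinge-flank
contacts (positive pixels) and *forms* lobe-tip/latch contacts (negative
pixels). Defaults: 10 residues per lobe at 3.8 Å spacing, 2 hinge residues,
3 latch residues, 41 frames spanning 100 ns, opening 25°→60°, Gaussian
coordinate noise of 0.15 Å.

The distance between equal-radius residues across the hinge is the chord
`2 r sin(θ/2)`, so the default schedule is spaced uniformly in `sin(θ/2)`:
those hinge-flank distances are then *exactly affine in time*, and their
zero-noise time correlation is exactly +1 (up to floating point), not
merely close to it. The generator derives its ground truth from the
noiseless geometry by plain distance arithmetic — threshold crossing, trend
sign, and an affinity check — independently of the contact/correlation
machinery it is used to test. The amplitude is sized so that the
closest-flank distances stay below `r_end` throughout (no truncation
plateau) while the ensemble still classifies unambiguously open
(final-window mean RMSD ≈ 5.3 Å against the 2.5 Å threshold).

What the fixture does **not** emulate: thermal kinetics (the opening is a
deterministic schedule, not a stochastic barrier crossing), side chains and
packing (one atom per residue by default; a two-atom variant exercises the
all-pairs minimum), solvent, and any ligand. Passing tests therefore
demonstrate the correctness of the analysis operators and their
composition, not the physical realism of any simulation.

`generate_plate_assay()` simulates the standard assay layout (3 biological
× 3 technical replicates at 0/1/100 mM ligand, plus an empty-vector
background series) as `background + F0·(1 + dF/F0) + noise` per well, with
defaults `F0 = 1000`, `background = 50`, `noise = 10` (arbitrary plate
units, ~1% relative noise — an optimistic but realistic plate reader).
The noiseless pipeline inverts the generator exactly; under noise the
recovery tests compare pooled estimates over independent simulated plates
against three standard errors.

## Numerical choices

- Superposition is Kabsch via SVD with the determinant sign guard, so
  reflections are never returned; degenerate (coincident/collinear) point
  sets are an error rather than an arbitrary answer.
- Torsions use the atan2 formulation (well-conditioned near 0° and 180°),
  returned in (−180°, 180°] with planar-cis = 0; collinear quadruples are
  an error. The tests cross-check against an arccos-of-normals oracle.
- A distance or time series with zero variance has correlation 0 by
  convention (the pixel carries no information, and `NA`s would poison the
  matrix mean).
- Matrix means require identical shapes; trajectories require strictly
  increasing frame times; windows longer than the trajectory are errors,
  not silent truncations.
- Frame times default to the frame index when no interval is given, so
  "ns" windows degrade to frame counts on index-timed data.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
25-residue hinge fixtures of 41 frames, ensembles of up to 10 replicates,
1000-series property sweeps for the contact machine and the correlation,
200 random matrices for the clustering oracle, and 20–30 simulated plates
for the assay calibration. These sizes give sub-two-minute suites while
exercising every code path; all of them scale linearly (frames, pairs) or
quadratically (residues) if larger systems are analysed.

## Limitations

- The method needs the transition to actually occur in the input ensemble;
  replicates that stay closed contribute nothing to the matrix (and the
  pipeline errors if none opens).
- Pearson-vs-time assumes an essentially monotone transition within each
  replicate; a replicate that opens and recloses will dilute its pixels.
- Hotspots propose *regions*; they do not rank individual sites within a
  region, and wet-lab screening of the enumerated sites remains necessary.
- The crystal-pair matrix (`two_structure_matrix()`) is deliberately crude
  (pixels in {−1, 0, +1}) and is provided for comparison, to show what
  static end points alone can and cannot resolve.
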