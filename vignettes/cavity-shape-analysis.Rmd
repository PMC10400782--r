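---
title: "Cavity shape analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cavity shape analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voidshape)
```

## The scientific problem

When a small solute sits in water it does not occupy a cavity shaped like
its own van der Waals surface.  The solvent void that hosts it is larger,
irregular, and typically *branched*: finger-like protrusions of empty space
reach away from the solute between the surrounding water molecules.  The
shape of this void — not just its volume and area, but the number and
lengths of its branches and the longest path across its surface — carries
enough information to predict solvation thermodynamics (free energy,
enthalpy, entropy) and empirical hydrophobicity measures through simple
standardized linear models.

`voidshape` implements that analysis chain for explicit-water snapshots:

1. **Void extraction.** Remove the solute, treat every water oxygen and
   hydrogen as a sphere (van der Waals radii 1.52 and 1.2 Å), tessellate the
   sphere centers, and place a *probe sphere* at every Voronoi vertex whose
   empty radius (distance to the nearest atom surface) is at least the probe
   radius (1.2 Å).  Probes are merged into voids through Voronoi-edge
   connections whose *bottleneck* — the narrowest empty radius along the
   connection — is at least 1.1 Å.  The void with maximal overlap with the
   (removed) solute's van der Waals region is the host void.
2. **Surface reconstruction.** The host void's probe-sphere union is sampled
   and closed into a watertight triangulated alpha-shape surface whose edges
   form a weighted graph.
3. **Descriptors.** Volume $V$, surface area $S$, longest surface geodesic
   $L$ (the weighted graph diameter), branch count `nbr` via density-peak
   clustering of surface vertices more than 5 Å from the solute surface, the
   branch-length summaries `dmin`, `dmax`, `dave`, `dtotal`, and the branch
   density $\mathrm{nbr}/N^{2/3}$ with $N$ the solute heavy-atom count.
4. **Regression.** Per-solute mean descriptors feed standardized,
   intercept-free linear models $y = \sum_j w_j X_j$; every non-empty
   feature subset is scored by leave-one-out (LOO) cross-validation and the
   winner reported with $R^2$, $R^2_{\rm LOO}$ and $\mathrm{MSE}_{\rm LOO}$,
   plus leave-$k$-out error-scaling diagnostics.

Because no simulation trajectories ship with the package, a synthetic-data
module generates (a) water-like sphere packings at ambient density, (b)
*phantom cavities* — spheres and $k$-tendril stars carved into the packing
with analytic ground truth — and (c) regression fixtures drawn from known
linear models.  Phantoms make every stage falsifiable: a correct pipeline
must recover the carved volume, area and tendril count.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `probe_radius` | 1.2 | Å | minimum empty radius of a retained probe |
| `bottleneck_radius` | 1.1 | Å | narrowest passage that still merges two probes |
| water O / H radii | 1.52 / 1.2 | Å | solvent sphere radii |
| `branch_threshold` | 5 | Å | surface height above the solute that defines branch candidates |
| `dc` | 2.5 | Å | density-peak kernel cutoff (half the threshold) |
| `delta_min` | `2 * dc` | Å | separation that promotes a height peak to a branch center |
| `alpha_factor` | 2 | – | alpha-ball radius = factor × probe radius |
| `sample_area` | 0.8 | Å² | probe-sphere surface area per mesh sample point |
| `number_density` | 33.4 | nm⁻³ | ambient water density for the synthetic bath |

The probe/bottleneck pair and the 5 Å branch threshold are the standard
values of the cavity-analysis literature; all of them are plain function
arguments and echoed into the pipeline manifest.

## The synthetic bath and what it does (not) emulate

The generator places rigid 3-site waters (O–H 0.9572 Å, H–O–H 104.52°,
random orientations) by random sequential insertion under a 2.6 Å O–O hard
core, then *quenches* the packing: zero-temperature Metropolis moves under a
harmonic soft-sphere repulsion of diameter 3.1 Å (the effective
Lennard-Jones size of water).  Plain random insertion leaves percolating
interstitial voids that ambient water does not have; the quench restores a
liquid-like first-neighbor shell and removes essentially every probe-sized
bulk void, which is what matters for cavity geometry.

Carving a phantom removes whole molecules, which by itself leaves a loose
boundary roughly one molecular layer beyond the nominal region.  The carve
therefore alternates three relax/refill cycles: a rigid-molecule quench
against a harmonic wall at the carved boundary — with a short-range wall
attraction reproducing the contact-density enhancement a liquid shows at a
hard wall — and a *saturating* re-insertion of waters into any pocket that
still fits a molecule, as an equilibrated liquid would fill it.  After this
the actual cavity volume matches the carved analytic volume to a few
percent across radii 4–8 Å.

What the bath does **not** emulate: hydrogen-bond network correlations,
orientational structure near charged groups, thermal interface
fluctuations, and long-range electrostatics.  Passing phantom-recovery
tests therefore demonstrates the *measurement chain* is correct, not that
the bath reproduces real water's void-size distribution quantitatively; at
low branch thresholds (3 Å) the quenched packing shows more shallow surface
pockets than equilibrated water would.

## Numerical choices

* **Tessellation.** An incremental Bowyer–Watson 3D Delaunay tessellation
  (compiled code) backs both the Voronoi probe construction and the alpha
  complex.  In-sphere tests use the lifted determinant in extended
  precision with a conservative scale-aware tolerance; point location is a
  stochastic walk with an exhaustive-containment fallback.  Inputs are
  deterministically jittered (1e-6 Å keyed to the atom index; 0.02 Å for
  surface samples, far below mesh resolution) so cospherical degeneracies
  are broken reproducibly.
* **Weighted vs ordinary Voronoi.** The tessellation is the ordinary
  Voronoi diagram of the atom centers, with radii subtracted when the empty
  radius is evaluated.  This approximates the additively weighted diagram;
  O and H radii differ by only 0.32 Å, and the approximation is audited by
  an independent brute-force grid oracle (probe-center accessible region,
  26-connected flood fill, probe-radius dilation) rather than assumed.
* **Edge bottlenecks** are the minimum empty radius sampled at the two
  Voronoi vertices and the edge midpoint.
* **Periodic boundaries** are handled by replicating atoms within 6 Å of
  each face before tessellation and keeping vertices in the primary cell;
  correctness is enforced by translation-invariance tests.
* **Surface.** Probe spheres are sampled on a deterministic Fibonacci
  lattice (one point per 0.8 Å²) with an interior support lattice so the
  alpha complex is solid; tetrahedra with circumradius ≤ 2.4 Å are kept,
  the largest block's outer boundary is extracted, non-manifold pinches are
  repaired by dropping incident tetrahedra, and ten Taubin λ/μ smoothing
  passes (0.5/−0.53) remove sampling-scale scallop texture.  Smoothing is
  volume-preserving: on phantom spheres it leaves $V$ unchanged and brings
  $S$ from ~15% above to within ~5% of the analytic area; on an ideal
  single-probe sphere the mesh reproduces $V$ and $S$ to 0.3%.
* **Host selection.** The per-frame pipeline needs the void *hosting* the
  solute; among all voids the one with maximal Monte-Carlo overlap (20 000
  fixed-seed samples) between its probe union and the solute van der Waals
  union is chosen, ties breaking to the smaller component id.
* **Branch clustering.** Candidates are surface vertices whose distance to
  the nearest solute sphere surface exceeds the threshold.  They are
  clustered by the density-peak (Rodriguez–Laio) assignment rule with the
  *height field itself as the density*: a center is a candidate with no
  higher candidate within `delta_min`.  Protrusion tips are then exactly
  the centers; mid-wall bumps always have a higher point up-wall nearby and
  never split a tendril, and a center found at one threshold persists at
  every lower threshold, which makes the branch count provably
  non-increasing in the threshold.  A cutoff-kernel density remains
  available in `density_peak_cluster()` for ordinary point clouds.
* **Branch length** is the maximum height over the cluster's members —
  parameter-free, and it reproduces tendril lengths on star phantoms to
  about 0.2 Å.
* **Standardization** uses the population convention (divide by $n$),
  configurable; inside every LOO fold the means and scales are re-fit on
  the training rows to avoid leakage (a global mode exists for comparison).
  After standardization the model has no intercept.
* **Subset selection** minimizes $\mathrm{MSE}_{\rm LOO}$ by default
  (in-sample $R^2$ is monotone in subset size and is only offered with a
  warning); ties break to fewer features, then lexicographic order.
* **Leave-$k$-out scaling.** $\mathrm{Error}_i\sqrt{N-i} /
  (\mathrm{Error}_1\sqrt{N-1})$ is reported for $i \le k$; with noiseless
  data the $0/0$ case returns 1 with a degeneracy flag.

## Design choices where the field leaves room

* The hosting void among all voids in a frame is identified by maximal
  solute overlap — the natural reading of "the void hosting the solute".
* What feeds the branch clustering ("positions of the surface nodes and the
  solute") is resolved as the solute-relative height field on surface
  vertices.
* `PhantomTruth$tendril_length` measures the tendril cap's reach beyond the
  carved core surface, so that with a solute of radius equal to the core
  the detected branch length equals the recorded truth by construction.
* The carve adds waters (saturating refill) even though a literal reading
  of phantom conservation would forbid it; without refill the depleted
  boundary freezes 5 Å deep fingers into the cavity that a liquid would
  fill, corrupting branch counts.
* A grid-oracle "component" is compared against probe merging only above a
  25 Å³ marginality floor (about one water volume): below it, threshold-
  scale specks flicker between the grid and Voronoi views.

## Problem sizes used by the test-suite and acceptance runs

Phantom recovery runs in a 30 Å cubic box (~900 waters) with spheres of
radius 4, 6 and 8 Å and stars of 2–5 tendrils (8 Å long); smaller 16–20 Å
baths back the unit tests.  Regression checks use 20-row fixtures (the
amino-acid scale), 100 × n = 2000 fixtures for weight recovery, and 50
fixtures for the error-scaling band.  These sizes keep each acceptance
property in the minutes range on a single core while leaving the Monte-Carlo
and discretization errors well inside the stated tolerances.

## Known limitations

* The alpha-shape surface is resolution-dependent below ~1 Å features;
  descriptors are comparable across solutes only at fixed sampling
  parameters (which the pipeline enforces and records).
* The quenched bath's shallow-pocket statistics differ from real water, so
  branch counts at thresholds well below 5 Å carry generator noise; the
  ordering of branch counts across systems at a 3 Å threshold is not
  resolvable from single frames (see the decisions recorded in the test
  suite).
* Ordinary (unweighted) Voronoi with radius-corrected empty distances is an
  approximation to the additively weighted diagram; it is validated
  empirically against the grid oracle, not exact.
* No triclinic boxes; no trajectory decoders (export snapshots to
  GRO/PDB/XYZ first); no force fields or energetics anywhere.
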