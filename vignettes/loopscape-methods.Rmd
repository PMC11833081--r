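---
title: "Occluding-loop states, contact filtering and free-energy landscapes: methods"
author: "loopscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occluding-loop states, contact filtering and free-energy landscapes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscape)
```

## The scientific problem

Cathepsin B (CTSB) is a lysosomal cysteine protease whose endopeptidase
activity is auto-inhibited by its occluding loop (residues 185–200 in UniProt
numbering for the murine enzyme): when the loop covers the active-site cleft
the enzyme is "closed", when it swings away the enzyme is "open" and active.
Cystatin C (CST3) is an endogenous inhibitor of CTSB that, after
domain-swapped dimerisation or proteolytic truncation, loses its
active-site-directed inhibitory mode; ensemble simulations of such CST3
species bound to a surface pocket of CTSB show the occluding loop spending
more time open — allosteric activation rather than inhibition.

`loopscape` implements the post-processing side of that analysis as a tested,
reusable pipeline. It consumes multi-frame structural ensembles of two-chain
complexes (multi-model PDB), and produces: per-frame open/closed loop states,
contact-filtered sub-ensembles, frame-normalised residue contact statistics,
a two-dimensional free-energy landscape over contact-distance principal
components, density-based conformational clusters with representative
structures, and cross-condition statistics. A seeded synthetic-trajectory
generator supplies ground-truthed inputs so every stage is testable without
any external download.

## Reaction coordinate: loop/active-site COM distance

The open/closed coordinate is the Euclidean distance between the
mass-weighted centroids (COM) of two residue groups — by default the
occluding loop (185–200) and three active-site residues (108, 278, 298),
shipped as the `preset_ctsb_murine()` preset but fully configurable.

Two conventions are fixed here and used pipeline-wide:

* **Heavy atoms, standard masses.** COM is computed over non-hydrogen atoms
  with standard atomic weights. Sampling engines often repartition hydrogen
  masses; heavy-atom standard-mass COM makes the coordinate independent of
  the engine, and differs from an all-atom COM by well under the
  classification tolerance for groups of this size. `heavy_only = FALSE` is
  available as a sensitivity check.
* **The boundary is closed.** A frame with distance exactly equal to the
  threshold is labelled *closed*: the threshold (default 16.5 Å) *describes
  the closed state*, so the inequality is `d <= t`. `threshold_scan()`
  evaluates the empirical CDF of the distance trace on a grid (default
  12–24 Å in 0.1 Å steps), so `classify_states()` at any grid point and the
  scan agree by construction.

The open-state **fold change** between conditions is defined as the ratio of
group means, `mean(case) / mean(reference)`, not a mean of pairwise ratios.
With several case and reference simulations the two readings differ; the
ratio of means is the convention here because it is well-defined for unequal
group sizes and degrades gracefully when a single simulation has few frames.

## Contacts and ensemble filtering

A contact is two heavy atoms of different chains strictly closer than
0.33 nm; internally all lengths are Å (PDB-native), so the cutoff constant
is 3.3. The strict inequality means a pair at exactly 3.30 Å is *not* a
contact. Two kernels implement detection: a brute-force all-pairs kernel and
a cell-list kernel with cell edge equal to the cutoff. Both evaluate the
same squared-distance expression on the same operands, so they return
bitwise-identical pair sets (a tested invariant); the cell list is the
default above 500 atoms, brute force below.

Ensemble filtering discards frames without any inter-chain contact
(`filter_frames_any_contact()`), optionally restricted further to frames
touching a named residue site such as the allosteric pocket used for
mutagenesis, residues {169, 215, 221, 222, 224, 333} on the enzyme chain
(`filter_frames_site_contact()`). Filters compose by logical AND.

Per-residue contact statistics count **residue-pair** contacts (not atom
pairs) and divide by the number of frames: a residue in contact with two
partner residues in every frame scores 2.0, so values above 1 flag residues
binding several partners at a time. The atom-level alternative would scale
with residue size and bury that signal; the residue-level reading is adopted
pipeline-wide. Pair fractions are frames-in-contact over total frames.

## Contact-contact PCA and the free-energy landscape

ccPCA projects each frame onto principal components of inter-chain
distances over an equal-size atom mesh:

* **Mesh.** Let m be the heavy-atom count of the smaller chain. The smaller
  chain contributes all m heavy atoms in (residue number, atom name) order;
  the larger chain is strided with `k = floor(n_large / m)`, taking the
  first m strided atoms. The feature set is the full m × m cross product of
  mesh distances. The full product is the most literal reading of
  "distances between all such pairs"; because m² can exceed memory for large
  proteins, a seeded uniform subsample (`cap`) is available but off by
  default. The pair rule is isolated behind the `ContactMesh` type, so a
  one-to-one paired-distance variant is a one-line strategy swap if wanted.
* **PCA.** Features are centred by column mean and not scaled (they share Å
  units); zero-variance columns are dropped and recorded; the fit is an SVD
  (`stats::prcomp`). Component signs are fixed so the largest-magnitude
  loading of each component is positive — scores are then reproducible
  across BLAS/LAPACK builds.
* **Landscape.** PC1/PC2 scores are binned on a `bins × bins` histogram
  (default 100; axis ranges padded by 1% of the span on each side so extreme
  points do not sit on the outer edge). Bin probabilities P are converted to
  a Gibbs free energy by Boltzmann inversion,
  ΔG = −RT·ln(P / max P), with R = 0.008314462618 kJ/(mol·K) and T = 300 K
  by default (the low end of a typical replica-exchange temperature ladder;
  both configurable). The modal bin has ΔG = 0 exactly, and renormalising
  exp(−ΔG/RT) over occupied bins reproduces P to machine precision — a
  tested round trip. Empty bins are *masked* (NA), never given infinite
  energy, so downstream consumers see only finite numbers.

## OPTICS clustering

No OPTICS implementation ships with the R packages this package depends on,
so `loopscape` implements the algorithm: reachability ordering with
unbounded neighbourhood radius (core distance = distance to the
`min_samples`-th neighbour, the point itself included) and xi-based cluster
extraction with predecessor correction. A unit test cross-checks
reachability values, processing order, noise sets and partitions against the
scikit-learn reference implementation on a mixed blob-plus-noise fixture.

Defaults: `min_samples = max(10, 1% of frames)` and `xi = 0.05`. One further
parameter matters in practice: `min_cluster_size`. With the conventional
default (`min_samples`), the xi method reports *leaf* clusters, and a dense
conformational basin shatters into micro-clusters of a few dozen frames.
Since the object of interest here is the set of **major** binding/loop
states, the package defaults to `min_cluster_size = max(min_samples,
5% of frames)`: a reported cluster must hold at least one frame in twenty.
On well-separated basins this returns exactly the planted states with zero
noise; the parameter is exposed for users who want the leaf hierarchy.
Clusters are renumbered 1, 2, … by descending size; noise is −1. Each
cluster's representative frame is the member nearest (Euclidean, in score
space) to the cluster centroid, ties broken by the lowest frame position,
and representatives can be written out as a multi-model PDB.

## Cross-condition statistics

`compare_groups()` runs classical one-way ANOVA (via `stats::oneway.test`,
equal-variance form) across named distance groups, then all pairwise
two-sided t comparisons with the pooled within-group variance
(`stats::pairwise.t.test`, classical post-hoc convention; Welch variant
behind a flag) and Šidák adjustment `p_adj = 1 − (1 − p)^m` over the
G(G−1)/2 comparisons. The degenerate all-identical case returns F = 0,
p = 1 rather than an error.

Two caveats are deliberate: frames from a sampling trajectory are
autocorrelated, so frame-level p-values are anti-conservative — the module
computes them exactly as is conventional but the documentation flags the
issue, and no effective-sample-size correction is applied. And whether the
unit of analysis should be frames or per-simulation means is a judgement
call; both work, since `compare_groups()` accepts any named numeric lists.

## The synthetic generator

`generate_two_state_enzyme()` and `generate_binding_ensemble()` produce
seeded ensembles with per-frame ground truth. Geometry is deliberately
schematic — pseudo-residues (N/CA/C/O heavy-atom motifs) on helical
templates — because the pipeline consumes only coordinates, masses and
labels; statistical realism is the requirement, not stereochemistry.

* **Two-state loop.** Default chain of 40 pseudo-residues: residues 1–3 are
  the "active site", the last 6 the mobile "loop", the rest a static body.
  Per frame the state is Bernoulli(`f_open`), and the loop template (rigid,
  mass-weighted COM at its origin) is translated along a fixed axis so the
  loop/active-site COM distance is exactly `d_state + N(0, σ)` — the noise
  acts on the COM scalar itself, making planted distances exact oracles.
  Defaults: d_closed = 12 Å, d_open = 20 Å, σ = 0.8 Å, 2000 frames; the
  open and closed modes sit 10σ apart, comfortably bimodal, mirroring an
  enzyme that is closed most of the time.
* **Binding poses.** A rigid 15-residue ligand chain occupies one of K
  discrete poses per frame (default K = 2 at 70/30 occupancy, 10 Å apart).
  Bound poses anchor a ligand atom 1.8 Å from a pocket-residue atom; unbound
  poses sit ≥ 10 Å off the complex. Per-frame jitter is isotropic Gaussian
  (σ = 0.25 Å) truncated at 4σ; truncation makes the planted contact
  geometry exact (bound frames are always within the 3.3 Å cutoff, unbound
  frames never are), so filter ground truths are guarantees, not
  probabilities. `couple_loop = TRUE` raises the open probability of bound
  frames (default 0.63 vs 0.2), emulating allosteric opening; the resulting
  open-state fold change of about 3.15 is the pipeline's headline statistic.

What the generator does **not** emulate: force-field energetics, solvent,
replica-exchange temperature mixing, intra-chain flexibility beyond the
loop, or realistic side-chain packing. Passing tests on synthetic data
therefore validate the *analysis* — state classification, filtering,
feature extraction, inversion, clustering, statistics — not the physics of
any particular simulation engine.

## Numerical and design choices

* Internal unit Å everywhere; the 0.33 nm cutoff is the constant 3.3.
* Atom indices are 1-based in file order (R convention); residue numbers
  are verbatim from the source file, never renumbered.
* PDB reading keeps altLoc ' '/'A' only and rejects insertion codes:
  trajectory frames, unlike crystal structures, should not carry them.
  Elements come from the element column with an atom-name fallback; masses
  from a built-in standard-atomic-weight table; unknown elements are a
  format error rather than a silent default.
* Contact kernels compare squared distances; both kernels share one
  expression so equality is exact, and the boundary case (distance = cutoff)
  is excluded by the strict inequality in floating point as in exact
  arithmetic.
* The landscape's degenerate case (all scores identical) widens the axis to
  a unit span and yields a single occupied bin at ΔG = 0.
* Pipeline outputs contain no timestamps; a rerun with the same config and
  seed is byte-identical (a tested property). All seeded randomness flows
  through a seed-restore helper so generators never perturb the caller's
  RNG stream.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to be statistically
meaningful yet quick: two-state recovery at 2000 frames; pose recovery at
1000 frames (m = 60 mesh atoms, 3600 features); kernel equivalence on 50
random frames of 500 atoms; ANOVA null calibration over 2000 replicates of
3 × 50 draws. The complete suite runs in well under a minute on one CPU.

## Known limitations

* No kinetic or time-lagged analysis: replica-exchange ensembles are not
  time-ordered, so states are occupancies, not rates.
* No reweighting across replica temperatures; landscapes describe the
  ensemble as given.
* Binary trajectory formats (DCD/XTC) are out of scope; multi-model PDB is
  the interchange format, and converters exist in every MD toolchain.
* Frame-level significance tests inherit the autocorrelation caveat above.
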