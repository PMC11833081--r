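# loopscape

Ensemble post-processing for two-chain protein complexes, built around the
question of how cathepsin B's occluding loop responds to allosteric binders.
Cathepsin B (CTSB) is auto-inhibited when its occluding loop (residues
185–200, UniProt numbering) covers the active site; dimeric or truncated
cystatin C (CST3) species that bind a surface pocket can shift the loop
toward the open, catalytically active state. `loopscape` turns multi-frame
structural ensembles of such complexes into state populations, contact
statistics, free-energy landscapes and cluster summaries — with a seeded
synthetic-trajectory generator so the whole pipeline is testable end to end
without any external data.

## What it computes

* **Loop states.** Per-frame distance between the mass-weighted centroids
  (heavy atoms, standard masses) of the occluding loop and the active-site
  residues; frames with d ≤ t are *closed* (default t = 16.5 Å), above it
  *open*. `threshold_scan()` gives the closed fraction as a function of t
  (the empirical CDF), and `open_fraction_fold_change()` the ratio of mean
  open fractions between conditions.
* **Contacts and filtering.** A contact is two heavy atoms of different
  chains strictly closer than 0.33 nm (3.3 Å). Ensembles are filtered to
  frames with any inter-chain contact, optionally restricted to a residue
  site such as the allosteric pocket {169, 215, 221, 222, 224, 333}.
  Per-residue statistics are contact counts normalised by frames (values
  above 1 mean multiple simultaneous partners), exportable as a network
  edge/node table.
* **ccPCA landscape.** Distances over an equal-size inter-chain heavy-atom
  mesh (smaller chain complete, larger chain strided to the same size; full
  m × m pair cross product) are collected per frame, centred, and projected
  onto two principal components. The PC1/PC2 histogram is converted to a
  Gibbs free-energy surface by Boltzmann inversion

  ΔG = −RT · ln(P / max P)

  (R = 0.008314462618 kJ mol⁻¹ K⁻¹, T = 300 K by default), so the modal bin
  has ΔG = 0 and empty bins are masked.
* **Clusters.** OPTICS (implemented in-package: reachability ordering plus
  xi extraction, cross-checked against scikit-learn) over the PC scores;
  clusters are reported in descending size with a representative frame
  (nearest the centroid) and per-cluster mean ± SD COM distance and open
  fraction.
* **Statistics.** One-way ANOVA across conditions with Šidák-corrected
  pooled pairwise t comparisons (`p_adj = 1 − (1 − p)^m`).

## Worked example

The default pipeline config simulates a reference condition (isolated
enzyme, open fraction 0.2) and an allosterically coupled binding condition
(bound frames open with probability 0.63), then runs every stage:

```r
library(loopscape)
cfg <- list(seed = 11, conditions = list(
  reference  = list(type = "two_state", role = "reference",
                    n_frames = 1200L, f_open = 0.2),
  allosteric = list(type = "binding", role = "case", n_frames = 1200L,
                    f_open = 0.2, couple_loop = TRUE, f_open_bound = 0.63)))
res <- run_pipeline(cfg, out_dir = "demo")
writeLines(res$report)
```

```
loopscape run report
seed: 11
threshold: 16.5 A | cutoff: 3.3 A | T: 300 K | bins: 100

condition      role         frames     kept  clustered  clusters    open_frac
reference      reference      1200     1200          -         -       0.2000
allosteric     case           1200      834        817         1       0.6067

open-state fold change (case / reference): 3.0336
one-way ANOVA across conditions: F(1, 2398) = 224.584, p = 1.33754e-48
```

Reading it: of the 1200 allosteric frames, 834 have the ligand in contact
with the enzyme (the bound pose, drawn at 70% occupancy); those frames form
one conformational cluster, and their loop is open 60.7% of the time versus
20.0% in the reference — a 3.03-fold increase in open (active) states for
this seed, with the planted value at 0.63/0.20 = 3.15. Per-condition output
directories contain `states.tsv`, `scan.tsv`, `ccpca_scores.tsv`,
`landscape.tsv`, `clusters.tsv`, `contact_network.tsv` and
`representatives.pdb`; the run writes `report.txt`, `compare.tsv` and the
resolved config. Reruns with the same config and seed are byte-identical.

A thin command-line wrapper over the same functions ships at
`inst/cli/loopscape.R` (subcommands `run`, `simulate`, `states`, `scan`,
`contacts`, `compare`, `--version`).

## Documentation

The methods vignette (`vignettes/loopscape-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic generator does and does not emulate, and the numerical
conventions (boundary handling, sign fixing, masking, determinism).
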