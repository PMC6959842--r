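# mdmotifs

Hydrogen-bond motif discovery and conformational-state analysis for
molecular-dynamics trajectories of protein–DNA complexes.

## What it is for

MD simulations of the mismatch-repair sensor MutSα (the MSH2–MSH6
heterodimer) bound to differently damaged DNA — cisplatin or carboplatin
adducts, FdU substitution — produce ensembles of frames whose differences
encode how the protein discriminates damage types.  `mdmotifs` is an R
workbench for asking *which features of the ensemble distinguish the damage
classes*:

- **H-bond motif mining.**  Frames become binary residue-pair hydrogen-bond
  vectors (donor–acceptor ≤ 3.2 Å, D–H–A angle ≥ 120°); a Gini-split binary
  classification tree is fitted with the damage class as the response, with
  leaf probabilities P(c | leaf) = count(c, leaf) / count(leaf), and pruned
  level-by-level from the bottom until only the few most discriminating
  contacts remain.
- **Amorim–Hennig clustering.**  Intelligent Minkowski-weighted K-means
  (anomalous-pattern initialization that selects K, per-cluster feature
  weights w_kv = 1/Σ_u (D_kv/D_ku)^{1/(p−1)}, explicit rescaling followed by
  a final K-means; p = 2 by default) partitions heavy-atom conformations into
  states, with per-system occupancy tables and representative frames.
- **Ensemble kinetics.**  Per-atom RMSF, Pearson dynamic cross-correlation
  matrices, coordinate-covariance PCA over a common basis, and free-energy
  landscapes ΔG = −kT ln(P/P₀) over (PC1, PC2) histograms
  (k = 0.0019872 kcal mol⁻¹ K⁻¹, T = 300 K).
- **Stacking states.**  A geometric classifier (centroid separation ≤ 5 Å,
  ring-normal angle ≤ 30°, lateral offset ≤ 2 Å) for whether a probe Phe ring
  stacks on the damaged base, the complementary base, or neither.
- **Synthetic data with planted ground truth.**  Seeded generators for
  Bernoulli H-bond matrices with planted discriminative bonds, Gaussian-well
  trajectories with flexible regions / coupled atoms / H-bond triads, and
  stacked/unstacked ring systems — so every stage has a parameter-recovery
  test without any MD data.

Trajectory I/O (PDB topology; DCD or multi-model PDB coordinates, with frame
striding, solvent stripping, Kabsch superposition and concatenation over
common atoms) is built on `bio3d`.

## Worked example

The demo configuration generates a three-class synthetic study (two planted
discriminative bonds among 50 background bonds; three conformational wells;
planted stacking states), runs every stage, and prints a report:

```r
library(mdmotifs)
bundle <- run_pipeline(demo_config(seed = 1))
summarize_bundle(bundle)
```

```
mdmotifs pipeline report
========================
seed: 1

decision tree (pruned):
  splits on: SYN:HB002, SYN:HB001
  leaf 1 [SYN:HB002 & SYN:HB001] -> Cis (Carbo 46.8%, Cis 49.4%, FdU 3.8%)
  leaf 2 [SYN:HB002 & !SYN:HB001] -> Cis (Carbo 0.4%, Cis 93.8%, FdU 5.8%)
  leaf 3 [!SYN:HB002 & SYN:HB001] -> Carbo (Carbo 94.8%, Cis 0.4%, FdU 4.7%)
  leaf 4 [!SYN:HB002 & !SYN:HB001] -> FdU (Carbo 9.5%, Cis 8.1%, FdU 82.5%)

prune curve (levels removed -> loss):
  0 -> 0.0000
  1 -> 0.0004
  ...
  15 -> 0.3816
  16 -> 0.6667

cluster occupancy (% of system frames):
  Carbo: cluster 1 (77.00%), cluster 2 (10.00%), cluster 3 (13.00%)
  Cis: cluster 1 (9.33%), cluster 2 (81.33%), cluster 3 (9.33%)
  FdU: cluster 1 (10.67%), cluster 2 (9.33%), cluster 3 (80.00%)

RMSF: peak 10.047 A at SYN:GLY6; median 3.443 A

stacking-state fractions:
  Carbo: stacked_damaged 6.33%, stacked_complement 88.67%, none 5.00%
  Cis: stacked_damaged 4.67%, stacked_complement 89.67%, none 5.67%
  FdU: stacked_damaged 61.00%, stacked_complement 8.00%, none 31.00%
```

Reading the output: the two-level tree recovered exactly the two planted
bonds (`SYN:HB001`, `SYN:HB002`) — a frame showing both bonds is labeled
"Cis" with the per-class leaf probabilities shown; the prune curve rises from
0 loss (full tree, 16 split levels) to the 2/3 majority baseline (root leaf,
three balanced classes); clustering recovered the three planted wells, each
dominated by its signature class (~80% occupancy, matching the generator's
design); and each class's stacking fractions track its planted state mix.
All artifacts (feature matrix, tree JSONs, prune curve, occupancy and label
CSVs, RMSF/DCCM/PCA/FES tables, log) are written to the configured output
directory and are byte-identical across reruns with the same seed.

The same stages run on real data by replacing `synthetic:` with `inputs:`
declarations (topology/coords/stride/label per system) in the config, or by
calling the module functions directly (`load_trajectory()`,
`detect_hbonds()`, `binarize()`, `fit_tree()`, `amorim_hennig()`, `rmsf()`,
`dccm()`, `pca_basis()`, `project_fes()`, `stacking_fractions()`, ...).

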