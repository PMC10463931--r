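# ddpd3 — dynamic protein descriptors from MD trajectories

Static protein descriptors used in proteochemometric (PCM) bioactivity
modelling — residue property scales, sequence embeddings — ignore protein
dynamics. `ddpd3` condenses a molecular-dynamics trajectory into
fixed-length **3D dynamic protein descriptors (3DDPDs)** and provides the
machinery to evaluate them: RMSD/RMSF trajectory analysis aligned to a
multiple sequence alignment (MSA), classical comparison descriptors and
compound fingerprints, a random-forest PCM/QSAR benchmarking harness with
seed-replicate significance testing and the AVE chemical-bias statistic,
and hierarchical clustering of descriptor vectors for variant
discrimination. It is aimed at computational drug-discovery groups working
with trajectory repositories (e.g. for class A GPCRs) and bioactivity sets
of pChEMBL-scale potencies.

## The method

For a trajectory of *F* frames, split into *S* = ⌊*F*/*f*⌋ blocks of *f*
frames, each selected atom contributes per block and axis the mean, median
and population SD of its coordinate ("coordinate" mode, 9·S columns) or the
SD alone ("rigidity" mode, 3·S columns), plus one Gasteiger (PEOE) partial
charge. After column-wise min-max standardization, a PCA over atoms retains
the smallest *k* components reaching a variance fraction *v*. Two routes
follow:

* **rs3DDPD** (residue-specific, one-hot-like): atom-PC scores are grouped
  per residue (mean and SD), standardized again, reduced to exactly *n*
  residue components, and placed at the target's MSA columns
  (position-major, `AA{column}_PC{c}`, zeros at gap columns):
  length *n·L*. With *n* = 5 on a 757-column class A alignment this is
  **3785 features**.
* **ps3DDPD** (protein-specific, embedding-like): per-target matrices are
  truncated to the shared *S*, stacked across targets, and reduced by one
  joint PCA retaining *m* components; each target aggregates component
  scores over its atoms as average/median/SD: length *3m* (**30 features**
  when the 95% rule retains ten components).

Defaults are the optimized settings: rs — rigidity, *f* = 100, *v* = 0.95,
*n* = 5, all heavy atoms, full sequence; ps — coordinate, otherwise
identical. Descriptor generation is deterministic: re-runs are
bit-identical.

## Worked example

```r
library(ddpd3)

# a synthetic 40-residue target with factor-structured dynamics
topo <- synth_topology(40)
traj <- synth_factor_trajectory(topo, n_frames = 2500, k = 8,
                                noise_sd = 0.05, noise_mod = 0.5, seed = 11)
topo
#> ddpd_topology: 200 atoms, 40 residues, 199 bonds
traj
#> ddpd_trajectory: 2500 frames x 200 atoms (nm)

# per-residue fluctuations
range(compute_rmsf(traj))        # nm
#> [1] 0.323 0.653

# residue-specific descriptor on a 757-column alignment
msa <- synth_msa(setNames(strrep("A", 40), "AA1R"), pad_to = 757)
rs <- compute_rs3ddpd(traj, msa, "AA1R")
rs
#> rs3DDPD for AA1R: 3785 features
round(rs[c("AA1_PC1", "AA1_PC2", "AA2_PC1")], 4)
#> AA1_PC1 AA1_PC2 AA2_PC1
#> -0.4294 -0.1409 -0.4537
```

Each feature name encodes an alignment column and a residue-stage
principal component, so model importances can be traced back to generic
receptor positions (`trace_feature("AA223_PC3", bw_table)` reports the
Ballesteros–Weinstein label or loop region of column 223). Bioactivity
benchmarking builds a model matrix of ECFP6-style fingerprints plus
protein descriptors (`build_feature_table()`), fits seeded random forests
(`train_eval_rf()`, `benchmark_pcm()`), and compares descriptor sets over
the ten fixed replicate seeds with `compare_descriptors()`.

A command-line front end (`exec/ddpd3`) exposes the fixture writers,
RMSF/descriptor generation and clustering as subcommands, e.g.
`ddpd3 rs --topology x.pdb --traj x.dcd --msa msa.fasta --target ID --out rs.csv`.

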