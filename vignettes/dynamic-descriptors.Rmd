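---
title: "Dynamic protein descriptors from MD trajectories: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic protein descriptors from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddpd3)
```

## The problem

Proteochemometric (PCM) bioactivity models predict compound potency across a
set of related targets by concatenating a compound descriptor (here a folded
circular fingerprint) with a protein descriptor. Classical protein
descriptors are static: one-hot residue property scales or whole-sequence
embeddings see only the sequence. Proteins, however, act through an ensemble
of conformations, and molecular dynamics (MD) trajectories record exactly
the per-atom fluctuation structure that static descriptors discard. This
package condenses an MD trajectory into fixed-length *dynamic* descriptor
vectors suitable for PCM modelling, and ships the surrounding machinery
needed to evaluate them: trajectory analysis (RMSD/RMSF aligned to a
multiple sequence alignment), classical comparison descriptors, a
random-forest benchmarking harness with seed replicates and significance
testing, and hierarchical clustering of descriptor vectors for variant
discrimination.

## The descriptor model

Generation proceeds in stages:

1. **Sub-trajectory statistics.** The trajectory of $F$ frames is divided
   into $S = \lfloor F/f \rfloor$ contiguous sub-trajectories of $f$ frames
   (remainder frames are dropped so every block is the same size; the
   field's deposition standard of 2500 frames with $f = 100$ gives
   $S = 25$). For every selected atom, sub-trajectory and axis the mean,
   median and population SD of the coordinate are computed (*coordinate*
   mode, $9S$ columns) or the SD only (*rigidity* mode, $3S$ columns).
2. **Charge channel.** One Gasteiger (PEOE) partial charge per atom,
   computed once from the bond graph with hydrogens present, is appended as
   a final column, so the descriptor sees atom identity as well as
   geometry. The feature matrix is therefore atoms $\times (9S{+}1)$ or
   $(3S{+}1)$.
3. **Standardization.** Every column is min-max scaled to $[0, 1]$.
   Constant columns map to zero, which keeps degenerate channels inert.
   The charge column is standardized jointly with the coordinate
   statistics — charges and statistics enter the PCA on an equal footing.
4. **Atom-stage PCA.** Rows are atoms, columns are the standardized
   features; the smallest number of principal components whose cumulative
   explained variance reaches the threshold $v$ is retained (default
   $v = 0.95$).
5. **Residue-specific route (rs3DDPD).** Atom-PC scores are grouped per
   residue as mean and population SD ($2k$ features per residue), the
   residue matrix is min-max standardized again (mirroring the atom-stage
   treatment) and reduced by a second PCA retaining exactly $n$ components
   (default $n = 5$). Each residue's scores are placed at its alignment
   column, position-major, giving a vector of length $n \cdot L$ with
   feature names `AA{column}_PC{c}`; the target's gap columns are exact
   zero blocks. With the class A GPCR alignment of $L = 757$ columns the
   default configuration yields $5 \times 757 = 3785$ features.
6. **Protein-specific route (ps3DDPD).** Per-target feature matrices
   (coordinate mode by default) are truncated to the minimum shared $S$
   across targets, stacked row-wise, standardized globally and reduced by a
   single atom-stage PCA retaining $m$ components. Each target aggregates
   every component's scores over its own atoms as average, median and
   population SD, PC-major, giving $3m$ features; when the variance rule
   retains ten components the vector has $30$ features.

Both defaults — rs: rigidity, $f{=}100$, $v{=}0.95$, $n{=}5$, all heavy
atoms, full sequence; ps: coordinate, $f{=}100$, $v{=}0.95$, all heavy
atoms — are the configurations found optimal for PCM regression under a
temporal split.

Descriptor generation contains no randomness: repeated runs are
bit-identical, which the test suite asserts.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mode` | rigidity (rs) / coordinate (ps) | which coordinate statistics feed the PCA |
| `frame_split` (f) | 100 frames | sub-trajectory length; trades temporal resolution against estimation noise of each statistic |
| `atom_variance` (v) | 0.95 | explained-variance fraction retained by the atom PCA |
| `residue_pcs` (n) | 5 | residue-stage components (rs only); fixes the per-column feature count |
| `atom_selection` | all-heavy | `all-heavy` excludes hydrogens; `non-carbon` additionally drops carbons |
| `residue_selection` | full | `full` sequence, or an MSA-column-defined binding pocket |

Internal coordinates are nanometres; PDB/DCD I/O converts from Angstrom.
Because every column is min-max standardized, descriptor values are
unit-free and insensitive to the length unit.

## Numerical choices

* **Population SD** (divisor $N$) everywhere a spread is computed; the
  sample/population distinction is immaterial at $f = 100$ but the choice
  is fixed for reproducibility.
* **Remainder frames dropped** when $f \nmid F$: equal-sized blocks keep
  statistics comparable across sub-trajectories.
* **PCA sign convention:** each axis is oriented so its largest-magnitude
  loading is positive, making scores reproducible across platforms.
  Scores are validated against an independent covariance-eigendecomposition
  oracle to $10^{-8}$ in the tests.
* **Rank handling:** the variance rule may legitimately retain one
  component; only a rank-zero matrix errors. The residue PCA requires more
  residues than requested components and errors otherwise.
* **Degenerate standardization:** constant columns scale to zero rather
  than NaN.
* **Cross-target width reconciliation (ps):** trajectories of unequal
  length are truncated to the minimum shared sub-trajectory count before
  stacking (public GPCR deposits mix 1250-, 2000- and 2500-frame runs).
* **Boundary rules:** pChEMBL exactly at the 6.5 cutoff is *active*;
  records from the cutoff year onward are *test* in a temporal split;
  degenerate MCC denominators give 0; feature-importance ties break
  lexicographically.
* **RMSD/RMSF references:** RMSD is measured against the first frame after
  rigid-body superposition. RMSF superposes frames onto the mean structure
  (two-pass: fit to frame 1, average, re-fit) over the C$\alpha$ atoms —
  the standard choice where only the RMSD reference is conventionally
  fixed.
* **Atom PCA orientation:** rows are atoms and columns statistics, so
  components are patterns over sub-trajectory features and each atom
  receives a score per component ("PCs for each atom").
* **Alignment columns are all kept**, including columns that are gaps in
  every supplied target; the descriptor length then depends only on the
  alignment, not on the target set.
* **Hierarchical clustering** defaults to average linkage (UPGMA); the
  linkage is configurable and recorded in the output because flat clusters
  can differ by method. Distances are Euclidean over the *non-null bits*:
  columns zero (or missing) across the whole compared set — shared gap
  columns for rs vectors, unresolved positions for RMSF vectors — are
  removed, which never changes a pairwise distance. Flat clusters cut the
  tree at a fraction (default 0.7) of the final merge distance, joining
  merges strictly below the threshold.
* **AVE chemical bias** uses nearest-neighbour Tanimoto distances against
  a threshold grid (default 51 points on $[0,1]$, equivalent to
  $\mathrm{mean}(1 - d_{\min})$ on a dense grid); the grid is a
  configuration argument rather than hard-coded, since the operational
  constants live in the statistic's original definition.
* **Student's t-test** (pooled variance, two-sided) compares seed-replicate
  metrics, starred at 0.05 / 0.01 / 0.001.

## The synthetic generators

No public trajectory or bioactivity data is bundled; generators produce
inputs with known statistical structure so every stage is testable offline.

* `synth_topology()` replicates a residue template (peptide backbone
  N/CA/C/O/H by default, with the carbonyl double bond so PEOE sees sp2
  centres) into a bonded chain; reference coordinates follow a coarse
  helix so superposition code paths are non-degenerate.
* `synth_trajectory()` adds isotropic Gaussian displacements, i.i.d.
  across frames, atoms and axes, with per-residue SD $\sigma_r$. The
  closed form $\mathrm{RMSF} = \sigma\sqrt{3}$ makes recovery testable:
  at $F = 2500$ the estimate lands within 5% (the tests use 60 residues so
  the six rigid-body degrees of freedom absorbed by superposition cost
  under 2%). No autocorrelation is modelled — sub-trajectory statistics
  remain well defined and analytic.
* `synth_factor_trajectory()` drives sub-trajectory block means (and,
  optionally, the within-block noise SD) by `k` orthonormalized latent
  factor patterns. The per-atom statistics matrix then has `k` dominant,
  near-equal variance directions, which is the knob used to exercise the
  explained-variance rule at a chosen rank: ten shared factors across a
  stack of targets retain exactly ten components under the 95% rule. It is
  also the fixture for the full residue-specific pipeline, whose default
  five residue components need an atom-stage spectrum richer than the
  plain i.i.d. model produces.
* `synth_msa()` lays sequences into an alignment with per-target gap
  plans and padding; `synth_bioactivity()` draws additive
  target + compound + noise pChEMBL values over a fixed embedded pool of
  50 valid drug-like SMILES, with uniform publication years, so both split
  flavours and signal-recovery checks are exercisable.

What the generators deliberately do **not** emulate: force-field physics,
autocorrelated dynamics, membrane/solvent atoms, replicate-to-replicate
variability, and realistic chemical series. Passing tests therefore
demonstrate the pipeline's algebra, determinism and statistical behaviour
under known signal — not predictive performance on real receptors, which
requires real trajectories and bioactivity data.

## Benchmark harness

`train_eval_rf()` wraps a random forest (ranger backend) at library-default
hyperparameters — deliberately untuned so descriptor comparisons carry the
fewest degrees of freedom — with seeded 5-fold cross-validation on the
training side, test-set MCC (classification) or Pearson *r* and RMSE
(regression), and impurity importances for feature traceback via
`trace_feature()`. `qsar_baseline()` fits one compound-only model per
target and reports the unweighted mean metric. The replicate loop uses the
ten fixed seeds `r paste(ddpd_seeds(), collapse = ", ")` and is
bit-reproducible single-threaded.

Problem sizes used by the shipped test suite were chosen to make the
statistical assertions sharp at interactive runtimes: signal-recovery runs
use 2000 records (40 synthetic targets x 50 compounds) over three seeds,
with label-shuffled controls; the ten-seed reproducibility check runs on a
12-target subset; closed-form RMSF recovery uses 2500 frames.

## Known limitations

* Trajectory input is PDB + DCD; XTC/TRR readers are not available in the
  R toolchain this package builds on, and error explicitly.
* Fingerprint hashing is deterministic within this package but not
  bit-compatible with other cheminformatics toolkits; SMILES are
  canonicalized (Open Babel) before hashing so rewritings of one molecule
  collide correctly.
* PEOE charges cover H/C/N/O/S/P/halogens with hybridization inferred from
  bond orders; exotic elements and formal charges are out of scope.
* Residue scale tables ship for two z-scale flavours (5- and 3-component),
  MS-WHIM and a five-property physicochemical table assembled from
  standard amino-acid constants; an ST-scale table is not bundled because
  no offline source of the published values was available to embed.
* Replicate trajectories are not aggregated; descriptors describe a single
  replicate, and conformational changes induced by ligand binding are not
  represented.
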