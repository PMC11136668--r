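---
title: "Methods: flexibility descriptors, curation heuristics and graph baselines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flexibility descriptors, curation heuristics and graph baselines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ligdyn is a desk-scale toolkit for working with protein–ligand complexes
that have been augmented along two orthogonal axes: quantum-chemical
descriptors of the ligand (consumed as inputs, never computed here) and
molecular-dynamics trajectories of the complex. This vignette explains the
models and procedures the package implements, the assumptions behind them,
the tunable parameters and their defaults, and what the synthetic study
conditions do and do not demonstrate.

## Data model

A complex is an ordered atom table (element, labels, role, Cartesian
coordinates in Å, optional B factor in Å², mass in Da) with derived
protein/ligand index partitions. Waters and monatomic ions are retained in
the table but excluded from both partitions, so every downstream metric and
featurization operates on protein and ligand atoms only. Missing B factors
are `NA`, not 0 — zero is a legal B value. Internally everything is 1-based
and in Å; PDB serial numbers are carried only as labels.

Trajectories are `[n_frames × n_atoms × 3]` arrays with strictly increasing
frame times; the generator default of 100 frames over 8 ns mirrors the
common practice of storing ~100 snapshots of a production run after
discarding equilibration. Trajectory, quantum and affinity records are
stored in a hierarchical HDF5 layout, one group per entry keyed by its PDB
ID, with the measurement axis encoded in the dataset-name prefix
(`atoms_*`, `frames_*`, `trajectory_*` for dynamics; `molecular_*`,
`atomic_*` for quantum data). The exact key strings of any particular
published file are not assumed: `read_h5()` accepts a key map (also
loadable from a YAML configuration) that translates canonical names to the
names present in the file, so foreign files are readable on a best-effort
basis.

## Trajectory descriptors

All descriptors first remove global rigid-body motion. The superposition is
the closed-form least-squares rigid fit (Kabsch, via a 3×3 SVD with a
reflection guard), applied per frame over an alignment selection that
defaults to protein heavy atoms — the same convention that defines ligand
RMSD "after alignment of the protein". Whether a published adaptability
used all-atom or Cα alignment is not fixed by convention, so the selection
is an explicit parameter.

**Adaptability.** For atom $x$ with reference position $r_{\mathrm{ref},x}$
(frame 1 by default),

$$\gamma_x = \frac{1}{N_{\mathrm{frames}}} \sum_i^{N_{\mathrm{frames}}}
\left| r_{\mathrm{ref},x} - r_{i,x} \right|,$$

the mean Euclidean distance from the reference across all frames of the
aligned trajectory. The sum runs over *all* timesteps and the divisor is
$N_{\mathrm{frames}}$, so the reference frame contributes a zero term and is
included by default; `include_reference = FALSE` gives the
$N_{\mathrm{frames}}-1$ variant. Hydrogens are dropped by default (they
roughly double model size while adding little signal). Under i.i.d.
isotropic Gaussian displacements with per-axis s.d. $\sigma$ the distance is
Maxwell-distributed, so $\gamma \to \sigma\sqrt{8/\pi}$, RMSF
$\to \sigma\sqrt{3}$, and $\gamma/\mathrm{RMSF} \to \sqrt{8/(3\pi)} \approx
0.921$ — these closed forms are the package's strongest self-checks.

**RMSF** is the root-mean-square deviation of each atom about its time-mean
aligned position (≥ 2 frames). **Ligand RMSD** superposes each frame on the
protein and evaluates the ligand deviation without re-fitting the ligand.
**Centre-of-mass distance** is mass-weighted by default (geometric centroid
by flag; the convention is not universal). **Buried SASA** is
$\mathrm{SASA}(P) + \mathrm{SASA}(L) - \mathrm{SASA}(PL)$ with each term
from a Shrake–Rupley sampler: Bondi van der Waals radii, probe 1.4 Å, and a
deterministic 960-point Fibonacci lattice per atom (all configurable). At
960 points the sampler reproduces an isolated sphere exactly and the
two-sphere spherical-cap closed form to better than 1%.

## Structure-curation heuristics

The published curation protocol is quantum-chemical (wavefunction
convergence, population analysis, optimization-induced connectivity
changes). ligdyn re-expresses each check at the geometry/connectivity level
so the logic is exercisable without any electronic-structure code, and
treats quantum-derived fields (HOMO–LUMO gap, electron count, charges,
polarizabilities) as inputs:

* **Clashes**: non-bonded pairs closer than 0.5 × the summed covalent radii.
  A cell-list grid and the all-pairs enumeration are both implemented and
  must agree exactly; the grid is the default.
* **Bond/hybridization perception**: bond iff distance ≤ r_cov(a) +
  r_cov(b) + 0.4 Å; order upgraded when the distance falls below the
  midpoint between reference lengths of adjacent orders; hybridization from
  bonded-neighbour count plus local planarity (3-coordinate) or bond angle
  (2-coordinate).
* **Valence audit**: an atom fails when its bond-order sum corrected by the
  formal charge exceeds the element's allowed valence (C 4, N 3 — so
  neutral 4-coordinate N fails while N⁺ passes — O 2, S 6, …). A one-bond
  neighbourhood whose formal charges sum to +2 or more is flagged as local
  charge excess: the signature of an over-protonated group such as a
  guanidinium carrying +3 around its central carbon.
* **Reference-geometry checks**: bond lengths against a small internal
  CCCBDB-style table (>10% deviation flags), angles against the ideal VSEPR
  value for the centre's hybridization (>12° flags), and pyramidalization
  of sp² centres (>0.25 Å out-of-plane flags). These checks compare the
  observed geometry to the *intended* chemical graph passed in: a nitro N–O
  stretched 17% reads as a clean single bond if re-perceived from the
  distances, which is precisely why the stretched geometry is pathological.
  The defaults were chosen so that idealized geometry passes silently while
  deformations of the magnitude seen in curated ligand sets (bonds ~17%
  long, angles ~20° open, pyramidal sp² centres) are flagged; all are
  configurable.
* **Connectivity comparison** reports the symmetric difference of two bond
  sets (created/broken bonds) separately from order changes.
* **Property-outlier screening** fits, per element group of at least 8
  points, a least-squares line of polarizability on partial charge and
  flags robust (median/MAD) residual z-scores above 4 — the wrong-element
  signature. Degenerate groups fall back to a univariate screen.

A report's verdict is `clean` only when no warning- or failure-level
finding exists. The package reports; it never repairs structures — manual
inspection is the appropriate follow-up for the handful of extreme cases
such checks surface. The separate model-training filter is much wider
(20 s.d., single pass over all entries) because its only job is to drop
pathological regression targets, not to judge structures. Note an
arithmetic consequence of the single-pass rule: one outlier among $n$
entries can reach a z-score of at most about $\sqrt{n}$, so a 25 s.d. point
is only constructible in samples of more than ~625 entries.

## Graph featurization

Nodes are retained heavy atoms; an undirected edge joins every pair within
4.5 Å ("nearest neighbours within a distance" is read as a radius
criterion, not k-nearest, since no k is ever specified and the weight rule
is distance-based); each edge is weighted 1/d in Å⁻¹. Node features start
with a one-hot element block over {C, N, O, S, P, F, Cl, Br, I, other};
optional per-atom blocks (partial charge, adaptability) are appended in
declared order, each with a 0/1 mask column so absent values are
distinguishable from zeros. Edge structure depends only on pairwise
distances, hence is exactly invariant under rigid motion. Pocket selection
keeps whole residues: every protein residue with any heavy atom within 8 Å
of any ligand heavy atom, plus the ligand.

Training-time augmentation translates every node independently by a
per-axis uniform draw in [−0.05, +0.05] Å and recomputes edges and weights.
A uniform law was chosen because only an amplitude is conventionally
quoted; a Gaussian alternative is a flag.

For relative-affinity learning, records are clustered by (protein group,
affinity type) so each cluster holds one protein and one measurement type;
singleton clusters are discarded. Within a cluster one base molecule is
paired with every other member and the label is
$\log_{10}(K_\mathrm{target}/K_\mathrm{base})$ — decimal, matching pKi/pKd
conventions. The base-molecule choice is not fixed by convention; ligdyn
uses the cluster-median affinity entry (ties broken by smallest entry id),
which centres the label distribution and is recorded in run metadata. The
base is not paired with itself by default (a flag adds the zero-label
pair).

## Baseline models

Three learners, written as plain matrix algebra with analytic
backpropagation and Adam (no deep-learning runtime is required):

* **Graph-level quantum-property regression**: a dense embedding layer,
  then sequential message-passing blocks whose messages are conditioned on
  the edge weight through a learned softplus gate and whose node state is
  updated by a GRU cell shared across blocks, then sum pooling and a dense
  head with two outputs (electron affinity and chemical hardness,
  standardized to unit variance during training and de-standardized at
  inference, with equal loss weight).
* **Node-level adaptability regression**: sequential edge-weighted graph
  convolutions followed by two linear layers per node — no pooling of node
  features into graph features. The convolution aggregates neighbour
  features with the raw edge weights plus a self-loop (sum aggregation)
  rather than symmetric normalization, deliberately: normalization divides
  out exactly the degree information a flexibility target depends on.
* **Twin relative-affinity model**: one shared-weight encoder runs on both
  complexes of a pair; ligand and protein nodes are pooled separately by
  mean, the concatenated embedding passes through three linear layers with
  ReLU nonlinearities to a scalar score, and the prediction is
  score(target) − score(base). Antisymmetry under swapping and exact zero
  on identical pairs therefore hold by construction, not by training.

Reference-scale settings (3 message-passing blocks / batch 128 / 200 epochs
for the quantum task; 5 convolutions / batch 8 / 15 epochs for the node
task; 5 convolutions / batch 50 / 50 epochs for the pair task, at
~370k parameters) are recorded in every training log; the desk defaults
(hidden width 16, 2–3 blocks, ~10³–10⁴ parameters, around 150 epochs,
learning rate 10⁻³–10⁻²) train in seconds to minutes on one CPU. Per-layer
widths, conv-block activations and the loss reduction (per-node mean within
a graph, then mean over the batch) are implementation choices logged with
each model, not claims about any reference implementation. With a fixed
seed and a single thread, training is reproducible run-to-run; predictions
are computed per graph, so they are independent of batching by
construction.

## Benchmark construction, splitting, validation

Benchmark sets group affinity records by (publication, protein group,
affinity type) and require ≥ 15 entries; a *high dynamic range* is
quantified as ≥ 2 decades of affinity (a 100-fold span) — a reasonable
reading of "high", exposed as a parameter since no number is conventional;
*few additional occurrences* of the protein elsewhere is quantified as ≤ 5
(likewise a parameter); groups with a cofactor or metal at the binding site
are excluded by default.

Leakage-aware splitting clusters sequences by single-linkage at 30%
similarity and assigns whole clusters to train/validation/test by seeded
greedy bin-packing toward the target fractions (82/9/9 and 80/10/10 are
both in use for different tasks; the fractions are a parameter). Similarity
is 3-mer containment identity — an alignment-free stand-in chosen to avoid
an external alignment-tool dependency while preserving the threshold
semantics; because single linkage merges *any* pair at or above the
threshold, no cross-split pair can reach it, which the tests verify by
exhaustive post-check.

B-factor validation drops entries whose modal B value accounts for ≥ 80% of
atoms (the boundary-inclusive reading — more exclusions — of the cleaning
rule for placeholder B columns), then correlates per-atom B factors with
RMSF per entry and averages. Pearson correlation is invariant under affine
rescaling of B, so a B = a + b·RMSF entry scores exactly 1.

## Synthetic study conditions

The generators fabricate: complexes (helical 4-atom-residue backbone plus
an idealized all-trans ligand chain built from the internal reference
geometry, placed in 3–4 Å contact without clashes), trajectories (frame 1 =
input; later frames add i.i.d. per-atom Gaussian displacements from a
mobility profile, then one shared random rigid motion of up to 10°/3 Å per
frame so alignment is non-trivial but solvable), quantum tables (targets
that are fixed linear functions of element counts + noise of 0.05 eV;
per-element charge/polarizability pairs on a noisy line with planted
off-line outliers at ~10× the residual spread), and affinity clusters (true
log₁₀ affinity linear in ligand composition, noise 0.1 decades, with
optional planted filter violations).

Displacements are i.i.d. Gaussian rather than force-field dynamics *on
purpose*: the ground-truth adaptability is then analytically
$\sigma\sqrt{8/\pi}$, which is what makes the fixture an oracle. The
conditions therefore validate the estimators, the combinatorial procedures
and the learnability of the architectures; they do not emulate
time-correlated dynamics, solvent effects, anisotropic fluctuations, real
experimental B-factor noise, or chemistry beyond idealized chain ligands,
so passing tests certify the machinery, not real-data performance. In
particular the learnability checks use targets that are linear in
composition or neighbour counts — recoverable signals by construction —
and desk-scale scores on them say nothing about scores on a full curated
database.

Problem sizes used by the test-suite and the acceptance script — 5,000
frames for the Maxwell limit (sampling error well inside the 2% band),
200-point graphs against the O(n²) oracle, ~1,000 pooled atoms for outlier
recovery, 120–220 molecules per learnability task, 100 entries for the
null B-factor simulation — were chosen as the smallest sizes at which the
statistical tolerances are comfortably non-marginal.

## Numerical and degenerate-input policy

Superposition requires ≥ 3 non-collinear selected atoms (the SVD rank is
checked); RMSF requires ≥ 2 frames; correlations require n ≥ 2; a zero
standard deviation disables the wide-band filter rather than dividing by
zero; empty prediction inputs return empty outputs; a missing reference
bond length is an info-level finding, never a failure; top-k selection
breaks ties by descending value then ascending index so evaluation is
deterministic. All randomness flows through explicit integer seeds, and the
command-line layer writes a provenance record (tool version, subcommand,
parameters, seed) beside every output, with errors mapped to stable exit
codes (0 ok, 2 usage, 3 format, 4 validation, 5 internal).

## Known limitations

Quantum quantities are consumed, never computed; no force-field energies
(the MMGBSA slot in frame properties is accepted as input data); no
automatic structure repair; no mmCIF, first model only for multi-model PDB
files; absent B factors serialize to PDB as 0.00 because the fixed-column
format has no empty encoding (in memory they stay `NA`); k-mer containment
is a coarse proxy for alignment identity — adequate for leakage prevention
at a 30% threshold, not for fine phylogenetic distinctions; and the
hand-rolled learners target desk-scale clarity and reproducibility, not
GPU-scale throughput.
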