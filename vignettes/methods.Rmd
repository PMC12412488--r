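---
title: "Three-graph geometric message passing: model, training, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-graph geometric message passing: model, training, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The representation problem

Conventional molecular graph networks see atoms and bonds but not shape:
two conformers, or two enantiomers, have identical graphs. tripod3d
encodes a conformer through three linked graphs,

* **G** (atom-bond): atoms are nodes, bonds are edges;
* **H** (bond-angle): bonds are nodes; a bond angle $(u, v, w)$ — two
  bonds sharing the apex atom $v$ — is an edge;
* **I** (angle-dihedral): bond angles are nodes; a dihedral
  $(u, v, w, x)$ — two angles sharing the central bond $(v, w)$ — is an
  edge,

with the continuous internal coordinates attached as features: bond
lengths $l_{uv}$ on the H-level nodes, bond angles
$\phi_{uvw} \in [0, \pi]$ on the I-level nodes, and **signed** torsions
$\theta_{uvwx} \in [-\pi, \pi)$ on the I-level edges. Because every input
is an internal coordinate, the embedding is exactly invariant to proper
rigid motions and to atom relabeling. A mirror reflection negates every
non-degenerate torsion while leaving lengths and angles unchanged, so the
representation separates enantiomers precisely when the torsion features
are present — ablating them (zeroing the torsion inputs) recovers a
mirror-invariant bond-angle model, and disabling the H level as well
recovers a plain atom-bond GNN. These nested ablations are part of the
API (`network_config(use_dihedral_level=, use_angle_level=)`).

## Update equations

One iteration updates the three levels top-down, I then H then G, so each
lower level sees the current iteration's higher-level state as its edge
embedding:

1. every angle aggregates its dihedral-neighbor angles plus the torsion
   embedding of the connecting dihedral;
2. every bond aggregates its angle-neighbor bonds plus the shared angle's
   (just-updated) hidden state;
3. every atom aggregates its neighbor atoms plus the connecting bond's
   (just-updated) hidden state.

Aggregation and combination follow the Graph Isomorphism Network: sum
aggregation, then a two-layer perceptron applied to
$(1+\epsilon)\,h + a$ with learnable $\epsilon$, a residual connection,
layer normalization (with learnable gain and bias), and graph normalization
(aggregates divided by the square root of the level's node count).
Both orientations of every bond, angle, and dihedral participate, so
messages flow symmetrically. After $K$ iterations the molecule embedding
is the mean of the final atom states; the per-atom states feed atom-level
heads. Defaults: hidden width 32, $K = 8$, dropout 0.2 (supervised
training only — see below).

An earlier-state variant (lower levels reading the *previous* iteration's
higher-level states) is equally expressive when weights are
per-iteration; the current-state order is what makes the top-down update
sequence meaningful, and is what we implement.

## Self-supervised pretraining

Masking follows a first-order-neighborhood rule: 15% of atoms (at least
one) are selected uniformly; the features of the selected atoms, their
adjacent atoms, the bonds touching a selected atom, and every angle and
dihedral containing a selected atom are replaced by a reserved mask
token. Targets are only elements containing a selected atom. Masked
elements keep their graph connectivity — masking hides attributes, not
structure.

Six losses are available, all driven by heads on the final atom states:

* squared error of the masked bond lengths, bond angles, and dihedral
  angles (the dihedral is compared through its $(\sin, \cos)$ pair, which
  respects the $2\pi$ wrap; a raw-angle mode exists behind
  `dihedral_target = "raw"` for strict fidelity to the squared-error
  formulation);
* a 30-class cross-entropy on the binned interatomic distance over (up
  to 500, subsampled) ordered atom pairs, bins of equal width on
  [0, 15] Å with clamping;
* squared error of masked-atom partial charges and masked-bond
  Wiberg-style orders (the electronic stage).

Pair heads use the sum of the two endpoint states, so they are symmetric
by construction. Degenerate geometry (collinear angle or dihedral
frames, as in nitriles) is flagged at geometry time and excluded from the
corresponding losses rather than erroring.

Pretraining runs in two stages: geometry first (on MMFF94 conformers),
then electronic (warm-started from the geometry weights) — plus
single-stage and no-pretraining variants, giving the four strategies
exposed by `pretrain_strategy()`. Optimization is mini-batch Adam
(learning rate $10^{-3}$, batch 16) with a fresh mask plan per molecule
per epoch, each derived deterministically from (master seed, epoch,
molecule id); two runs with the same seed are bitwise identical. The four
geometric tasks are optimized jointly with unit weights (configurable);
nothing in our experiments suggested a round-robin schedule was needed.

Two training-efficiency choices matter at desk scale and are deliberate
defaults:

* **no dropout during SSL** — the self-supervised stages are fitting
  problems; regularization noise only slows convergence of a small model
  on a small corpus. Fine-tuning keeps dropout 0.2.
* **scale-aware head initialization** — scalar regression heads start
  with their output bias at the typical target value (1.45 Å, 1.95 rad,
  bond order 1), so the few hundred Adam steps of a desk-scale run are
  spent learning deviations, not climbing from zero to the target scale.

## Fine-tuning and evaluation

Datasets are partitioned by Bemis–Murcko scaffold (generic carbon-
skeleton variant behind a flag): groups sorted by descending size then
scaffold string, filled greedily into train until the train fraction is
reached, then validation, then test; molecules sharing a scaffold are
never separated. Fractions default to 0.8/0.1/0.1, the MoleculeNet
convention. A two-layer perceptron head on the pooled embedding
(molecule tasks) or the atom states (atom-level regression) is trained
end-to-end with Adam, early-stopped on the validation metric (patience
10, up to 100 epochs), and the test score of the best-validation epoch is
reported as mean ± standard deviation over 4 repeats with distinct
seeds. ROC-AUC uses the rank statistic (ties half-counted; identical to
exhaustive pair counting), and multi-task classification averages the
tasks with both labels present.

## Discrimination experiments

`run_discrimination_experiment()` perturbs each conformer with
independent one-sided uniform$(0, 0.5)$ Å noise per coordinate (exactly
as stated — the induced net translation is removed by alignment),
embeds original and perturbed copies under dihedral-enabled and
dihedral-ablated encoders, and reports per-molecule embedding distances,
the Davies–Bouldin index over the original/perturbed labels, and the
mean Kabsch-aligned RMSD. RMSD uses proper-rotation superposition
(reflections excluded): for centered uniform noise with per-coordinate
variance $0.5^2/12$ the expected aligned RMSD is approximately
$0.25\sqrt{(3n-6)/(3n)}$ Å — about 0.235 for a 20-atom molecule, and
about 0.232 averaged over the built-in drug-like set (mean ≈ 17 heavy
atoms), which is what `scripts/acceptance.R` recomputes. Raw, un-normalized
embeddings enter the Euclidean distances and the Davies–Bouldin index;
normalizing would only rescale distances without changing the
separation ordering, and the index is scale-invariant anyway.

Enantiomer pairs used in tests are constructed as a conformer and its
exact coordinate mirror image, which shares every length and angle and
negates every torsion. Stereoisomer sets from SMILES enumeration instead
differ in their chirality tags and relaxed geometries; both routes are
exposed.

## The fixture generator

`builtin_molecules()` is a fixed list of ~310 molecules: named drugs and
natural products, four enumerated drug-like families (para-substituted
benzamides, biphenyl amides, sulfonamides, phenoxyacetamides, pyridine
amides, aryl esters) sized like screening-library compounds (mean ≈ 17
heavy atoms), molecules with 1–4 stereocenters, and degenerate edge
cases (single atom, diatomic, linear nitrile, benzene). Conformers come
from seeded MMFF94 embedding, so the whole dataset is reproducible to a
digest.

Surrogate electronic labels emulate quantum-chemical targets without any
quantum chemistry: charges follow an electronegativity-difference rule
$\psi_u = \kappa\,(EN_u - \overline{EN}_{N(u)})$ plus Gaussian noise
(σ = 0.02), clipped to $[-1, 1]$ and re-centered to sum to the formal
charge; bond orders are the nominal order minus
$c\,(l_{uv} - l_{\mathrm{ref}})$ plus noise, with $c = 2$ per Å. The
charge surrogate is deliberately topology-driven (so learning it tests
the masking/recovery machinery, not conformer quality) while the
bond-order surrogate deliberately depends on the conformer's bond
lengths (so learning it requires using the geometry input). Toy
supervised targets are a documented linear function of heteroatom,
ring-bond, and rotatable-bond counts (coefficients 0.5/0.2/0.3, noise σ
0.3; classification thresholds the score at 5.5, the median noiseless
score of the built-in list).

What passing on these fixtures does **not** show: the surrogates have no
conformational polarization, no resonance, and the fixture chemical
space is far narrower than a real screening library; results transfer to
real charge schemes (CM5/NPA/Hirshfeld) only in the qualitative sense
that the training machinery recovers learnable signal through masking.

## Problem sizes and numerical choices

Desk-scale defaults used by the test-suite learning checks: 200
pretraining molecules, 20 geometry epochs / 30 electronic epochs, hidden
width 32, $K = 3$ (a shallow network keeps a 20-epoch run in the
well-optimized regime; the $K = 8$ default targets larger corpora);
fine-tuning comparisons use 50 labelled molecules and 4 seeds.
These sizes are the package's chosen demonstration conditions.

Other numerical choices: angle cosines are clamped to $[-1, 1]$ before
`acos`; collinear frames are flagged when the normalized cross product falls below $10^{-2}$ (within about half a degree of collinear); coincident bonded atoms (< $10^{-6}$ Å) are an
error; softmax cross-entropy is computed with max-shifted logits and a
$10^{-12}$ floor; layer normalization uses population variance with
$10^{-5}$ stabilizer; Kabsch alignment corrects the SVD determinant sign
to exclude reflections, and below 3 atoms falls back to translation-only
alignment (flagged). Distances entering the binner are clamped into the
edge bins, so out-of-range geometry cannot error.

A desk-scale caveat: the masked bond-length task is the hardest of the
four geometric tasks under the first-order-neighborhood masking rule
(both endpoints of every target bond have their attributes hidden), and
at a few hundred optimizer steps the margin by which the trained model
beats a constant-mean predictor on that one term is small and varies
with the run seed; the angle, torsion, distance, and electronic tasks
show comfortable margins. On a corpus thousands of molecules deep this
distinction disappears, but it is the honest picture at the
demonstration sizes above.

## Known limitations

Single lowest-energy conformer only (no ensembles); heavy-atom graphs
(hydrogens are features, not nodes); no long-range or intermolecular
terms; the hand-written trainer is single-threaded and intended for
desk-scale corpora, not millions of molecules; checkpoints store dense
weights as JSON text. The chemistry backend requires a Python with RDKit
on the PATH.
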