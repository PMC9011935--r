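---
title: "Methods: deep clustering of small-molecule libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep clustering of small-molecule libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large screening libraries — tens of thousands of small molecules given only
as SMILES strings — need to be grouped into structurally coherent clusters
before they can inform diversity analysis, training-set design for QSAR/QSPR
models, or hypotheses about shared mechanisms of action. No labels exist, so
the whole pipeline must be unsupervised: featurize every molecule, compress
the features into an embedding, cluster, and judge the clustering with
internal (ground-truth-free) indices.

`molcluster` implements that pipeline end to end. This vignette records the
model choices, their assumptions, and the numerical conventions that make
the results reproducible.

## Molecular representations

Three representations are computed per molecule:

1. **Global descriptors** — one real vector per molecule. The default set
   combines an in-package suite of constitutional and topological
   descriptors computed from the molecular graph (molecular weight, ring and
   element counts, hydrogen-bond donors/acceptors, rotatable bonds, Wiener
   index, Balaban's J, Zagreb and Randić indices, kappa shape indices,
   eccentric connectivity, and so on) with physicochemical properties from
   OpenBabel (logP, TPSA, molar refractivity, Lipinski donor/acceptor
   counts). The descriptor count `D_g` is toolkit-dependent and is recorded
   in run metadata rather than assumed. A descriptor that evaluates to
   `NA`/`Inf` (for example, OpenBabel properties of a single-atom molecule)
   is logged and imputed to 0 before z-scoring — never propagated silently.

2. **Atomic feature matrix** (`n_atoms` × 145) — one-hot blocks in fixed
   order: atom type (118, by atomic number), degree (6), formal charge (5,
   bins −2…+2), chirality (4: unspecified/CW/CCW/other), bonded hydrogens
   (5), hybridization (5: sp, sp², sp³, sp³d, sp³d²), aromaticity (1), and
   atomic mass divided by 100 (1). Out-of-range categories (degree > 5,
   charge beyond ±2, > 4 hydrogens) are clamped to the last bin of their
   block so the width never varies.

3. **Bond feature matrix** (`n_bonds` × 12) — bond type (4:
   single/double/triple/aromatic), conjugated (1), in-ring (1), and stereo
   (6: none/any/Z/E/cis/trans).

SMILES parsing is done by an in-package parser covering the organic subset,
bracket atoms, branches, ring closures, aromatic lowercase notation,
`@`/`@@` tetrahedral chirality, and `/ \` directional bonds, because the
featurizer needs attributes (chirality, double-bond stereo, aromatic
perception, implicit hydrogen counts) that are not all preserved by the
available toolchain's SDF route. OpenBabel is still used for SMILES
canonicalization (the round-trip invariant `parse → canonical → parse`
is tested against it) and as an independent cross-check on atom/bond counts
in the test suite. Two perception conventions worth noting:

* *Stereo*: directional-bond analysis yields the cis/trans categories; the
  E/Z slots (which require CIP priority ranking) and "any" exist in the
  block layout but are not produced by the parser.
* *Conjugation*: a bond is conjugated when aromatic, when a multiple bond
  is adjacent to another π bond or to a lone-pair heteroatom, or when a
  single bond links two π centres (or a π centre and a lone-pair N/O/S).
  This tracks the usual toolkit notion closely enough for a one-hot flag.

## Feature engineering

Atom and bond matrices have molecule-dependent row counts, so they are
aggregated to a fixed length before anything dataset-wide can happen:

* **Per-molecule PC1 scores.** The *transposed* atomic matrix (145 rows =
  the fixed feature axis, columns = atoms) is centered per column and its
  rows are projected on the first principal component of the column
  covariance. That yields exactly 145 numbers per molecule regardless of
  size; the bond matrix gives 12 more, for a 157-long local vector. This
  orientation is the only one that produces a fixed-length vector for
  variable-size molecules. PCA signs are arbitrary, so the loading entry
  with the largest absolute value is made positive. Degenerate cases are
  defined, not exceptional: a single column degenerates to centering, a
  zero-variance matrix returns the zero vector, and a bond-free molecule
  contributes 12 zeros.
* **Dataset-level PCA.** The molecules × 157 matrix is centered (no
  scaling) and reduced to its top 50 components; explained-variance ratios
  go into metadata.
* **Z-scoring.** Global descriptors are standardized per column with the
  population SD (divide by *n*); the convention is immaterial at library
  scale but must be fixed for reproducibility. Constant columns become
  zero and are flagged.
* **Fusion and filtering.** The 50 local components and the z-scored
  descriptors are concatenated and columns with population SD below 1e−12
  are dropped (the tolerance guards float noise around an exact-zero-
  variance rule); dropped names are logged. Whether the second PCA should
  also scale its 157 inputs was an open choice; we center only, consistent
  with the local features already being one-hot/0.01-scaled.

## Embeddings

The fused table is compressed with a feed-forward autoencoder. The encoder
applies six blocks of (affine map → batch normalization → ReLU) and an
affine head producing `d` values (plain AE) or `2d` values interpreted as a
mean `E(Z)` and log-variance (VAE); the decoder mirrors the encoder. The
objective is mean squared reconstruction error per row, plus for the VAE
the KL divergence of the diagonal Gaussian posterior from the standard
normal,

$$L = \frac{1}{m}\sum_j \lVert x^j - \hat{x}^j\rVert^2
  + \frac{\beta}{2} \sum_{i=1}^{d}\bigl(V(Z) - \log V(Z) - 1 + E(Z)^2\bigr)_i ,$$

with the KL term averaged over the batch. Since $v - \log v - 1 \ge 0$ for
all $v > 0$, the term is non-negative and vanishes exactly at
$E(Z)=0, V(Z)=1$; $\beta = 0$ recovers the plain reconstruction objective.
Parameterizing the variance as $V(Z) = \exp(\cdot)$ keeps it positive by
construction.

Choices that the architecture sketch leaves open, fixed here: squared error
as the per-row reconstruction loss (the inputs are continuous z-scored
features); six blocks with default widths 128–96–64–48–32–24 (configurable
— "six layers" is stated, widths are not); β defaults to 1; Adam at
learning rate 1e−3; 100 epochs, batch 256 (reduced with a warning when the
table has fewer than two batches of rows), early stop after 10 epochs of
< 1e−5 improvement. One integer seed controls initialization, shuffling
and reparameterization sampling, so training is bit-reproducible. Embeddings
are always extracted in inference mode — batch normalization uses running
statistics and the VAE emits posterior *means*, never samples — so
`encode()` is deterministic. The implementation is plain base-R matrix
arithmetic; its backpropagation (including batch normalization) is verified
against numerical gradients to ~1e−9 in development and against behavioral
contracts in the test suite.

## Clustering and model selection

* **K-means**: Lloyd iterations from k-means++ seeding, best of
  `n_init = 10` restarts by inertia, stopping at centroid shift < 1e−4 or
  300 iterations. A cluster that empties mid-iteration is re-seeded at the
  point farthest from its centroid. Inertia is recorded per iteration (it
  is provably non-increasing, and tested).
* **BIRCH**: points are inserted in input order into a CF tree (entries
  store count, linear sum, squared sum); a point is absorbed by the closest
  leaf entry when the merged radius stays within `threshold` (default 0.5),
  nodes exceeding `branching_factor` (default 50) split on their farthest
  entry pair. Leaf-entry centroids, weighted by entry size, are clustered
  into `k` by Lloyd iterations from a deterministic farthest-first seeding,
  and points inherit their entry's cluster. If the tree summarizes to fewer
  than `k` entries (e.g. a threshold above the data diameter), the global
  step falls back to the raw points so `k` clusters are still returned.
  The whole procedure is deterministic given input order.
* **Cluster count**: `scan_k()` clusters at every candidate `k` (default
  grid 5–200 in steps of 5) and records the mean Silhouette, computed on a
  seeded subsample of up to 10,000 points because the exact calculation is
  O(m²) per grid point. Scores are cached to CSV (written at full
  precision, so resumed scans are bit-identical). `select_k()` picks the
  *plateau onset*: the smallest grid `k` whose score stays within ε = 0.01
  over the next 2 grid points; when no plateau exists it falls back to the
  argmax, and the rule actually used is reported. Cluster labels follow the
  `0 … k−1` convention throughout.

## Validation indices

Three internal indices are implemented from their definitions and verified
against independent brute-force implementations (double/triple loops over
explicit distances and outer products) on a thousand random instances:

* Silhouette $s = (b-a)/\max(a,b)$ averaged over points, with $a$ the mean
  intra-cluster distance and $b$ the mean distance to the nearest other
  cluster; singleton clusters contribute 0 so the mean stays defined.
* Calinski–Harabasz $\mathrm{tr}(B_k)/\mathrm{tr}(W_k) \cdot (n-k)/(k-1)$,
  with the dispersion matrices taken about the global centroid and cluster
  centroids respectively; zero within-cluster dispersion yields an
  infinite-score sentinel with a warning.
* Davies–Bouldin $\frac1k\sum_u \max_{v\ne u} (s_u+s_v)/d_{uv}$, where the
  cluster "diameter" $s_w$ is the mean point-to-centroid distance (the
  standard reading of the loose term) and $d_{uv}$ the centroid distance;
  coincident centroids are an error naming the clusters.

All three are invariant to relabeling and rigid translation (tested). One
numerical detail matters: the vectorized expanded form
$\lVert x\rVert^2+\lVert y\rVert^2-2x^\top y$ leaves ~1e−8 of cancellation
noise on self-distances, which is enough to break a 1e−9 oracle-agreement
bound on mean Silhouette; the implementation therefore centers the data
(a no-op for the index) and pins self-distances to exactly zero, after
which agreement is at machine precision. Final reported evaluations always
use the exact indices; subsampling exists only inside the scan.

## Similarity analysis

Extended-connectivity fingerprints are computed by iterative neighborhood
hashing: each atom starts from an invariant over (atomic number, degree,
hydrogen count, charge, ring membership, aromaticity); each round re-hashes
it with the sorted (bond type, neighbor invariant) pairs; every
(atom, radius) environment contributes one bit after folding to `n_bits`
(default 2048). All environments are kept (no duplicate-environment
pruning), and the atoms each environment spans are retained. Folded
fingerprint bit values are implementation-specific — similarities should
only be compared within one toolkit — so cross-toolkit similarity values
are treated as qualitative.

Tanimoto similarity is $|A\cap B|/|A\cup B|$ for binary fingerprints and
$\sum_i \min(a_i,b_i)/\sum_i \max(a_i,b_i)$ for counts (the standard count
generalization; two empty fingerprints compare as 0 with a warning).
Similarity maps assign each test-molecule atom the weight
$\mathrm{sim}(\text{ref},\text{test}) -
\mathrm{sim}(\text{ref},\text{test} \setminus \text{bits}(a))$, removing
every bit whose environment contains the atom; weights are normalized by
their maximum absolute value for rendering. Defaults follow the two use
cases: maps use counted fingerprints (radius 2, 2048 bits), similarity
matrices binary ones (radius 1, 2048 bits).

t-SNE for the cluster scatter is the exact O(n²) algorithm (perplexity
calibration by bisection, early exaggeration, momentum, adaptive gains),
seeded and deterministic; it is intended for the few-thousand-point
visualization sizes the pipeline feeds it (`tsne_max`, default 2000).

## Synthetic data: what it emulates and what it does not

`fixture_smiles()` assembles valid drug-like SMILES from a fragment
grammar — substituted aromatic and aliphatic ring cores, alkyl chains,
carboxylates, sulfonamides, amides, nitro groups, aryl halides, nitriles,
chiral and cis/trans motifs — plus three mandatory degenerate cases: a
single heavy atom (`O`), a 2-atom/1-bond molecule (`CO`), and the
3-atom/2-bond minimum (`CCO`) that real libraries bottom out at. Grammar
composition guarantees validity without rejection sampling. The generator
covers the featurizer's edge cases; it does *not* emulate the chemical
distribution of any real screening library, so passing tests demonstrate
correctness of the machinery, not chemistry-specific cluster structure.

`gaussian_mixture()` plants `k` isotropic unit-SD Gaussian blobs for
recovery tests. Centroid directions are drawn isotropically at random and
rescaled so the *minimum* pairwise centroid distance equals `separation`:
the stated spacing is attained by the closest pair while most pairs are
farther apart, as in a randomly planted mixture. (The alternative — every
pair exactly at the minimum — is a worst-case simplex in which even the
Bayes-optimal assignment misclassifies a few per cent of points at
moderate separations, which says nothing about the clustering algorithm
under test.) Sampling separation-5 blobs in 32 dimensions, k-means
recovers the planted partition at ARI ≈ 0.97–0.99.

## Problem sizes and limitations

The shipped tests and the acceptance script run at deliberately modest
sizes — a few hundred fixture molecules, mixtures of up to 3,000 points,
autoencoders on 500 × 40 tables — chosen so the whole suite completes in a
few minutes on one CPU while still exercising every contract; all sizes
scale up through configuration. Known limitations: the SMILES parser
targets standard organic-chemistry SMILES (isotope labels are parsed but
do not alter the mass feature; CIP E/Z assignment is not performed); the
descriptor suite is smaller than a full cheminformatics descriptor
collection (`D_g` ≈ 45 by default, recorded in metadata); radicals are not
modelled (the radical-electron descriptor is 0 under the valence model,
and typically drops out in the zero-variance filter); BIRCH quality
depends on `threshold` relative to data scale, as in any CF-tree
implementation; and exact t-SNE is quadratic in the number of points.
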