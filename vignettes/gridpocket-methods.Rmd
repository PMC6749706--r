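---
title: "Multi-channel voxel descriptors and 3D convolutional pocket prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-channel voxel descriptors and 3D convolutional pocket prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpocket)
```

## The model

A protein binding site is shaped by two complementary factors: the geometry
of the surface (ligands bind in enclosed cavities, not on flat faces) and
the non-bonded interactions a ligand can form there (van der Waals contacts,
hydrogen bonds, electrostatics). `gridpocket` encodes both on a common voxel
lattice so that a convolutional network can learn their joint signature.

The lattice uses cubic 1 Å voxels. The grid covers the protein bounding box
plus an 8 Å buffer on every side; with a 1 Å spacing the number of voxels per
axis is `ceil(extent) + 16`. The center of voxel `(i, j, k)` (1-based) is
`origin + (i - 1/2, j - 1/2, k - 1/2)`. The buffer serves two purposes: the
energy cutoff sphere (8 Å) of any probe position near the surface stays
inside the lattice, and sample blocks centered on surface sites never reach
outside the grid.

### Channel 1: protein–solvent–protein shape scan

A voxel is *protein* when its center lies within the van der Waals radius of
at least one atom, otherwise *solvent*. The occupancy mask is scanned along
seven directions — the axes x, y, z and the four cube diagonals (1,1,1),
(1,1,−1), (1,−1,1), (−1,1,1), chosen pairwise non-antiparallel — stepping one
voxel at a time (diagonal steps advance one voxel on every axis). On each
scan line, every maximal solvent run bounded by protein voxels at *both*
ends is a protein–solvent–protein (PSP) event and adds one to each voxel of
the run. A voxel value is therefore the number of directions (0–7) in which
it is enclosed; deep cavities approach 7, open surface approaches 0. Two
boundary conventions are deliberate: a run touching the grid boundary is
open to bulk solvent and never counts, and protein voxels themselves stay at
0 (only solvent voxels can be part of a run). Both conventions are exercised
by the tests, and the compiled line-walking scan is checked against an
independent run-length oracle on random masks.

### Channels 2–4: probe energies

A probe is placed at every voxel center and its interaction with the protein
is accumulated with an 8 Å pair cutoff (pairs farther apart are ignored; no
switching function is applied, matching the abrupt-cutoff definition of the
descriptor).

* **van der Waals** — a united-atom methyl probe (AutoDock type C). Pair
  energy `A/r¹² − B/r⁶` with `A = ε r₀¹²`, `B = 2 ε r₀⁶`; per-pair parameters
  come from the Amber/AutoDock combination rules `ε = √(εᵢ εⱼ)`,
  `r₀ = rᵢ + rⱼ` over the per-type table shipped with the package (AutoDock4
  values). The voxel value is the sum over protein atoms in range. A
  united-atom probe was chosen over an all-atom methyl because the latter
  would require an arbitrary orientation at every voxel; with a single
  carbon the sum is orientation-free and deterministic.
* **hydrogen bond** — a hydroxyl probe: an acceptor oxygen (OA) at the voxel
  center and a donor hydrogen (HD) 0.96 Å away along +x. The orientation of
  the O–H bond is not determined by the descriptor definition; a fixed
  orientation keeps the channel deterministic and is configurable through
  `hydroxyl_probe()`. Pair energy follows the 12-10 form `C/r¹² − D/r¹⁰`
  (`C = 5 ε r₀¹²`, `D = 6 ε r₀¹⁰`), evaluated only for donor/acceptor pairs;
  the acceptor type carries the well: 5 kcal/mol at 1.9 Å for O and N
  acceptors, 1 kcal/mol at 2.5 Å for S. Hydrogen bonds saturate — a probe
  cannot bond to five atoms at once — so the voxel keeps the single
  candidate with the largest absolute energy instead of the sum: with
  candidates {−3.2, +1.1} the value is −3.2. Voxels with no candidate pair
  in range are 0.
* **Coulomb** — a unit positive point charge. The voxel value is
  `Σ K q / r²` over charged protein atoms in range, with
  `K = 332.0636 kcal·Å/(mol·e²)` and partial charges taken from the PDBQT
  input. The inverse-*square* form is the descriptor's printed definition
  and is implemented as such; `energy_params(coulomb_exponent = 1)` switches
  to the physical 1/r energy for users who prefer it. Distances are clamped
  at 10⁻⁶ Å so a voxel center coinciding exactly with an atom stays finite;
  the enormous clash energies this produces are tamed by the arctangent
  normalization below.

Energy probes are evaluated at every voxel, including protein-interior ones.
Interior values are large and positive, which is itself informative (the
network sees "impossible" regions), and bounded after normalization.

### Normalization

The four channels live on wildly different scales (counts 0–7 versus
energies spanning many orders of magnitude), so every voxel value is mapped
through `v ↦ (2/π)·arctan(v)` into the open interval (−1, 1); 0 maps to 0
and 1 maps to exactly 0.5. In double precision the arctangent of clash-level
energies (≳10¹⁶) rounds to the closed boundary, so normalized values are
nudged to the nearest representable double inside the open interval.
Normalization is applied to the whole grid before any block is cut, so
overlapping blocks always agree on shared voxels, and normalizing twice is
an error.

## Training data: block sampling

The classifier's unit is a 16³ voxel block. For a protein with an annotated
site the site center is snapped to the block-center lattice and the blocks
at per-axis offsets {−2, −1, 0, +1} Å become the 64 positive samples — the
half-open [−2, 2) reading is the unique one that yields 4 offsets per axis
and the documented 64 = 4³ count, and the union of those blocks is a 20 Å
(16 + 2 + 2) cube around the site. Negative samples come from scanning the
grid with 16³ blocks at a 4 Å stride: blocks whose centers fall *outside*
that 20 Å envelope of every site are candidates, down-sampled without
replacement to 64 under a recorded seed, for 128 blocks per protein.

Blocks centered inside the envelope but not among the 64 positives are
neither positive nor negative: they overlap the site too much to be clean
negatives. Labelling them negative would teach the network a razor-thin
boundary between a block centered 1 Å from the site and one centered 3 Å
away — and would make the prediction stage unsatisfiable, because a stride-4
scan can align at most one block per site with the positive lattice while
the clustering stage (below) requires at least seven passing blocks.

## The network

The classifier is a fixed 14-layer stack: Conv3D(2, 8³) → Conv3D(4, 8³) →
MaxPool(2³) → Dropout 0.25 → Conv3D(8, 4³) → Conv3D(16, 4³) → MaxPool(2³) →
Conv3D(32, 2³) → Conv3D(64, 2³) → Dropout 0.25 → Flatten → Dense(128, ReLU)
→ Dropout 0.5 → Dense(1, sigmoid). All convolutions are same-padded ReLU
layers, so the spatial trace is 16 → 16 → 8 → 8 → 4 → 4 and the flattened
feature length is 64·4³ = 4096; the first convolution holds
(8³·4 + 1)·2 = 4098 parameters. The published layer table is internally
inconsistent around the flatten stage (its dropout row lists a 32-channel
input after a 64-filter layer); the resolution here is the only
shape-consistent one — dropout acts on 64×4³ and the dense layer receives
4096 features, matching the table's own printed dense input.

No deep-learning framework is involved: the forward and backward passes are
implemented directly (single-precision im2col + GEMM convolutions in
compiled code), trained with Adam (learning rate 10⁻³, batch 32) on binary
cross-entropy. Loss, optimizer and schedule are not part of the descriptor
definition; they are package choices exposed through `network_config()`.
Training draws shuffling and dropout from R's RNG, so a seed makes runs
bit-reproducible. When a validation set is supplied, training stops after
`patience` epochs without validation-loss improvement and restores the best
weights; by default it also stops once training accuracy reaches 1, since
further epochs only sharpen overconfidence. Weight updates use
single-precision arithmetic — ample for a classifier whose inputs live in
(−1, 1) — while all descriptor math is double-precision.

## Prediction

A new protein's normalized descriptor is scanned with 16³ blocks at a 4 Å
stride and every block is scored. Blocks with probability ≥ 0.5 are
clustered with DBSCAN on their centers with Eps = stride + 1 = 5 Å and
MinPts = 7. The Eps choice makes face-adjacent lattice blocks (4 Å apart)
neighbors while diagonal neighbors (4√2 ≈ 5.66 Å) are not; MinPts = 7 is
exactly a face-adjacent neighborhood (six neighbors plus the point itself),
so a reported pocket requires a solid clump of passing blocks, never a
stray singleton or thin chain. Neighborhood counts include the point itself
(the scikit-learn convention); under the alternative (exclusive) convention
MinPts = 7 would reject even a perfect face-adjacent clump, so the inclusive
convention is the only one consistent with the published parameter choice.
Noise blocks are dropped rather than merged into the nearest cluster. Each
cluster becomes one pocket: center = unweighted mean of member block
centers, score = mean member probability. Pockets are ranked by score, with
deterministic tie-breaks (cluster size, then lexicographic center order).

Evaluation uses the center-to-center offset between a predicted pocket and
the actual site center, defined as the unweighted geometric mean of the
ligand atom positions. Top-N evaluation takes the best offset among the N
highest-scoring pockets (so it is non-increasing in N); the looser hit
criterion accepts a pocket center within 4 Å of *any* ligand atom. Proteins
with no predicted pocket are reported separately in summaries rather than
silently dropped or scored as infinite offsets.

## The synthetic generator

`make_hollow_shell()` builds protein-like structures with a known answer: a
cavity of radius 5–6 Å (a pocket diameter of 10–12 Å, the scale of a
drug-binding site, and the scale the MinPts = 7 / stride 4 clustering
geometry presumes) enclosed by concentric atom layers 1.7 Å apart at one
atom per ~2.56 Å², which keeps the occupancy shell contiguous and at least
two voxels thick — so cavity voxels are PSP-enclosed in all seven
directions. Atom types are drawn from a C/N/OA/SA/HD mix; charges follow a
zero, alternating, or seeded-random scheme. One to three solid surface
blobs are attached outside the shell so the bounding box (and hence the
grid origin) is not symmetric around the cavity. Everything is a pure
function of the `fixture_spec`, and `corpus_specs(n, seed)` derives varied
per-protein specs deterministically.

What the fixtures emulate: enclosed cavities of realistic size, mixed atom
chemistry, partial charges, bounding-box asymmetry, and enough grid extent
that the stride-4 scan has well over 64 negative candidates. What they do
not emulate: real secondary structure, side-chain packing, surface
roughness, shallow or elongated grooves, multi-site proteins, and crystal
artifacts. Passing the end-to-end recovery test therefore demonstrates that
the descriptor, sampling, network, clustering and evaluation stages compose
correctly — not that the shipped defaults reach any particular accuracy on
experimental structures, which requires training on a curated database.

## Problem sizes and numerical choices

The test suite runs entirely on synthetic data at desk scale: the
end-to-end check trains on a 30-fixture corpus (3,840 blocks, an 80/20
protein-level split) for up to 6 epochs and evaluates Top-1 recovery of the
planted center within 4 Å on 10 freshly generated held-out fixtures; oracle
comparisons use ≤ 50-atom proteins on ≤ 18³ grids at 10⁻⁹ relative
tolerance, and the PSP scan is compared against its oracle on one hundred
random 12³ masks. Tie-breaks, boundary conventions, and degenerate inputs
(empty ligands, all-zero charges, sites clipped by the grid edge, grids
with a single candidate block) all have pinned behavior: errors where the
input is unusable, warnings plus best effort where a sensible partial
answer exists.

Known limitations: PDB input carries no charges, so the Coulomb channel is
zero unless a PDBQT is supplied; the hydroxyl probe orientation is fixed
rather than optimized per voxel; DBSCAN is quadratic in the number of
passing blocks (irrelevant at pocket scale); and the shipped force-field
table covers the common AutoDock types only — unknown types fail loudly
rather than guessing.
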