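---
title: "Force-field-inspired graph attention: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-field-inspired graph attention: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Classical force fields approximate a molecule's potential energy as a sum of
four interaction families:

$$E = E_\mathrm{bond} + E_\mathrm{angle} + E_\mathrm{torsion} +
E_\mathrm{nonbonded},$$

with a harmonic bond-stretch term in the distance $r$, a harmonic angle-bend
term in the valence angle $\theta$, a three-fold cosine series in the
dihedral $\phi$, and a Coulomb + Lennard-Jones nonbonded term in inverse
powers of $r$. These four families map exactly onto graph neighbourhoods of
the bonded molecular graph: a bonded neighbour (1 hop) interacts through
bond stretching, the end of a three-atom chain (2 hops) through angle
bending plus a nonbonded pair term, and the end of a four-atom chain (3
hops) through torsion plus a nonbonded pair term. FFiNet turns this
decomposition into an attention-based message-passing network: each atom
aggregates messages from its 1-, 2-, and 3-hop neighbours, and the
attention score of each path is computed from the *functional form* of the
matching force-field term, evaluated on the path's internal coordinates.

No force-field *parameters* ($K_r$, $r_{eq}$, partial charges, LJ radii,
...) are used anywhere: the force field contributes only the embedding
basis

| hops | interaction | basis $m_k$ |
|------|-------------|-------------|
| 1 | bond stretch | $\{r,\ r^2\}$ |
| 2 | angle + nonbonded | $\{\theta,\ \theta^2\} \oplus \{r^{-1}, r^{-12}, r^{-6}\}$ |
| 3 | torsion + nonbonded | $\{\cos\phi, \cos 2\phi, \cos 3\phi, \sin\phi, \sin 2\phi, \sin 3\phi\} \oplus \{r^{-1}, r^{-12}, r^{-6}\}$ |

where the nonbonded part always uses the end-pair distance of the path.
Distances are in Angstrom, angles and dihedrals in radians; dihedrals are
signed (right-handed atan2 convention), which makes the $\sin$ columns
chirality-sensitive: a mirror image flips their sign while every other
basis column is unchanged. All bases are invariant under proper rigid
motions because they depend only on internal coordinates, which is what
makes the network's predictions rotation- and translation-invariant by
construction rather than by augmentation.

### The attention score

For a directed path $p$ of hop $k$ with target atom $i$ and source atom
$j$, the unnormalized score is

$$e^k_{ij} = a_k^\top\,\mathrm{LeakyReLU}\!\Big(\big(\textstyle\sum_{r\in p}
W_r h'_r\big) \odot \big(W_k\, m_k[p]\big)\Big),$$

a GATv2-style dynamic attention with the spatial basis entering
multiplicatively. A softmax over all hop-$k$ paths sharing target $i$
yields weights $\alpha$, and the hop output is the $\alpha$-weighted sum
of projected source embeddings. Three design points deserve an explicit
statement because the formula leaves them open:

* **Path sum.** The sum $\sum_{r \in p} W_r h'_r$ runs over *every* atom
  along the path — target, intermediates, source — with $W_r$ indexed by
  the atom's position in the path and shared across paths. The geometry of
  an angle or dihedral is a property of the whole chain, so the score
  should be allowed to depend on the whole chain.
* **Positional encoding.** $h'_r$ is the node embedding multiplied
  elementwise by the transformer sinusoid evaluated at position $k$ (the
  hop distance), so the score function can distinguish which hop channel
  it is serving. The encoding is parameter-free and deterministic.
* **Heads.** The score is computed per head on `hidden_dim / n_heads`
  column slices with head-specific $a_k, W_k, W_r$; head outputs are
  concatenated and linearly mixed. The mixing matrix carries no bias so
  that an atom with no hop-$k$ paths has an exactly-zero hop-$k$ output —
  this makes both the empty-hop masking and the no-axial ablation identity
  exact rather than approximate.

### Axial attention, layer, readout

Per node, the three hop outputs are arbitrated by *axial attention*: the
score of hop $k$ is the dot product of the node's input embedding with its
hop-$k$ output, scaled by $1/\sqrt{d}$ (the conventional dot-product
temperature; the choice is ours, the source formulation is silent), and a
softmax over the hops available to that node yields weights $\beta$. Hops
with no path to a node are masked out of its softmax, which avoids 0/0.
The layer finishes with dropout, a residual connection, and layer
normalization: $h' = \mathrm{LN}(h + \mathrm{Dropout}(\sum_k \beta_k
o_k))$. With `use_axial = FALSE` the weighted sum degenerates to a plain
sum — the no-axial ablation. Restricting `use_hops` yields the 1-hop and
2-hop ablations; with `use_hops = 1` the 2- and 3-hop parameter blocks do
not even exist.

Graph readout concatenates a gated weighted sum (gate
$g_i = \sigma(w^\top h_i + b)$, exposed as the atom-contribution signal
for interpretation) with per-dimension max pooling, followed by a
two-layer MLP. Regression heads emit raw values; classification heads
emit per-task logits with a masked binary cross-entropy loss, so
multitask datasets with missing labels train on exactly the observed
entries.

### Ring-induced hop overlap

In a ring, a bonded neighbour is also the endpoint of a 2-hop path. Hop
membership here is by *path length*, not shortest-path distance, and all
paths are kept: force fields apply the angle term to every bonded triple
and the torsion term to every bonded quadruple, rings included, and each
path carries distinct geometry. Multiple paths between the same atom pair
are likewise kept as separate attention keys — the softmax normalizes over
paths, not unique neighbours — and axial attention can down-weight
redundant channels. The alternative (shortest-path semantics) is
implemented behind `dedupe_hops = TRUE` so it stays testable.

## Protein–ligand complex graphs

A complex graph merges the bonded graphs of a pocket and a ligand and adds
*typed* nonbonded edges between every intermolecular atom pair closer than
5 Angstrom (strict inequality), the cutoff conventionally used as the
accuracy/cost trade-off for interaction graphs. Nonbonded edges enter the
1-hop edge list only, carrying the nonbonded basis
$\{r^{-1}, r^{-12}, r^{-6}\}$ through an edge-type-specific projection
$W_k^{nb}$ — this resolves the dimension mismatch with the bonded basis (3
vs 2 columns) without padding artifacts. 2- and 3-hop chains are built
over bonded edges only, because angle and torsion terms are defined along
bonded chains; deleting the nonbonded edges recovers the disjoint union of
the two input graphs exactly. Pocket pruning to a radius around the ligand
is available but off by default, since PDBBind-style layouts already ship
pocket files.

## Input pipeline

Molecules enter as SMILES (optionally with labels from a CSV) or as
SDF/PDB/mol2 structure files. SMILES are parsed and conformers generated
with the ETKDG distance-geometry method through an RDKit subprocess
bridge; the generator is seeded, so identical (SMILES, seed) pairs yield
bitwise-identical coordinates, and a failed embedding falls back once to
random-coordinate initialization before the record is dropped with a
logged reason — robustness over completeness, as appropriate for
large-scale screening. Only heavy atoms become nodes; hydrogens are folded
into the per-atom H-count feature (the MoleculeNet convention, which also
shrinks the k-hop index). Atom features are eight families at fixed width
38: atomic number, formal charge, chirality tag, H count, hybridization
(one-hot with an "other" bucket each), aromaticity, mass/100, and H-bond
donor/acceptor flags (flags, not counts — the coarser encoding, chosen
because finer granularity is not specified anywhere and flags are what
perception SMARTS provide robustly). The exact vocabularies are frozen in
a versioned constants block (`ffinet-features-1`) shared between the R and
bridge sides.

All indices in the R API are 1-based (the language convention).

## Numerical choices

* **Basis standardization.** The raw basis columns span orders of
  magnitude ($r^2 \sim$ tens, $r^{-12} \sim 10^{-4}$), which conditions
  training badly if left to the learnable projections alone. Each column
  is z-scored with statistics frozen from the training split and stored in
  the checkpoint. Whether the original formulation scales the basis is not
  stated; this is our choice and it is always applied.
* **Inverse-power clamp.** Distances feeding $r^{-1}, r^{-6}, r^{-12}$ are
  clamped below at 0.8 Angstrom — under any physical heavy-atom separation
  — so a distorted conformer cannot blow up the basis.
* **Collinear dihedrals** are undefined; they are returned as 0 with a
  warning rather than NaN, since embedded conformers essentially never
  produce them but distance-geometry edge cases can.
* **Softmax stabilisation.** Scores are clamped to $\pm 80$ before
  exponentiation. This cannot change a softmax materially (a 40-unit score
  gap already saturates the weight to within $10^{-17}$) but guarantees
  `exp` never overflows, and it keeps the vectorized grouped softmax free
  of per-group max bookkeeping.
* **Label standardization** (regression): labels are z-scored on the
  training split and the transform inverted at prediction time.
* **LayerNorm epsilon** $10^{-6}$; LeakyReLU slope 0.2 (the GATv2
  convention); Xavier-uniform initialization, deterministic per seed.

## Training

Adam with mini-batches of 128 molecules (batched as one disjoint graph, so
batching is exact, not approximate), early stopping on validation loss
with the best-epoch parameters restored, learning rate $10^{-3}$ with
$\times 0.5$ plateau decay, global gradient-norm clipping at 5, and random
8:1:1 train/validation/test splits with largest-remainder rounding. The
source work tunes its hyperparameters by Bayesian search and does not
print the selected values, so the defaults here (patience 30, decay
patience 10) are package choices and are stated in
`ffinet_train_config()`. Every source of randomness — initialization, data
order, dropout — derives from the training seed; identical calls give
identical histories. Repeated-run aggregation (mean and sd over three
seeds, the field's reporting convention) is provided by `run_repeats()`.

The default model is 3 layers, hidden width 64, 4 heads. Width 64 (rather
than a more typical 128) is a deliberate concession to this
implementation's pure-R training loop on a single CPU: it keeps the
end-to-end acceptance run inside its time budget, and on the synthetic
task the wider model adds nothing. All of it is configuration, not
constants.

Everything in the network — forward pass, reverse-mode gradients, Adam —
is implemented in base R matrix code, because no deep-learning runtime is
assumed to exist in the execution environment. The analytic gradients are
verified against central finite differences in the test suite, for the
plain, complex-mode, no-axial, and restricted-hop configurations.

## What the synthetic generator emulates — and what it does not

The generator samples from a frozen vocabulary of 221 drug-like SMILES
(alkanes through fused heteroaromatics, charged species, stereocentres,
and a few real drugs), embeds one ETKDG conformer per molecule, and
guarantees that any set of three or more molecules contains an acyclic
chain with 3-hop paths, a ring, and a polar molecule. The regression
target is a *pseudo-energy*: a fixed, documented function coupling all
four basis families (harmonic bond term around 1.5 Angstrom, harmonic
angle term around the tetrahedral 1.911 rad, a three-fold torsion term,
and an inverse-distance crowding term over 2-/3-hop end pairs) plus
Gaussian noise (default sd 0.05). The weights 1 / 0.5 / 0.3 / 0.1 give the
four terms comparable magnitudes on the vocabulary, so each hop channel
demonstrably carries signal. The end-pair sum runs over directed entries
(each unordered pair twice), the bond/angle/torsion sums over unique
tuples; the test suite pins this convention with a hand-computed propane
value.

Because the target is invariant to rigid motions and atom relabelling, a
correct implementation can learn it and an implementation that breaks
invariance cannot reach the acceptance threshold — that is the point of
the design. What a green synthetic run does **not** establish: performance
on real assay labels (noise here is Gaussian and homoscedastic; assay
noise is neither), scaffold generalization (splits are random), label
distributions of any real benchmark, or conformer-quality sensitivity
(one ETKDG conformer is the input, and the target is computed from that
same conformer — real labels are not functions of the conformer you
happen to embed). The synthetic complex fixture likewise tests graph
construction and learnability, not docking realism: poses are random
rigid placements constrained to 1–10 contacts, not energy-minimized
binding modes.

## Known limitations

* The RDKit bridge is a subprocess with JSON exchange; per-call overhead
  (~1 s of interpreter start-up) makes batched calls essential, and the
  package batches everything it can.
* Training is CPU-bound R; hundreds of molecules and width 64 train in
  about a minute or two, but the implementation is not intended for
  QM9-scale datasets.
* Hops are fixed at three — the receptive field the energy decomposition
  justifies; no deeper hops are implemented.
* No conformer ensembles, protonation-state enumeration, or charge
  assignment; single conformer per molecule.
* Hyperparameter search is reduced to a hook (`run_repeats` over
  configurations); full Bayesian search at publication scale is out of
  scope.
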