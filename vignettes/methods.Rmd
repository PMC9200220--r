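---
title: "Structure-free virtual screening with dfscreen: models, assumptions, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-free virtual screening with dfscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfscreen)
```

## The problem

Structure-based virtual screening (docking) scores a protein-ligand pair by
searching for a binding conformation, which costs seconds per pair and makes
libraries beyond a few hundred thousand compounds impractical without a
supercomputer. `dfscreen` implements the alternative strategy of
*structure-free* screening: both the binding pocket and each candidate ligand
are reduced to fixed-length descriptor vectors, and a small neural classifier
maps the concatenated pair directly to a binding probability in (0, 1). One
forward pass replaces a docking run, so tens of millions of compounds can be
ranked on a workstation; the top of the ranking is then handed to docking, MD
or experiment.

The package covers the complete workflow: featurization (pocket and ligand),
the classifier, a streaming screening engine with selection and
drug-likeness filtering, the enrichment statistics used to judge such
screens, structural clustering of hits, and synthetic-data generators that
give every stage inputs with known ground truth.

## Featurization

### Substructure sentences

A molecule is encoded as an ordered sequence of Morgan-environment
identifiers: for every heavy atom, in atom-index order, one identifier per
radius in ascending order (radii \{0, 1\} by default, the Mol2vec
convention). Radius-0 identifiers hash the atom invariants (element, heavy
degree, hydrogen count, charge, aromaticity); radius-$r$ identifiers fold in
the sorted (bond order, neighbor identifier) pairs of the previous round, so
identifiers are invariant under input atom reordering. Identifiers are
31-bit polynomial hashes; they are deterministic and stable, but they are
*not* numerically identical to any external toolkit's identifiers — all
downstream code treats them as opaque words.

Hydrogens are stripped before sentence generation (environments are computed
on heavy atoms), which is why the hydrogen count enters the radius-0
invariants instead.

### Embeddings

`train_embedding()` learns a word2vec-style table (skip-gram with negative
sampling) over a corpus of sentences; `embed_molecule()` sums the token
vectors of a sentence into one 300-dimensional vector (mean aggregation is
available behind a flag). Summation makes the representation additive: the
vector of a disconnected union of two molecules is the sum of their
vectors, a property the tests exploit as an oracle.

Unknown identifiers never fail lookup. Tokens rarer than `min_count` are
replaced by a dedicated `UNK` word before training, so the unknown vector is
itself trained whenever the corpus supports it; with `min_count = 1` (the
default) the unknown vector is zero. Screening libraries always contain
unseen substructures, so totality of lookup is a hard requirement, not a
convenience.

The trainer is single-threaded with a self-contained xorshift RNG: the same
corpus, dimension and seed give bit-identical tables on any machine. The
default window is 10 and the default epoch count 20 — substructure corpora
are tiny compared to text corpora, so several passes are needed before
co-occurrence structure appears in the cosine geometry.

### Pockets

The pocket is defined exactly as screening practice defines it: every
protein residue with at least one atom within 10 Å (1 nm) of any atom of a
reference bound ligand, kept as a whole residue. Selection is monotone in
the radius and symmetric in the distance computation. Waters and common
buffer components are excluded from the reference-ligand candidates;
alternate locations keep the highest-occupancy conformer (ties broken by
altloc letter); only the first model of a multi-model file is read.

How a pocket becomes featurizable input is the one genuinely unstated step
in this family of methods, so the package makes it explicit and
deterministic: `pocket_to_molecule()` builds a pseudo-molecule from the
pocket's heavy atoms with bonds inferred by the covalent-radius criterion
$d \le r_i + r_j + 0.45$ Å. The result is a possibly disconnected graph that
goes through the same sentence/embedding path as a ligand. Backbone atoms
are included; bond orders are uniformly single (the Morgan invariants still
separate chemical contexts through element, degree and neighborhood). A
residue-template fallback was considered and rejected: the distance
criterion is total, needs no name matching, and is deterministic on any
input that has coordinates.

## The classifier

### Architecture

The default network takes the 600-dimensional concatenation (pocket half
first) and stacks 10 *densely connected* blocks of 100 ReLU units: block $i$
consumes the concatenation of the normalized input and all previous block
outputs, so its input width is $600 + 100(i-1)$ and the sigmoid head sees
$600 + 10 \cdot 100 = 1600$ features. "All outputs of preceding layers" is
ambiguous about whether the raw input is included; the package includes it
(the DenseNet convention, and the interpretation consistent with a constant
100-unit growth per block), with `include_input = FALSE` available. The
parameter count is closed-form and asserted at build time.

Inputs are z-scored by a normalizer fitted on training features only
(population standard deviation, floored at $10^{-8}$ so constant features
map to zero rather than dividing by zero). Training minimizes binary
cross-entropy with Adam (learning rate $10^{-3}$, batch 128, 50 epochs by
default, He-uniform initialization, seeded shuffling). None of these
optimization constants are published for the original model; they are
package defaults, and reproducibility per seed is part of the contract.
Dropout defaults to 0 in the dense network — the published 0.25 rate is
attributed to the convolutional alternative — but is configurable.

### The convolutional alternative

`build_cnn()`/`fit_cnn()`/`score_cnn()` implement the described 1-D CNN:
two convolution blocks of two conv layers each, width-2 max-pooling and
dropout 0.25 per block, a 256-unit dense layer with dropout, a sigmoid
head, RMSprop on binary cross-entropy. Filter counts (16/32) and kernel
width (3) are not published; they are package choices. Dropout is active
only during training: scoring is deterministic and batch-size invariant for
both architectures.

## Screening and selection

`screen_library()` streams a `.smi` library in batches against a fixed
pocket vector; unparseable records are counted, not fatal. Results are
sorted by descending score with ties broken by compound id, so output is
byte-stable under input permutation. `screen_vectors()` is the
precomputed-vector route used when ligand vectors already exist (synthetic
worlds, cached featurizations).

Selection is either by score cutoff (score $\ge c$; the convention used with
$c = 0.99$ and $0.9$) or by top fraction (`ceiling(f * n)` rows — "top 10%"
is not defined to the row, and ceiling is the package's choice).
`recall_at_top()` reports the fraction of known actives inside the top
10–50%, non-decreasing in the fraction by construction. The Lipinski filter
uses inclusive bounds (MW $\le$ 500, logP $\le$ 5, HBD $\le$ 5, HBA
$\le$ 10); donors are counted as hydrogens on N/O and acceptors as N+O, the
classic rule-of-five convention. The built-in logP is a deliberately coarse
additive atom-contribution estimate — monotone in hydrophobic content, not a
calibrated Crippen model — which is sufficient for rule-of-five style
triage and for the synthetic library's planted violations.

## Enrichment statistics

For a screen with $N_{total}$ known actives among $N_{all}$ compounds, of
which $NN_{sel}$ score above a cutoff and $N_{sel}$ of those are active,
the prediction–random ratio is

$$\mathrm{Ratio} \;=\; \frac{N_{sel}/N_{total}}{NN_{sel}/N_{all}}
\;=\; \frac{N_{sel}/NN_{sel}}{N_{total}/N_{all}},$$

the true-positive rate among selected compounds relative to the rate a
random selection of the same size would achieve; equivalently the precision
of the selection over the library prevalence. Both algebraic forms are
computed and asserted equal. A ratio is undefined when nothing is selected
($NN_{sel} = 0$) and the package raises a typed error rather than returning
a silent zero; the same policy (an `NA` sentinel) applies to
zero-denominator precision and MCC, because silent zeros corrupt table
averages. Note the ratio is bounded above by $N_{all}/N_{total}$: at 20%
active prevalence no selection can be more than 5-fold enriched, which is
why meaningful enrichment benchmarks need DUD.E-like (~2%) prevalence.

Threshold metrics (accuracy, TPR, precision, MCC) default to the 0.5
operating point; published summary tables rarely state theirs, so the
threshold is configurable and the package's acceptance checks use only
reconstructions that do not depend on it: `reconstruct_counts()` inverts a
printed (TPR, precision, pos, neg) row to integer confusion counts and the
package recomputes MCC and accuracy from those.

Rank AUC is the Mann–Whitney form (ties counted half), invariant under
monotone score transforms, and is tested against an $O(n^2)$ pairwise
oracle.

## Hit clustering

High-scoring compounds are grouped with average-linkage agglomerative
clustering — the reciprocal-nearest-neighbor (Murtagh) family — on pairwise
Tanimoto distances between 2048-bit radius-2 circular fingerprints, with the
tree cut at $k = 6$ groups by default. Average linkage was chosen over
single/complete for stability on the blocky distance structure chemotype
families produce. The representative of each cluster is its medoid (minimum
summed intra-cluster distance, ties by id order); the published analyses do
not state their representative rule, so medoid is a package decision, not an
inferred fact. Exact distance ties between distinct molecules could in
principle make the merge order depend on input order; duplicates (distance
0) merge first regardless, and the permutation-invariance test uses tie-free
inputs.

## The synthetic world

`generate_world()` is a planted-signal model of binding: pockets and ligands
carry latent vectors in $\mathbb{R}^k$, a pair binds iff the dot product of
its latents reaches a threshold, and the observed 300-d vectors are a fixed
random linear map of the latents plus Gaussian noise. Defaults, chosen once:

* **k = 4** — a low-dimensional compatibility space, the simplest stand-in
  for the handful of pharmacophore-like factors that dominate a binding
  decision, and small enough that a few thousand pairs identify it;
* **noise_sd = 0.1** — roughly 10% observation noise relative to unit-scale
  latent signal, enough that memorization fails but recovery is expected;
* **prevalence = 0.2** — the threshold is auto-tuned so 20% of all
  pocket-ligand pairs bind, inside the generator's contract of [0.05, 0.5].

Training sets are built exactly as the field builds them: positives are
binding pairs, negatives are *cross-combinations* — a pocket paired with a
ligand that binds some other pocket — with every true-binding pair excluded,
at a 1:1 ratio by default (the published work does not state its ratio).

`generate_toy_complex()` writes minimal fixed-column PDB complexes in which
each residue's minimum heavy-atom distance to a planted 3-atom ligand is
*exactly* a prescribed value (an anchor atom is placed at the target
distance along a direction chosen so every other atom pair is provably
farther), so pocket-membership tests have zero geometric slack.
`generate_smiles_library()` assembles unique SMILES from a fragment grammar
whose size distribution is heavy-tailed, so a 200+ molecule library
contains violations of every individual Lipinski rule alongside clearly
drug-like members. `generate_labeled_library()` turns a world pocket into a
DUD.E-like evaluation set: its binders as actives, sampled non-binders as
decoys (50:1 by default), with the world's observed vectors attached so
ground-truth enrichment is known.

What the generators deliberately do **not** emulate: real chemotype
distributions, binding-affinity values, correlated assay noise, or any
relationship between a compound's grammar-generated SMILES and its world
vector (the SMILES serve identity, descriptor and clustering purposes). A
green signal-recovery test therefore establishes that the pipeline recovers
a recoverable planted signal — it does not certify performance on real
screening data.

## The signal-recovery benchmark

`signal_recovery_benchmark()` is the end-to-end check: world at default
signal settings (40 pockets, 6,000 ligands so the labeled library reaches
5,000 compounds), 2,000 training pairs, held-out pair AUC, then screening a
labeled library built around a pocket whose binder count is near 2% of the
library (the DUD.E-like regime in which enrichment is measurable; see the
prevalence bound above). Across three seeds the held-out AUC exceeds 0.9
and the 0.99-cutoff enrichment ratio exceeds 5, with recall@top-f%
non-decreasing — these are the stochastic acceptance checks, run verbatim
in `tests/testthat/test-acceptance.R`.

The benchmark trains for 40 epochs rather than the `fit_dfcnn()` default 50
purely to bound runtime on one CPU; this is a compute scale-down. It is
worth recording that a deeper cut (25 epochs) left one seed's model so
poorly calibrated that no library compound scored above 0.99 — the ratio at
that cutoff is then undefined. Sharp cutoffs like 0.99 measure calibration
as much as ranking: a model can rank almost perfectly (AUC 0.98) and still
place nothing above 0.99.

## Numerical and degenerate-input policy

* Scores are clamped to $[10^{-12}, 1 - 10^{-12}]$: the (0,1) contract
  survives saturated sigmoids.
* Constant features: normalizer std floored at $10^{-8}$, transformed to 0.
* Empty pocket: a warning and an empty structure, not an error (a radius
  can legitimately select nothing); unknown ligand ids and single-class
  training sets are errors.
* Zero-denominator metrics: `NA` sentinel; undefined ratios: typed error.
* Ties: screening rows by compound id; max-pool by earlier position;
  medoids by id order. All outputs are byte-stable across runs and input
  orderings.
* Persistence: weights serialize exactly (RDS) with a JSON sidecar carrying
  a format version; loading an unknown version is a typed error; a saved
  and reloaded model scores bit-identically.

## Known limitations

* The SMILES parser covers the organic subset, bracket atoms, charges,
  rings and branches; stereochemistry and isotopes are accepted and
  ignored. Substructure identifiers are internally consistent, not
  interchangeable with external toolkits' identifier values.
* logP is a coarse estimate; do not use it outside relative, rule-of-five
  style filtering.
* Pocket pseudo-molecules use single bonds only; aromatic and order
  perception on protein fragments is out of scope.
* The bundled benchmark tables are published summary statistics; the
  acceptance checks reproduce their internal arithmetic (means and
  count-level reconstructions), which verifies this package's statistics,
  not the original screening runs — those would require the original
  trained weights and the 10.4M-compound library, both out of scope.
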