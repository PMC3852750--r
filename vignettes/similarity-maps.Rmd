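---
title: "Similarity maps: how simmapr attributes similarity and predictions to atoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity maps: how simmapr attributes similarity and predictions to atoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fingerprint similarity is the workhorse of ligand-based virtual screening:
two molecules are encoded as sparse vectors of structural features and
compared with a simple metric such as Dice or Tanimoto. The number that
comes out is easy to compute and hard to interpret — and interpretability
vanishes entirely once fingerprints feed a classifier that outputs a bare
probability of activity. simmapr implements *similarity maps*, a direct
attribution scheme: for every heavy atom of a test molecule, remove the
fingerprint bits that atom participates in, recompute the score, and call
the difference the atom's weight,

$$ w_i \;=\; s_{\mathrm{orig}} - s_{\mathrm{mod}(i)}, $$

where $s$ is either the similarity to a reference compound or a model's
$P(\text{active})$ (for naive Bayes, $\ln P(\text{active})$, because its
evidence is multiplicative). A positive weight means the atom supports the
score; a negative weight means the score *rises* when the atom's features
are deleted. Weights are normalized by the maximum absolute value and
rendered as a sum of isotropic Gaussians centered on the atoms — green for
positive, pink for negative, gray for no change.

## Fingerprints and ownership

The attribution is only as meaningful as the mapping from atoms to bits,
which simmapr calls *ownership*. Three flavors ship:

* **Atom pairs (`ap`)** — a count vector over hashed (atom type, atom
  type, topological distance) descriptors for all heavy-atom pairs within
  `max_path_length` bonds (default 30). Each pair belongs to exactly its
  two atoms with multiplicity one, so masking an atom decrements every
  pair through it by one. The bit-space is $2^{32}$.
* **Circular, element-typed (`morgan`)** — ECFP-style environments of
  radius 0 up to 2 (default) around every atom. As a count vector the
  $2^{32}$ hash ids are kept; as a bit vector the ids are folded to 1024
  bits (`id mod 1024`). An environment belongs to its center *and* every
  atom within the radius.
* **Circular, feature-typed (`feat_morgan`)** — the same construction
  with atoms typed by six pharmacophoric classes (donor, acceptor,
  aromatic, halogen, basic, acidic) instead of element invariants. The
  class definitions live in an editable SMARTS file
  (`inst/extdata/feature_definitions.smarts`).

Hashing, SMILES/molblock parsing, aromaticity perception, 2D layout and
SMARTS matching are delegated to the RDKit toolkit through a bundled
Python helper (`inst/python/rdkit_backend.py`, JSON over a subprocess).
That choice is deliberate: fingerprint hash values are
implementation-defined, and published similarity tables are only
reachable with the ecosystem's standard implementation. Everything the
package is *about* — ownership bookkeeping, bit removal, weights,
normalization, metrics, the two classifiers and the renderer — is
implemented in R and verified against independent oracles in the test
suite (a brute-force masked-vector recomputation must agree exactly,
molecule by molecule and atom by atom).

### Bit collisions are preserved, not repaired

Folding to 1024 bits makes distinct environments collide. In the bundled
ligand panel, an environment of the amide moiety of the test molecule and
an environment of its alkyl linker hash to the same folded bit, so two
chemically unrelated atom groups co-own one bit. For *binary* vectors,
removing either atom clears the shared bit entirely; this is what the
removal semantics of a bit vector dictate, it is visible in the resulting
map (the amide appears more negative than the count-vector map suggests),
and simmapr reproduces it faithfully rather than splitting the bit. For
*count* vectors each atom only subtracts its own multiplicity. A
regression test pins the collision down.

### Empty fingerprints

The similarity of two empty fingerprints is defined as 0, not 1. Masking
the only atom of a one-atom molecule empties its fingerprint; treating
"nothing" as identical to anything would flip that atom's weight sign.

## Classifiers

Screening data are heavily imbalanced, so the random forest is
*balanced*: each of the `n_trees` (default 100) CART trees is trained on
a bootstrap of the minority class plus an equal-sized draw with
replacement from the majority class. The per-tree row indices are
recorded on the model object, making the balance property checkable
exactly. Trees are shallow (`max_depth = 2`, `min_samples_split = 2`,
`min_samples_leaf = 1` — the grid-search optimum reported for the
dopamine D3 data this method was demonstrated on) and are fit with
`rpart` at `cp = 0`; $P(\text{active})$ is the mean of per-tree leaf
class frequencies. Per-split feature subsampling is not used: with
class-balanced bootstraps and shallow trees, resampling alone provides
the ensemble variance, and determinism from a single master seed stays
trivial to reason about.

The naive Bayes classifier is the closed-form Bernoulli model with
additive Laplace smoothing ($\alpha = 1$ by default) and empirical class
priors:
$P(f\!=\!1 \mid c) = (n_{cf} + \alpha)/(n_c + 2\alpha)$. It exposes both
$P(\text{active})$ and $\ln P(\text{active})$; probability maps for NB
default to log mode. A zero probability in log mode raises an error
rather than clamping — switching to linear probability mode is the
documented escape hatch.

Model feature vectors are the folded binary 1024-bit circular
fingerprints by default (the standard choice); any folded feature space
is accepted and its descriptor is stored on the model, so a mismatched
fingerprint is rejected with both descriptors in the message.

## Rendering

The map is $f(x,y) = \sum_i w_i\, e^{-((x-x_i)^2+(y-y_i)^2)/2\sigma^2}$
on a square grid (default $250 \times 250$, 10% padding): the weight
scales only the peak, never the variance. Nothing in the construction
fixes $\sigma$, the grid or the contour count, so these are declared
package defaults: $\sigma = 0.3 \times$ the median bond length of the
depicted molecule (tying blob size to depiction scale), and 10 evenly
spaced contour levels. The color scale is always symmetric about zero —
limits are $\pm\max_i |w_i|$, never data min/max — so the neutral gray
marks exactly "no change" whatever the weight distribution. Images are
composed directly into a pixel raster and written with the `png` package
(SVG embeds the raster and draws vector bonds), so output bytes are a
pure function of the inputs; no graphics device is involved.

## The synthetic screen

`make_synthetic_screen()` builds labeled toy screens so that the whole
pipeline — including classifier training — runs offline and in seconds:
actives are random chains from a small token grammar with a planted
substructure (default a piperazine, the pharmacophore at the center of
the dopamine D3 worked example, where the protonated ring nitrogen forms
the conserved salt bridge to Asp110 of the receptor); decoys come from
the same grammar without nitrogen rings and are verified by substructure
matching to not contain the planted pattern. Label purity is therefore
exact. What the generator does **not** emulate: realistic scaffold
diversity, activity cliffs, assay noise, or the decoy-property matching
of curated benchmark sets. Tests that pass on these screens demonstrate
that the machinery extracts a planted signal, not that any model
generalizes to real screening data. Published probabilities that depend
on a particular (partly undisclosed, randomly subsampled) training
corpus are correspondingly out of reach and are replaced by property
checks: exact per-tree class balance, exact agreement of the naive Bayes
fit with the closed-form oracle, and a positive mean weight on planted
atoms across 20 seeded replicates.

The default study conditions used by the tests and the acceptance script
are screens of 5–6 actives against 30–40 decoys with `n_trees = 100`;
the weight-oracle suite runs 100 generated molecules across all three
fingerprint flavors. These sizes keep a full run within a few minutes on
one core while leaving every property comfortably measurable.

## Numerical choices and degenerate inputs

* Bit-ids are doubles (R has no 64-bit integers); all ids are below
  $2^{32} \ll 2^{53}$, so arithmetic is exact.
* `normalize_weights(all zeros)` returns all zeros (rendered as a
  uniform neutral field) instead of dividing by zero.
* Dice/Tanimoto numerators and denominators are integer sums, so equal
  inputs give bit-identical outputs regardless of summation order — the
  oracle tests assert *exact* equality, not tolerances.
* An atom owning no bits (e.g. a disconnected single atom under atom
  pairs) always gets weight exactly 0.
* 2D layout is deterministic for a fixed input; a molecule that already
  carries coordinates is never re-laid out.

## Known limitations

* Weights attribute *bits*, not causal substructure effects; a collided
  bit attributes jointly to unrelated atoms by design (see above).
* Only heavy atoms are weighted and drawn; hydrogens are implicit
  throughout.
* Atom-pair ownership removes one count per pair involving the masked
  atom — the pair survives at reduced count when only one endpoint is
  masked, which is the literal reading of the removal rule this package
  implements.
* The third test compound of the original worked example was distributed
  only in that study's supplementary archive; the bundled panel carries
  the reference compound and the first test molecule, and all published
  numbers recomputed here refer to those two.
* The renderer aims for faithful, deterministic topography, not
  publication aesthetics: bonds are plain lines without element labels
  or stereo wedges.
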