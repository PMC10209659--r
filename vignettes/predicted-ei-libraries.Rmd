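---
title: "Predicted EI libraries: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicted EI libraries: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphei)
```

This vignette is the package's account of its methods: what is modeled, what
is assumed, which knobs matter, and where genuinely open design choices were
resolved. The companion README shows the pipeline in action.

## The identification problem

Electron ionization produces fragment-rich, highly reproducible spectra, so
GC-MS identification is classically a library lookup: compare the measured
spectrum against measured spectra of standards. Measured libraries, however,
cover only a small fraction of known structures. The approach implemented
here replaces the measured reference with a *predicted* one: learn a map
from molecular structure to EI spectrum, precompute predictions for a large
structure collection, and search that predicted library. Because a predicted
library can be enormous, the search is done in two steps — restrict to
candidates with the query's molecular formula (known upstream from
soft-ionization accurate-mass work), then rank the restricted set by cosine
similarity. The formula filter typically shrinks the candidate set by four
orders of magnitude, which improves both speed and accuracy (a smaller,
chemically coherent candidate set leaves fewer ways to be wrong).

## Graph representation

A structure becomes a graph with one node per heavy atom and one edge per
bond; hydrogens never appear as nodes (their count is implicit in the
element and bond pattern, and EI fragmentation is dominated by the heavy
skeleton). Node features one-hot the element over
(C, O, N, B, F, P, S, Cl, Si, Br, I) — the elements seen in routine GC-MS.
Edge features carry the bond order (single, double, triple, aromatic) plus
an independent ring-membership flag; a bond is "in a ring" exactly when it
is not a cut edge of the graph, computed exactly via `igraph::bridges()`.

Decisions worth recording:

* **Atom order is input order.** Nodes are numbered by the record's atom
  order (SMILES writing order, SDF atom-block order) with no
  canonicalization. Determinism is per input string, not per molecule
  identity; all model outputs are invariant to the order anyway (verified by
  permutation tests).
* **Stereochemistry is discarded.** Geometric and optical isomers give
  near-identical EI spectra, so cis/trans and R/S annotations are stripped
  and isomer pairs collapse to one graph. Isotopic labels are also stripped:
  the spectrum representation is unit-m/z.
* **Aromaticity** follows the parser's (Open Babel's) default perception
  model; Kekulé-form input is aromatized before featurization. Parsing goes
  through the SYBYL MOL2 representation because it both preserves input
  atom order and keeps aromatic bond types explicit.
* **Formal charges and radicals** are not represented in the features (no
  feature column exists for them); their only effect is through the
  hydrogen count entering formula and molecular weight.

## Spectrum representation, similarity and loss

Spectra live on an integer m/z axis from 15 to 1010 — 996 bins. Peak lists
are binned by rounding half away from zero; out-of-range peaks are dropped
with a warning (not clamped: a clamped peak would fabricate intensity at an
unrelated mass). Internally every spectrum is normalized to base peak 1.0.
Cosine similarity is scale-invariant, so this normalization cannot change
any ranking; MSP export scales to base peak 999 per the NIST text
convention, written at full precision so round-trips are exact.

Training minimizes a weighted squared error
\(L = \sum_i w(m_i)\,(A_i - P_i)^2\) over all bins. The weight profile is a
small registry: `uniform` (default, \(w = 1\)) and `sqrt_mz`
(\(w = \sqrt{m_i}\), up-weighting high-mass fragments, which are few but
diagnostic). The registry makes the choice explicit and swappable rather
than baked in; the package takes no position that either profile is
"correct" for real EI data.

## The MPNN

The model is a message-passing neural network: node and edge features are
embedded (`tanh` layers), then `message_rounds` rounds of edge-conditioned
messages with a gated update propagate local structure:

\[
m_v = \sum_{u \sim v} \mathrm{relu}(W_m [h_u ; g_{uv}] + b_m), \qquad
z_v = \sigma(W_z [h_v ; m_v] + b_z),
\]
\[
h_v \leftarrow (1 - z_v) \odot h_v + z_v \odot \tanh(W_u m_v + b_u).
\]

Sum pooling over nodes feeds a two-layer perceptron that emits the
996-vector. Sum pooling plus symmetric messages make the output exactly
invariant to atom reindexing. Defaults (64-dim node states, 32-dim edge
embeddings, 3 rounds, 128 hidden units) are sized for desk-scale training
sets of tens to hundreds of molecules; every size is a `model_config()`
field.

Numerical choices:

* **Output nonnegativity via softplus.** Intensities must be nonnegative.
  A hard rectifier on the output layer satisfies the constraint but lets
  entire spectrum bins "die" (zero gradient) during the large early Adam
  steps — in practice whole predictions collapsed to zero at learning rates
  that otherwise converge. Softplus is the smooth rectifier: strictly
  positive, so the base peak is always defined, with the small floor driven
  toward zero by training.
* **Optimizer.** Adam, minibatch 16, default learning rate 3e-3. The rate
  was chosen so that a desk-scale run (tens of pairs, 300 epochs, one CPU)
  converges to memorization; large-corpus training would use smaller steps
  and is out of scope here.
* **Early stopping and weight selection.** After every epoch the loss is
  computed on the validation set; the returned weights are those of the
  epoch with minimum validation loss, and training stops `patience`
  (default 20) epochs after the last improvement. This mirrors standard
  validation-minimum selection for this model family, where validation loss
  plateaus after a few hundred epochs.
* **Determinism.** Pure-R arithmetic plus a single seed controlling
  initialization and minibatch order makes training bit-reproducible; the
  test suite asserts identical histories for identical seeds.
* **Gradients.** Backpropagation through the message rounds is hand-written
  and verified against central finite differences (relative agreement to
  1e-4 or better on every parameter block, including the edgeless
  single-atom graph).

## Library construction and search

Three exclusion rules are applied before prediction, in a fixed order with
the first match reported: (i) multi-component records (salts, mixtures —
detected as disconnected covalent components), (ii) average molecular
weight over 1000 Da (beyond GC-MS volatility range; average atomic weights
are the GC-MS convention for this bound), (iii) elements outside the
allowed set. Note the order matters for reporting: a salt written as
separate ions is excluded as multi-component even if it also contains a
disallowed metal, while the same salt written covalently is excluded for
its element.

The library indexes records by Hill-notation formula (C first, H second,
rest alphabetical); any formula spelling canonicalizes to that key, and the
indexed lookup is tested equal to a linear scan. Search ranks candidates by
cosine similarity, descending, with ties broken by ascending identifier;
when a designated correct record is scored, its reported rank is the
*worst* rank within its tie block — the conservative reading. Rank
percentiles are boundary-inclusive: rank exactly `ceiling(p * n)` counts as
within the top `p` (so rank 10 of 1000 candidates is within the top 1%),
and "top" means rank 1 exactly. No cap is imposed on candidate-set size.
Persistence uses standard R serialization (`saveRDS`) plus MSP export.

## The fixture generator

Real training data — measured spectra paired with structures — is
proprietary at scale. The fixture module exists so the full loop is
testable and trainable without it:

* `generate_molecules()` enumerates a scaffold/substituent grammar (alkyl
  chains up to C8; benzene, substituted benzenes, pyridine, furan,
  thiophene, cyclopentane/cyclohexane, naphthalene; terminations including
  alcohol, amine, halogens, nitrile, ester, amide, acid) and samples it
  with a seed. On request it appends one specimen per exclusion rule for
  filter tests.
* `pseudo_fragment_spectrum()` assigns each molecule a deterministic
  spectrum: a molecular-ion peak (intensity 0.6) at the rounded molecular
  weight, plus one peak per fragment from cleaving each acyclic bond, with
  intensity `0.85^(heavy atoms in fragment)` — larger fragments are rarer,
  loosely echoing how extensive fragmentation depletes large ions. Fragment
  masses use average atomic weights with hydrogens assigned by a standard
  valence rule. Optional Gaussian intensity noise (truncated at zero)
  emulates measurement variability; `noise_sd = 0.05` leaves noisy copies
  at cosine ≈ 0.9–0.99 to their clean versions, a plausible
  replicate-to-replicate range.
* `fixture_pairs()` additionally rejects molecules whose noiseless spectrum
  duplicates an earlier one. Identifiability tests (self-search must return
  rank 1 for every query) are meaningless if two records carry identical
  spectra — under the conservative worst-rank tie rule they would *both*
  fail — so spectrum uniqueness is part of the generator's contract.

What the fixtures do **not** emulate: real fragmentation chemistry
(rearrangements, ring cleavages, isotope patterns), realistic formula-bucket
sizes (PubChem formulas can have thousands of isomers; fixture buckets are
small), and the long-tailed structural diversity of real corpora. Passing
tests therefore demonstrate that the machinery — featurization, learning,
indexing, ranking, bookkeeping — is correct and end-to-end trainable, not
that the model reaches any particular accuracy on measured spectra.

## Problem sizes

The shipped tests and the acceptance script run deliberately small studies:
20-pair memorization (300-epoch budget, mean training cosine ≥ 0.99),
100-pair trainability with a 10/10 validation/test split, a 200-record
library for self-search and noisy-query rank evaluation, and a 1000-record
single-formula bucket for the percentile rule. These sizes exercise every
code path in minutes on one CPU while keeping the statistical checks
meaningful; all of them scale up by changing a config argument.

## Known limitations

* Aromaticity and protonation follow Open Babel's models; other toolkits
  may perceive borderline systems differently, changing edge features.
* The loss's exact weighting for real EI data is an open modeling question;
  both provided profiles are defensible, neither is validated against
  measured spectra here.
* The MPNN is intentionally compact. Matching measured-library accuracy at
  corpus scale would require larger embeddings, longer training, and real
  data — none of which changes the interfaces exercised here.
* Tautomers and stereoisomer entries of the same skeleton collapse to one
  graph but are kept as separate library records if supplied separately (no
  deduplication across input identifiers).
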