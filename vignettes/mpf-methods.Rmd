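---
title: "Message-passing featurization and charge regression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Message-passing featurization and charge regression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpfcharge)
```

## The problem

Atomic partial charges are per-atom scalars (in units of the elementary
charge e) that summarize how a molecule's electron density is shared among
its atoms. They are widely used in drug discovery and molecular modelling,
but the reference methods that define them (DFT population analyses such as
Mulliken, Hirshfeld, CM5, DDEC6, or semiempirical schemes) are far too slow
for screening large libraries, and most learned surrogates either need
optimized 3D coordinates or are locked to the molecule sizes seen in
training.

`mpfcharge` implements a coordinate-free alternative: a parameter-free
*message-passing featurizer* (MPF) turns the bond graph of a molecule into a
fixed-length five-feature descriptor per atom, and a small dense network
regresses the charge of one atom at a time from that descriptor. Because the
network only ever sees single atoms, a model trained on small molecules
predicts molecules of any size without retraining; featurization costs
O(n²) and prediction O(n) in the atom count n.

## The molecular graph

A molecule with n atoms (hydrogens always explicit) is represented by:

* the atom vector `chi`, with `chi[i]` the Pauling electronegativity of atom
  i — used purely as a numeric label of the atomic type, not as a physical
  quantity; its narrow numeric range keeps the descriptor easy to normalize;
* the topology matrix `T`, with `T[i, j]` a numeric code for the bond type
  between atoms i and j (0 if unbonded), symmetric with zero diagonal;
* the adjacency matrix `A = (T != 0)`, the plain connectivity.

Five bond types are supported — single, double, triple, amide, aromatic —
mapped by default to the distinct nonzero codes 1–5. The downstream
arithmetic only requires the codes to be distinct and nonzero; a trained
model records the map it was featurized with, and that stored map takes
precedence at prediction time. Input comes from TRIPOS mol2 records
(element taken from the SYBYL atom-type stem, coordinates ignored, the
charge column kept as optional labels) or from SMILES, which are converted
to mol2 by Open Babel *without generating coordinates* and with hydrogens
made explicit. Formal charges in a SMILES do not alter the graph.

## Message passing and the five features

Every atom starts at stage 0 with feature `H_i = 1`, so all atoms carry the
same weight and the updates build up the description of the neighbourhood
in an unbiased way. One update round computes, for every atom i,

* bond contribution: `H_bond,i = Σ_j T[i,j] · H_j`
* atom contribution: `H_atom,i = Σ_j A[i,j] · chi[j] · H_j`
* self contribution: `H_self,i = chi[i] · H_i`

and sets `H_i ← H_bond,i + H_atom,i + H_self,i`. After `cutoff` rounds
(default 3, balancing accuracy against data and preprocessing cost), the
value at atom i encodes exactly its bond-distance ≤ cutoff neighbourhood —
nothing outside that radius can reach it. The descriptor row for atom i is

```
F_i = [H_bond,i, H_atom,i, H_self,i, H_MNE,i, H_SEN,i]
```

where the first three are the contribution terms of the *final* round,
`H_MNE,i` is the mean Pauling electronegativity of i's bonded neighbours,
and `H_SEN,i = chi[i]`. Atoms with identical labelled neighbourhoods
(graph automorphisms) therefore receive identical rows, which is what lets
the network assign equal charges to equivalent atoms.

Each feature column is z-scored with the mean and standard deviation pooled
over every atom of the training set (computed after the updates). We use
the *population* standard deviation, so duplicating the training set leaves
the statistics unchanged. A column with zero spread is mapped to 0 and
flagged with a warning — a constant feature carries no information.

## The charge network

The regressor is a fixed feed-forward net: 5 inputs, five hidden layers of
50 tanh units, one linear output. It is trained with Adam (learning rate
0.001, β₁ = 0.9, β₂ = 0.999, ε = 1e-7) on the mean absolute error of
z-scored charges for 100 epochs at batch size 16 (768 is the conventional
choice for very large training sets). Weights are Glorot-uniform
initialized from a recorded seed; epoch shuffling uses a second recorded
seed, so training is bit-reproducible. There is no validation split or
early stopping: the final-epoch weights are kept. Predictions are
denormalized with `Q = Q̂·σ_Q + Q̄`, the exact affine inverse of the target
z-score; a degenerate training set with σ_Q = 0 therefore predicts the
constant Q̄. Prediction refuses elements absent from the training element
set rather than extrapolate.

Models persist as a single JSON file: a metadata header (cutoff, bond-code
map, element set, charge-type label, normalization statistics, training
configuration and seeds) plus the weight arrays written at 17 significant
digits, which round-trips IEEE doubles exactly — a reloaded model predicts
bit-identically.

## Numerical determinism

Two accumulation choices matter and were made deliberately:

* The featurizer accumulates each row's sum column-by-column in ascending
  neighbour index with a single accumulator per row, rather than calling a
  BLAS matrix–vector kernel. BLAS kernels split the sum across SIMD lanes,
  which makes the last bits depend on where the structural zeros sit; with
  ordered accumulation, two atoms whose labelled neighbourhoods agree out to
  the cutoff get *bitwise identical* feature rows, so cutoff locality and
  automorphism symmetry are exact rather than approximate.
* Prediction uses a row-independent forward pass (the sum over inputs is
  accumulated in ascending index per output element), so an atom's charge
  depends only on its own feature row. BLAS GEMM blocks rows and can round
  identical rows differently by one ulp. Training keeps the fast BLAS
  forward — only the prediction surface needs row independence.

Permutation equivariance — relabeling atoms and permuting the output —
holds to machine rounding (about one ulp on features of magnitude ~10⁴) but
cannot be bitwise: relabeling genuinely permutes the order in which the
same addends are summed.

Graphs store dense n×n matrices, adequate up to roughly 20,000 atoms; the
O(n²) featurization cost is inherent to that representation and matches the
intended scaling of the method.

## Synthetic data: what it does and does not show

The package trains and tests entirely from generated data. Random molecules
are valence-respecting trees (optionally one ring) over C/N/O heavy atoms
with explicit hydrogens filling the remaining valence; a draw that
saturates every free valence before placing all heavy atoms raises a
classed error and set builders skip that seed deterministically. Synthetic
labels are an exact smooth function of the molecule's own descriptor,

```
q_i = 0.2·d_i + 0.05·d_i² + 2e-5·H_bond,i,   d_i = H_MNE,i − H_SEN,i
```

plus optional Gaussian noise — a scale of a few tenths of e, comparable to
real partial charges. Because the noiseless labels are exactly learnable
from the descriptor, held-out error against them measures the pipeline
(featurization, normalization, optimization, denormalization), not
chemistry. Passing these tests says nothing about accuracy on DFT or
semiempirical charges for real molecules; that requires real labelled data,
for which the reader should train on their own mol2 files with charge
columns.

## Study sizes and the recovery protocol

The bundled recovery experiment trains on roughly 500, 2000 and 8000 atoms
(molecules drawn at 9 heavy atoms, label noise σ = 0.01 e) and evaluates
RMSE on a held-out pool of ~1000 atoms with the same noise level; the
scaling benchmark times alkane chains of 100–1600 carbons (302–4802 atoms),
averaging repeated runs, and fits log–log slopes. These sizes keep a full
run within a couple of minutes on one CPU while spanning a decade of
molecule sizes.

One caveat the experiment exposes honestly: with σ = 0.01 e the held-out
RMSE floor is 0.01 e, and by 2000 training atoms the model error is already
well under the floor. Because the optimizer runs at a constant learning
rate with MAE loss and keeps the final-epoch weights, the endpoint wanders;
replicate runs at 8000 atoms differ by more than the expected improvement
from 2000 to 8000. The RMSE-versus-training-size curve is therefore
monotone in expectation but not in every realization — the flat end of the
curve is a draw from the optimizer's stationary noise.

## Limitations

* Only connectivity is seen: bond lengths, angles, torsions, conformations
  and through-space effects are invisible, as intended for a coordinate-free
  method; systems where secondary structure dominates will not be described.
* Interactions beyond the cutoff radius (3 bonds by default) are ignored.
* Five bond types only; exotic bonds are rejected, not coerced.
* Isolated (degree-0) atoms are rejected: the mean neighbouring
  electronegativity is undefined for them, and the intended chemical space
  (organic, lead-like) has none.
* The TL80 indicators use the nearest-rank convention (the
  `ceiling(0.8·n)`-th smallest absolute or percentage error); percentage
  metrics exclude only atoms with |true charge| < 1e-8 e.
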