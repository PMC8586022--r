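---
title: "Predicting nanopore kmer ionic currents from chemical structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nanopore kmer ionic currents from chemical structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmergcn)
```

## The problem

During nanopore sequencing, each nucleotide kmer occupying the pore's
sensing region (k = 6 for DNA, k = 5 for RNA in the chemistries modelled
here) produces a characteristic ionic current, in picoamperes. Kmer models —
lookup tables from kmer to mean current — underpin most downstream analyses,
including the detection of chemical modifications such as 5-methylcytosine
(5mC). Treating each modified base as an unrelated character makes the
number of kmers to calibrate grow polynomially with the number of
modifications, and control data for every modified kmer are rarely
available.

`kmergcn` instead regresses the current level on the kmer's *chemical
structure*. A kmer is assembled into a molecular graph (atoms as nodes,
covalent bonds as edges), each atom carries an 8-dimensional chemical
feature vector, and a graph-convolutional network (GCN) with a convolutional
and dense head maps the graph to a single pA value. Because chemically
related kmers have overlapping substructures, the network can interpolate
missing kmers and even extrapolate to modified bases it has never seen,
provided their chemical groups occur elsewhere in the training alphabet
(the 5-methyl group of 5mC, for instance, is present in thymine).

## From kmer to graph

Each nucleotide is a SMILES building block (a 5'-phosphorylated
(deoxy)ribonucleoside written so that plain string concatenation chains the
phosphodiester backbone); a kmer's SMILES is the concatenation of its
blocks plus a terminal `"O"` for the residual 3' hydroxyl:

```{r}
assemble_smiles("C", "DNA")
g <- kmer_graph("CGACGT", "DNA")
g
which(g$element == "P") - 1  # 0-based phosphorus positions
```

The package parses the restricted SMILES grammar these blocks use (atoms
C/N/O/P, single/double bonds, branches, ring closures) with atoms indexed
in order of appearance. Eight features per atom form the matrix `X`:
element one-hots (C, N, O, P), degree (distinct bonded neighbours — a
double bond counts once, so degree equals the adjacency row sum), implicit
valence (standard valence minus the bond-order sum; hydrogens are implicit,
so this equals the hydrogen count), total hydrogens, and an aromaticity
flag.

Aromaticity is perceived on the kekulized structure with a
domain-restricted rule: a ring is aromatic when every ring atom either
takes part in a double bond or is a nitrogen contributing a lone pair.
On the twelve building blocks this reproduces standard perception exactly
(verified against an independent cheminformatics toolkit and frozen into
the test fixtures): purine and pyrimidine(-one) rings are aromatic, the
furanose sugar ring and all exocyclic atoms are not. Note one bookkeeping
difference from toolkits that aromatize bonds: for pyrrole-type ring N–H
atoms we report implicit valence 1 (the verbatim definition on the
kekulized structure), while e.g. RDKit books that hydrogen as explicit
after aromatization; hydrogen counts agree everywhere.

Graphs are zero-padded to a fixed size `P` so every kmer yields equally
shaped tensors `A` (`P x P` binary adjacency) and `X` (`P x 8`). `P` is
the maximum heavy-atom count over all kmers of the configured alphabets:
133 for DNA 6mers over the canonical/5mC/6mA alphabets and 116 for RNA
5mers over canonical-plus-6mA. One documented discrepancy: a 6-letter RNA
alphabet containing 2mG admits the all-2mG 5mer, which needs
5 × 24 + 1 = 121 atoms, although the published dimensions quote 116 for
RNA throughout; `padding_size()` always computes the true enumerated
maximum, so mixed experiments remain encodable.

## The network

The forward model is

* **GCN stack** — `H^(l+1) = ELU(Â H^(l) W^(l))` with `H^(0) = X` and
  `Â = D̃^(-1/2) (A + I) D̃^(-1/2)`: self-edges are added and the operator is
  symmetrically normalized by the augmented degree, which keeps feature
  scales stable. (The source description writes the exponent as +1/2; only
  the inverse square root normalizes scale, matching the cited graph
  convolution construction, so that is what is implemented.) Layer widths
  follow `n = 16·2^(l-1)` counted from the output: depth 4 gives
  128/64/32/16. After `L` layers each atom's vector summarizes its
  chemical neighbourhood to graph distance `L`. Padded atoms carry zero
  features and only a self-loop, so they stay exactly zero through the
  stack.
* **CNN stack** — 1-D valid convolutions (kernel `K`) with ReLU over the
  (length × channels) matrix, each followed by 2 × 2 average pooling with
  stride 1, which shrinks both length and channels by one. The first
  convolution's output length is `P − K + 1` (124 for DNA with K = 10);
  subsequent dimensions follow `{m − K + 1 − 2 + 1, n − 2 + 1}`. Channel
  counts follow the same width ladder as the GCN stack, wide to narrow.
* **Head** — row-wise flatten, a dense layer of `N` nodes, and a scalar
  linear output (the pA value). The dense layer is linear; the ReLU
  convolutions above it provide the nonlinearity.

Training uses minibatch Adam (canonical defaults, batch size 32) on the
mean-squared error, at most 500 epochs, 10% inverted dropout after every
layer at train time, and early stopping: a seeded 10% validation split is
held out of the training kmers, and training stops after 10 epochs without
validation improvement, restoring the best-validation weights (restoration
is this package's choice; it stabilizes short runs and never worsens the
monitored loss). Targets are standardized internally to zero mean and unit
variance on the training set and predictions are returned in pA — standard
practice for regression networks that materially accelerates early
optimization. All stochastic elements (initialization, validation split,
shuffling, dropout) derive from the single `train_config()` seed, so runs
are bit-reproducible on one thread; repeat-to-repeat variability in the
experiment battery comes from advancing that seed per repeat.

Everything — graph operators, convolution via im2col, pooling, backprop,
Adam — is implemented directly in R on BLAS-backed dense algebra with
sparse block-diagonal batch operators, and the gradients are verified
against numerical differentiation in the test suite's oracle checks.

The tuned architectures found by 10-fold cross-validated grid search over
the 500-combination space (`table_grid()`) are available as
`tuned_config()`: DNA (4 GCN, 3 CNN, K = 10, N = 8192), canonical RNA
(4, 5, 10, 8192) and modified RNA (6, 6, 10, 8192). Desk-scale work and
the test suite use `reduced_config()` (2 GCN, 2 CNN, K = 4, N = 128,
≤ 50 epochs), which trains in minutes on one CPU.

## Experiment designs

`run_experiment()` reproduces the generalization battery over a reference
kmer model: random **downsample** splits at 5% intervals (fresh random
split per repeat), **base dropout** (train on kmers free of a base, test on
all kmers containing it: 729/3367 for DNA), **position dropout** (test on
kmers with a base at a fixed position: 3072/1024), **combination** (train
on the union of two base dropouts, test on kmers containing both bases:
1394/2702 DNA, 454/570 RNA), and **imputation** (all canonical kmers plus
a fraction of modification-containing kmers). `denovo_prediction()` trains
on canonical kmers only and predicts the full modification-extended
alphabet. Goodness of fit is RMSE (pA) and Pearson's r per train/test
subset, long-format, one row per repeat.

## The synthetic reference

Published kmer models are network downloads, so the package ships a
generator whose defaults stand in for them in every test:
`mean(kmer) = intercept + Σ_pos effect(pos, base) + N(0, noise_sd)`, with
intercept 100 pA, per-(position, base) effects drawn once from N(0, 4 pA)
(giving the ~70–130 pA dynamic range of real models; the scale is
arbitrary and documented as such), and noise_sd 0.5 pA. The additive
structure mirrors the positional sensitivity seen in position-dropout
analyses and has a closed-form oracle: OLS on one-hot
(position, base) indicators recovers the effects exactly at zero noise
(`ols_oracle()`), and at 0.5 pA noise its held-out RMSE is the best
achievable additive fit. The recovery check trains `reduced_config()` on a
50% split of the 4096 synthetic DNA 6mers and requires held-out r ≥ 0.9
and RMSE within 3× the OLS oracle; a representative run reaches RMSE
≈ 0.7 pA (1.4× oracle) and r ≈ 0.996 in about fifty epochs.

What the generator does *not* emulate: neighbour-interaction effects,
heteroscedastic and non-Gaussian event noise, strand/orientation
asymmetries, and the systematically different current shifts of real
modified bases. Passing the synthetic battery therefore demonstrates that
the encoder, network, optimizer and experiment plumbing are correct and
that the architecture can recover a position-additive signal from
chemical structure alone; it does not certify accuracy on real ONT or
nanopolish tables, for which the external-data experiments are documented
in the README.

`make_modified_reference()` extends a synthetic spec with a modified base
whose kmers inherit the parent's effects plus a position-dependent offset —
the stand-in for a measured modification model in imputation and de novo
designs.

## Embedding analysis

`atom_embeddings()` extracts the final GCN layer's activation vectors
(post-ELU, dropout disabled) for the real atoms of a kmer;
`atom_similarity()` computes atom-by-atom Pearson correlations within or
across kmers (zero-variance atoms get a 0 sentinel rather than NaN, and
exact symmetry/unit diagonal are enforced). In trained canonical models,
phosphate, sugar and nucleobase modules emerge as correlated blocks, and
the thymine and 5mC methyl carbons (atoms #38 and #58 of GT(5mC)AGA)
embed similarly — the signature of methyl-group generalization.
`project_2d()` summarizes embeddings in two dimensions via PCA (default)
or classical MDS; both are deterministic, which we prefer for regression
tests over stochastic neighbour-embedding layouts, and the projection
method is configurable.

## Numerical choices and edge cases

* Kmers are symbol sequences; modified bases are bracketed multi-character
  tokens (`GT[5mC]AGA`), with the nanopolish `M` convention supported on
  input and output via a dialect flag.
* `random_split()` uses `floor(fraction × n)` training kmers (so 0.95 of
  1024 RNA 5mers gives 972).
* Enumeration order is lexicographic in the declared base order; all
  splits, fixtures and written tables are deterministic.
* `empirical_model_from_events()` keys on `model_kmer` (strand-corrected
  sequence), averages all instances (`min_count` default 1), accumulates
  running sums so chunked/streamed input equals batch averaging to 1e-9,
  skips and counts all-`N` placeholder rows, and applies no deduplication
  of consecutive events. Event-table coordinates are 0-based half-open.
* Degenerate inputs fail loudly: padding overflow, dimension collapse in
  a CNN stack (reported with the layer index), non-symmetric adjacency,
  ragged or duplicated model tables, zero-variance correlation inputs.

## Problem sizes used by the shipped checks

The test suite trains micro-architectures on k = 2–3 kmer spaces (16–64
kmers, seconds each) plus one full recovery run (2048 training 6mers,
~5 minutes); the acceptance script only enumerates kmer spaces and counts
atoms (46,656 + 3,125 kmers, seconds). The full published-scale battery
(50 repeats × all designs × tuned architectures on real ONT/nanopolish
tables) is available through the same functions but takes CPU-days and
external downloads.

## Known limitations

* The SMILES subset is exactly what the building blocks need — no
  charges, isotopes, stereochemistry, or elements beyond C/N/O/P.
* The aromaticity rule is validated only for these nucleotide blocks; it
  is not a general Hückel implementation.
* Chemical groups are encoded with their covalent context, so "stacked"
  novel groups (e.g. the methylamine of 6mA built from methyl + amine)
  are not expected to extrapolate correctly — a property of the modelling
  approach, not of this implementation.
* Single-threaded determinism is guaranteed; multithreaded BLAS may
  reorder floating-point reductions.
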