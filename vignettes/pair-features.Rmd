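---
title: "Profile pair features for protein fold recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile pair features for protein fold recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaapfold)
```

## The recognition problem

A protein fold is a structural category: proteins sharing a fold have the
same core arrangement and topology of secondary-structure elements even when
their sequences have diverged beyond recognition. Fold recognition from
sequence alone is therefore hard exactly where it is most interesting — at
low sequence identity — and the most informative inputs are not the raw
sequence but (i) an evolutionary profile, a position-specific scoring matrix
(PSSM) produced by an iterative database search, which estimates per-residue
amino-acid substitution probabilities, and (ii) predicted secondary-structure
probabilities per residue (helix, strand, coil). kaapfold implements a
feature-extraction method that uses both jointly, plus the classification
and evaluation machinery around it.

## The model

For a protein of length $L$, let $P$ be the $L \times 20$ matrix of PSSM
linear probabilities (rows sum to 1, columns in the fixed order
A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W, Y, V) and $S$ the
$L \times 3$ matrix of secondary-structure probabilities (helix, strand,
coil). Concatenating them column-wise gives

$$Q = [\,P \mid S\,], \qquad Q \in \mathbb{R}^{L \times 23},$$

whose entry $q_{i,j}$ is the probability of amino acid or structure state
$j$ at position $i$. The $k$-separated amino-acid pair features are the
shifted pair products

$$R_k(m, n) = \sum_{i=1}^{L-k} q_{i,m}\, q_{i+k,n},
  \qquad 1 \le m, n \le 23,$$

i.e. the expected number of ordered co-occurrences of column $m$ at a
position and column $n$ exactly $k$ residues downstream, under the
independent per-position distributions the profile describes. Each $R_k$ is
flattened row-major — $(R_k(1,1), R_k(1,2), \dots, R_k(1,23), R_k(2,1),
\dots, R_k(23,23))$ — into a 529-vector $f(R_k)$, and the full feature
vector concatenates separations in ascending order:

$$F = \big(f(R_1), f(R_2), f(R_3), f(R_4)\big), \qquad \dim F = 4 \times 529
= 2116.$$

When both blocks are one-hot (a deterministic sequence and structure
assignment), $R_1$ restricted to its first $20 \times 20$ block reduces to
ordinary adjacent-pair counts, so the method is a probabilistic
generalization of bi-gram composition that additionally sees longer
separations and sequence–structure co-occurrence.

Two useful identities, both enforced by tests: all entries of $R_k$ are
non-negative, and because each block row sums to one,
$\sum_{m,n} R_k(m,n) = \sum_{i \le L-k} (\sum_j q_{i,j})(\sum_j q_{i+k,j})
= 4(L-k)$ — a conservation law that pins down the normalization.

### Choices fixed by the implementation

* **Structure states.** The structural block has $s = 3$ columns (helix,
  strand, coil), which is what makes $Q$ 23 columns wide and a single
  separation worth $23^2 = 529$ features. `s` is carried through generically
  (any row-stochastic block of width $s$ yields $(20+s)^2$ features per
  separation), but every default and every file reader assumes 3 states.
* **Flattening order** is row-major by first index $m$ then $n$; feature
  names (`k3_C_W` = source C, target W, separation 3) make the layout
  auditable, and downstream indices depend on it.
* **Separation bound.** `k_max = 4` by default; larger separations are
  permitted but pair correlation decays with distance and adds little.
* **PSSM linear probabilities.** ASCII PSSM files carry two blocks: integer
  log-odds scores and weighted observed percentages. `assemble_profile()`
  supports two conversion modes — `"percentage"` (default): percentages
  divided by 100 and row-renormalized, since that block is already an
  empirical probability; `"logistic"`: element-wise
  $1/(1+e^{-\text{score}})$ on the log-odds block, then row renormalization.
  The mode is recorded on the resulting profile. All-zero rows (they occur
  in real PSSMs) become the uniform row $1/20$, keeping $Q$ row-stochastic
  without discarding residues.
* **Non-standard residues** (B, Z, X, U) are kept as positions — the pair
  sum operates on profile rows, not letters — but are skipped by the
  sequence-only baseline extractors.
* **No feature scaling.** Feature vectors are passed to the classifier
  unscaled; the conservation identity above already ties their overall
  magnitude to $L$.

## Baseline feature sets

For comparison the package implements the standard sequence and profile
baselines, all in the same canonical ordering: amino-acid composition (AAC,
counts/length, 20-dim) and occurrence (raw counts, 20-dim); ordered
pair frequencies over the raw sequence — PF2 for adjacent pairs
$(s_i, s_{i+1})$ and PF1 for pairs with one intervening residue
$(s_i, s_{i+2})$, 400-dim each, concatenated as PF (800-dim; PF1 first).
The "separated by one residue" naming is easily inverted, so it is fixed
here: the gap argument counts intervening residues. Profile mono-grams
(column sums of $P$, 20-dim; an optional flag divides by $L$, off by
default) and profile bi-grams ($\sum_i p_{i,m} p_{i+1,n}$, 400-dim) are the
evolutionary analogues. Each extractor can also run on the consensus
sequence, obtained by replacing every residue with the amino acid of
highest PSSM probability (ties break to the lowest canonical index).

## Classification protocol

Classification uses a support vector machine with the radial basis kernel
$K(z_i, z_j) = \exp(-g \lVert z_i - z_j \rVert^2)$, delegated to libsvm via
e1071 (one-vs-one voting for multi-class). The complexity parameter $C$ and
kernel width $g$ are chosen by exhaustive grid search maximizing stratified
inner cross-validation accuracy on the training portion only; ties break to
smaller $C$, then smaller $g$. Defaults follow the conventional libsvm
search, $\log_2 C \in \{-5, -3, \dots, 15\}$ and $\log_2 g \in \{-15, -13,
\dots, 3\}$, with a coarse 3×3 `"fast"` preset
($\log_2 C \in \{-1, 5, 11\}$, $\log_2 g \in \{-13, -7, -1\}$) for tests
and small synthetic runs. The inner search uses 3 stratified folds — deep
enough to rank grid points, shallow enough to keep the nested protocol
tractable.

Evaluation is stratified $n$-fold cross-validation ($n$ = 5..10 in typical
benchmark use): within each class, ids are shuffled by a seeded generator
and dealt round-robin to folds, so per-class counts differ by at most one
and the assignment is a pure function of (labels, $n$, seed). The grid
search is re-run inside each outer training split, so the held-out fold
never influences hyperparameters; a `global_grid` switch exists to mimic a
single pre-CV search when comparability with that older practice is wanted.
Every protein is predicted exactly once, and identical inputs and seeds
reproduce identical results. Whether to average repeated CV runs is left to
the caller (run several seeds and aggregate the `glance()` rows).

Per-class quality is summarized one-vs-rest:
sensitivity $= 100\,\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$,
specificity $= 100\,\mathrm{TN}/(\mathrm{TN}+\mathrm{FP})$,
precision $= 100\,\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$,
computed per class and then averaged unweighted over the classes present in
the truth labels (a prevalence-weighted variant exists but is off by
default). Ratios with zero denominators — e.g. precision for a class never
predicted — are reported as 0 with a warning rather than NaN. In hard
multi-class problems true negatives dominate, so high specificity with
variable sensitivity is the expected signature; the degenerate
all-one-class predictor reproduces it exactly and is pinned by a test.

## The synthetic generator

Real inputs require an iterative database search and a secondary-structure
predictor, so the package carries a seeded generator of fold-structured
datasets that exercises every stage, including the file dialects. Its
generative model, per protein: length uniform in a range; a latent residue
sequence drawn from a per-class emission distribution (one Dirichlet draw
per distinct concentration row — classes with identical concentration rows
share the draw exactly); class-specific pair motifs implanted as
(separation $k$, source, target) rules at a fraction `strength` of candidate
slots spaced $k+5$ apart, so motif instances never create cross-instance
pair correlations at separations up to 4; evolutionary rows built as
$(1-\tau)\,\text{one-hot(latent)} + \tau\,\text{Dirichlet noise}$ with
temperature $\tau$ (default 0.15; $\tau = 0$ gives exact one-hots and the
consensus recovers the latent sequence verbatim); structure rows from a
persistent Markov chain over helix/strand/coil (stay probability
$1 - 1/\bar\ell$, mean segment length $\bar\ell = 6$, so state runs look
like real secondary-structure segments); and an observed sequence that is
the latent one with each position mutated to a uniform random amino acid at
a configurable rate — mimicking the fact that an evolutionary profile
averaged over homologs is less noisy than any single sequence, which is
precisely why profile-based composition outperforms raw-sequence
composition on real benchmarks.

Three presets define the study conditions used throughout the tests:

* `easy_spec()` — 4 classes × 60 proteins, lengths 50–120, distinct
  compositions, strong motifs at separations 1–4, distinct structure
  biases; pair features should recover class labels almost perfectly
  (the recovery test requires ≥ 90% at 5-fold CV), while shuffled labels
  must fall back to the 25% chance floor.
* `ordering_spec()` — 4 classes × 40 whose separability is deliberately
  layered: the emission is shared exactly by all classes and signal enters
  only through motif letters; classes come in reversed-motif pairs, so
  composition distinguishes the pairs but never the classes within one;
  a weak adjacent-pair direction (strength 0.3) is visible from bi-grams
  up; a strong separation-3 direction (strength 0.75) plus class-specific
  structure bias only reaches the full pair features; and a 60% mutation
  rate grades raw-sequence composition below profile composition. This
  makes the qualitative ordering pair features ≥ bi-gram ≥ mono-gram ≥ AAC
  a property of the construction rather than an accident of magnitudes.
* `lag_only_spec()` — 2 classes identical in every marginal: class 1
  implants C→W at separation 3, class 2 the reversed W→C at the same rate.
  Single-residue composition is class-independent by design; the two
  ordered-pair cells `k3_C_W`/`k3_W_C` carry all the signal, and ablating
  exactly those features must collapse accuracy — a locality check that the
  method finds the signal where it was planted.

What the generator does **not** emulate: biophysically realistic
substitution matrices, homology search artefacts, alignment-depth effects,
length/composition confounds of real fold classes, or inter-position
dependence beyond the implanted motifs. Passing its tests shows the
machinery is correct and that pair features exploit lag structure that
composition cannot see; it says nothing quantitative about accuracy on real
benchmark datasets, which require externally computed profiles.

## File formats and numerical conventions

The PSSM reader parses the standard ASCII dialect (header listing the 20
amino-acid columns twice, rows of 40 integer scores plus trailing per-row
statistics, K/lambda footer), re-orders columns into the canonical order
whatever the header order, ignores blank and `#` lines, and reports
1-based row indices in errors. The structure-prediction reader takes
explicit column positions (default: the last three columns in file order
coil, helix, strand) — auto-detecting a dialect is refused as guessing;
rows must sum to 1 within $10^{-3}$ and are renormalized. The fixture
writer emits integer percentages by largest-remainder rounding (each row
sums to exactly 100), which bounds the per-entry round-trip error by the
quantization step of 0.01; structure probabilities are written at 10
decimals, bounding that round trip by $10^{-9}$. Feature tables serialize
densely (full double precision) or in the sparse 1-based `index:value`
convention of common SVM tools, with values at 12 significant digits and
zero entries omitted.

## Problem sizes

The test suite and examples run entirely on generated data at desk scale:
the recovery and chance-level checks use the easy preset (240 proteins,
2116 features, 5-fold CV with the fast grid preset, shuffled-label controls
over 5 seeds), the ordering check runs 4 extractors × 3 seeds on the
layered preset (160 proteins), and the oracle-equivalence checks use 100
random profiles with $L \le 50$ and separations up to 6. These sizes were
chosen so the full suite exercises every claim in a few minutes on a single
core while keeping the statistical checks comfortably away from their
thresholds.

## Known limitations

Accuracies on the classical fold-recognition benchmarks (DD, TG, EDD) are
out of reach without external resources: they need the curated sequence
sets, an iterative search against a large sequence database to build real
PSSMs, and a secondary-structure predictor. The package reads those tools'
outputs but does not run them. The physicochemical-attribute baseline
(composition plus hydrophobicity/polarity/volume/polarizability classes)
is not implemented, as the attribute tables live outside this package's
sources; the extractor registry leaves the slot. Alternative classifiers
beyond the SVM are reachable only through the exported building blocks
(`stratified_folds()` + any fitter), not as named presets.
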