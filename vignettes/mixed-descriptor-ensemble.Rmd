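---
title: "Mixed-descriptor voting-ensemble classification of MHC proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-descriptor voting-ensemble classification of MHC proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcvote)
```

## The problem

Major histocompatibility complex (MHC) proteins are cell-surface molecules
that present peptide fragments to T cells; identifying which proteins in a
large collection belong to the MHC is a binary sequence-classification
problem. `mhcvote` treats it as such: protein sequences over the standard
20-letter alphabet come in, a 0/1 label (1 = MHC) comes out. The package's
scientific content is in three layers — the descriptor encoders that turn a
variable-length sequence into a fixed-length numeric vector, the
hard-voting ensemble that classifies that vector, and the evaluation
harness that quantifies performance.

## Descriptors

All five encoders operate on sanitized sequences (uppercase, only the 20
standard residues; `read_fasta()` enforces this with a `"drop"` or
`"reject"` policy). Their lookup tables — eight three-class physicochemical
partitions, five side-chain groups, seven conjoint-triad classes, and
Chou's hydrophobicity (H1), hydrophilicity (H2) and side-chain mass (M)
scales — ship as a plain-text data file and are validated at load time:
each partition must cover the 20 residues exactly once, and the three
scales are standardized to mean 0 and unit population variance over the 20
residues before use.

**`d188`** (188 dimensions). The first 20 components are residue
frequencies $V_i = N_i / L$ (so $\sum V_i = 1$). For each of the eight
properties the residue string is reduced to a string over classes
$\{1,2,3\}$ and summarized by composition (3 class fractions), transition
(3 values: adjacent pairs crossing each unordered class pair, divided by
$L-1$), and distribution (15 values: for each class, the positions of its
first, 25%, 50%, 75% and last occurrence as a percentage of $L$). The
quartile occurrence index is $\lceil qn \rceil$ for a class with $n$
occurrences, the dominant convention in this descriptor family; an absent
class contributes five zeros, and a length-1 sequence has all transitions 0
(there are no pairs). This yields $20 + 8 \times (3+3+15) = 188$ features.

**`apaac`** ($20 + 2\lambda$). Sequence order enters through correlation
factors
$$\tau_{2j-1} = \frac{1}{L-j}\sum_{i=1}^{L-j} H_1(R_i)\,H_1(R_{i+j}),
\qquad
\tau_{2j} = \frac{1}{L-j}\sum_{i=1}^{L-j} H_2(R_i)\,H_2(R_{i+j}),$$
for $j = 1..\lambda$. With normalized frequencies $f_u$ the components are
$P_u = f_u / (1 + w\sum\tau)$ for $u \le 20$ and
$P_{20+j} = w\tau_j / (1 + w\sum\tau)$, so the whole vector sums to 1.
Because the standardized scales take negative values, $\sum\tau$ can in
principle drive the shared denominator toward zero for adversarial
sequences; the encoder detects this degeneracy and errors rather than
returning unbounded values (it does not occur for random or natural
sequences at the default $w = 0.05$).

**`paac`** ($20 + \lambda$). The type-1 variant replaces the products by
averaged squared differences,
$\Theta(a,b) = \frac{1}{3}[(H_1(b)-H_1(a))^2 + (H_2(b)-H_2(a))^2 +
(M(b)-M(a))^2] \ge 0$, with the same normalization.

**`ksctriad`** ($343(k_{max}+1)$). Residues map to 7 conjoint-triad
classes; for each spacing $k$ the encoder counts class triples
$(s_i, s_{i+k+1}, s_{i+2(k+1)})$ into $7^3$ cells and rescales each k-block
by $(c - \min)/\max$, the conjoint-triad convention. An all-zero block
stays zero, and a window-count normalization is selectable
(`ksctriad_norm = "window"`).

**`cksaagp`** ($25(k_{max}+1)$) counts ordered side-chain-group pairs
$(g_i, g_{i+k+1})$ and divides by the $L-k-1$ windows, so each k-block is a
probability distribution over 25 cells; `encode_cksaap()` is the ungrouped
$400$-cell analogue.

The mixed vector concatenates enabled blocks in the fixed order `d188`,
`apaac`, `ksctriad`, `cksaagp`, `paac`; feature names follow the stable
`block.subblock.item` schema and are part of the model contract (prediction
rejects any column mismatch).

### Parameters and defaults

* `lambda_apaac = lambda_paac = 30`, `w = 0.05` — Chou's canonical pseudo
  amino acid composition settings. The correlation depth λ is in residues;
  larger values capture longer-range order but raise the minimum encodable
  length to $\lambda + 1$.
* `kmax_ksctriad = 0`, `kmax_cksaagp = 5` — the triad block already grows
  by 343 per spacing, so its default keeps only contiguous triads, while
  the cheap 25-cell group-pair block affords spacings up to 5.
* Sequences shorter than the largest requirement of the enabled blocks
  ($\max(\lambda_A + 1, \lambda_P + 1, 2k_T + 3, k_G + 2)$) are rejected at
  encoding time with the offending IDs listed — never silently padded or
  dropped.

These are deliberate conventions: the method description this package
implements does not fix λ, w or the k ranges, so the package exposes them
in `encoder_config()` and records them in every saved model and metrics
report.

## The ensemble

Three base learners are fitted on the (optionally standardized) feature
matrix: a 100-tree random forest, a linear-kernel SVM trained by sequential
minimal optimization via `kernlab::ksvm` ($C = 1$), and an SGD-trained
linear classifier with hinge loss and L2 regularization ($\lambda_{reg} =
10^{-4}$, 25 epochs, Pegasos-style step size $1/(\lambda_{reg} t)$,
unregularized intercept) implemented in the package. Standardization
(zero mean, unit variance per feature, constant features left unscaled) is
fitted on training data only and is on by default because two of the three
members are scale-sensitive.

Each member casts a hard 0/1 vote; the ensemble label is the 2-of-3
majority, which for three binary voters can never tie. Votes are returned
alongside the label so disagreements can be audited. A master seed fans out
to member seeds as `seed + 1/2/3` (forest, SVM, SGD), making fits
bit-reproducible. Soft (probability-averaged) voting is deliberately not
the default path: the hard vote is the defined method, and the members do
not share a calibrated probability scale.

## Evaluation

`compute_metrics()` derives SE, SP, ACC and MCC from confusion counts. A
zero SE/SP denominator yields `NA` plus an explicit flag; a zero MCC
denominator yields 0 with a flag — degenerate evaluations are visible, not
NaN-propagating. `cross_validate()` uses seeded, stratified folds (the
classes are near-balanced in the intended use, and stratification keeps
every fold usable for training); the primary report pools held-out
predictions across folds into one confusion table, because MCC of pooled
counts is well-defined while averaging per-fold MCCs is not, and the
per-fold table is retained alongside. `evaluate_holdout()` fits once on the
training set and refuses train/test ID overlap unless explicitly overridden
(`allow_overlap = TRUE`, for resubstitution checks only).

## The synthetic benchmark

`generate_synthetic()` provides a fully seeded two-class dataset so the
pipeline is testable end to end without downloads. Negatives draw residues
i.i.d. uniformly over the 20 letters; positives draw from
$(1-\delta)\,\text{uniform} + \delta\,\text{biased}$, where the fixed
biased distribution gives the hydrophobic residues C, L, V, I, M, F, W
weight 3 and the rest weight 1 (a crude but biologically flavoured
composition shift — membrane-associated classes are hydrophobic-enriched).
Lengths are uniform on 61–300 by default, so every sequence clears the
default encoder minimum of 31; an optional motif overwrites (not inserts,
preserving length) a random stretch of each positive.

What it emulates: two sequence classes whose residue-emission distributions
differ by a tunable amount, with realistic length variation. What it does
not emulate: domain architecture, homology structure, phylogenetic
redundancy, or any real MHC sequence family. A pipeline that separates
these classes demonstrates that encoding, training, voting and evaluation
are wired correctly and sensitive to compositional signal — it says nothing
about accuracy on real MHC data, which is dominated by subtler, non-i.i.d.
signals.

```{r example, eval = FALSE}
ds <- generate_synthetic(n_pos = 100, n_neg = 100, delta = 0.8, seed = 1)
cv <- cross_validate(ds, encoder_config(), n_folds = 10, seed = 1)
glance(cv)
autoplot(cv)
```

## Numerical and design notes

* The 188-feature layout is 20 AAC + 8 properties × (C 3, T 3, D 15); this
  is the only arithmetic consistent with both "21 numbers per property" and
  a 188 total, and it is the layout the wider 188D literature uses.
* Distribution percentages use 1-based positions, `position / L * 100`.
* Triad min–max scaling divides by the block maximum (not max − min),
  matching the conjoint-triad convention.
* Determinism is owned by `withr::with_seed` everywhere randomness occurs
  (fold shuffles, generator draws, member fits), so package calls never
  disturb the caller's RNG state.
* The test suite validates every encoder against independent brute-force
  reference implementations (naive character loops) at $10^{-9}$ on random
  short sequences, and checks the generator's null case, separation case
  and delta-monotonicity with 100+100-sequence datasets under 10-fold
  cross-validation — sizes chosen so the full suite exercises every code
  path at desk scale.

## Limitations

* Hyperparameters of the base learners are conventions, not tuned values;
  on real data a user should treat tree count, C and the SGD schedule as
  free parameters.
* The SVM member's training (SMO) scales superlinearly in sample count;
  for datasets in the tens of thousands expect the forest and SGD members
  to dominate wall-clock far less than the SVM.
* No feature selection or class weighting is implemented; strongly
  imbalanced datasets will bias the vote toward the majority class.
* MCC pooling across folds is the primary aggregate; per-fold MCC on tiny
  folds can be 0-flagged when a fold lacks a predicted class.
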