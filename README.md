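# mhcvote

Proteins encoded in the major histocompatibility complex (MHC) are central
to the vertebrate adaptive immune system, and screening large protein
collections for MHC members is a recurring sequence-analysis task. `mhcvote`
is an R package for exactly that binary decision: given a protein sequence,
is it an MHC protein or not?

It is aimed at bioinformaticians who want a transparent, fully reproducible
alternative to web-server predictors: every descriptor, every classifier
seed and every evaluation protocol is plain R, and a built-in synthetic
benchmark generator lets you exercise and test the entire pipeline with no
external downloads.

## The method

A sequence `R_1 R_2 ... R_L` over the 20 standard residues is encoded as the
concatenation of five classical descriptor families:

| block | dimension | content |
|---|---|---|
| `d188` | 188 | amino-acid composition (20) + composition/transition/distribution over 8 physicochemical 3-class partitions (8 × 21) |
| `apaac` | 20 + 2λ | amphiphilic pseudo amino acid composition: AAC plus hydrophobicity/hydrophilicity sequence-order factors τ_j = (1/(L−j)) Σᵢ H(Rᵢ)·H(Rᵢ₊ⱼ) |
| `ksctriad` | 343·(k+1) | k-spaced conjoint triads: residues mapped to 7 classes, class triples (sᵢ, sᵢ₊ₖ₊₁, sᵢ₊₂₍ₖ₊₁₎) counted and min–max scaled per k-block |
| `cksaagp` | 25·(k+1) | k-spaced side-chain group pairs: ordered pairs over 5 groups, counts / (L−k−1) |
| `paac` | 20 + λ | type-1 pseudo amino acid composition: AAC plus factors θ_j from averaged squared differences of standardized hydrophobicity, hydrophilicity and side-chain mass |

With the defaults (λ = 30, w = 0.05, triad k ≤ 0, group-pair k ≤ 5) the
mixed vector has 811 dimensions. The ungrouped `encode_cksaap()` (400 cells
per k) is also provided as the base method behind `cksaagp`.

Classification is a **hard-voting ensemble** of three base learners — a
random forest (100 trees), an SMO-trained linear-kernel SVM (C = 1) and an
SGD-trained hinge-loss linear classifier — each voting 0/1, the ensemble
taking the 2-of-3 majority. Features are standardized on the training data
only. Evaluation reports

    SE = TP/(TP+FN)   SP = TN/(TN+FP)   ACC = (TP+TN)/N
    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))

under stratified k-fold cross-validation (pooled held-out confusion counts,
per-fold breakdown retained) or an independent hold-out split.

## Worked example

```r
library(mhcvote)

# synthetic two-class benchmark: positives enriched in hydrophobic residues
ds <- generate_synthetic(n_pos = 60, n_neg = 60, delta = 0.8, seed = 42)

cfg <- encoder_config()
cv  <- cross_validate(ds, cfg, n_folds = 5, seed = 42)
cv
#> <mhc_cv> 5-fold stratified cross-validation (seed 42)
#>   pooled: ACC 0.9833  MCC 0.9667  SE 0.9833  SP 0.9833

tidy(cv)[, c("fold", "tp", "fp", "tn", "fn", "acc", "mcc")]
#> # A tibble: 5 × 7
#>    fold    tp    fp    tn    fn   acc   mcc
#>   <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     1    12     1    11     0 0.958 0.920
#> 2     2    12     0    12     0 1     1
#> 3     3    12     0    12     0 1     1
#> 4     4    11     0    12     1 0.958 0.920
#> 5     5    12     0    12     0 1     1
```

The pooled row says: of 120 held-out predictions across the 5 folds, 59
positives and 59 negatives were recovered (one miss each way), giving
sensitivity and specificity 0.983 and a Matthews correlation of 0.967 —
near-perfect recovery, as expected at this class separation (`delta = 0.8`
shifts the positive class's residue emission strongly toward hydrophobic
residues). At `delta = 0` the same pipeline hovers at chance (ACC ≈ 0.5).

`autoplot(cv)` draws the per-fold metrics; `glance(cv)` gives the pooled
one-row summary. To train a reusable model:

```r
fit <- fit_ensemble(encode_dataset(ds, cfg), config = cfg)
predict(fit, encode_dataset(ds, cfg))   # id, pred, and the three member votes
save_model(fit, "model.rds")
```

Real data enters as FASTA: `load_labeled("mhc.fasta", "non_mhc.fasta")`
reads a positive/negative pair (sanitization policy `"drop"` or
`"reject"`), and `evaluate_holdout(train, test, cfg)` runs the
independent-test protocol.

## Command-line interface

A thin Rscript front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mhcvote.R", package = "mhcvote"))')
Rscript $CLI synth    --out data --n-pos 100 --n-neg 100 --delta 0.8 --seed 1
Rscript $CLI train    --pos data/pos.fasta --neg data/neg.fasta --model model.rds --seed 1
Rscript $CLI predict  --model model.rds --fasta data/pos.fasta --out pred.tsv
Rscript $CLI evaluate --pos data/pos.fasta --neg data/neg.fasta --mode cv --folds 10 --out metrics.json
```

Exit codes: 0 success, 2 usage error, 3 data error, 4 internal error.

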