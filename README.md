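# wgdipc

Sequence-based protein classification — for example separating antifreeze
proteins (AFPs) from non-AFPs, or typing membrane proteins — needs two
things: a fixed-length numeric encoding of a variable-length amino-acid
sequence, and a way to discard the bulk of that encoding that carries no
class signal. `wgdipc` implements a complete, reproducible pipeline for
both, aimed at bioinformaticians building composition-based protein
predictors.

## The method

**Encoding (W-GDipC).** For a sequence $q_1 \dots q_n$, the dipeptide
composition is $\mathrm{DipC}(i) = f(i)/(n-1)$ over the 400 ordered
adjacent residue pairs; the generalized composition
$\mathrm{GDipC}(k)_i = f'(i)/(n-k-1)$ counts pairs separated by $k$
intervening residues (so $\mathrm{GDipC}(0) = \mathrm{DipC}$). The
weighted fusion

$$\text{W-GDipC} = \alpha\,\mathrm{DipC} + (1-\alpha)\,\mathrm{GDipC}(1),
\qquad \alpha = 0.8 \text{ by default},$$

combines adjacent and gap-1 information into one 400-dimensional
probability vector per sequence (the general convex form
$\sum_k \alpha_k\,\mathrm{GDipC}(k)$ with strictly decreasing weights is
also available).

**Selection (LRMR-Ri).** Four classical filters each pick `n` features:
Lasso (with a bisection search on the selection budget until the
selected-variable count lies in $[n, 1.05\,n]$), Ridge (closed-form
$b(\lambda) = (X'X+\lambda I)^{-1}X'Y$, penalty by cross-validated grid
search, top coefficients by magnitude), the maximal information
coefficient (grid-based normalized mutual information, grids capped at
$m^{0.6}$ cells), and Relief (nearest-hit/nearest-miss feature
weighting). If the four selected sets share a common subset, that
intersection is the final selection; otherwise Ridge re-selects from the
pooled union — a two-stage ensemble that screens out each single filter's
local optima.

**Evaluation.** Stratified five-fold cross-validation (selection refitted
inside each training fold by default) with accuracy, recall, precision,
F-measure and Matthews correlation; multiclass problems get per-class
one-vs-rest metrics plus a generalized overall MCC. SVM, decision-tree
and SGD (hinge-loss) backends are included, as is a planted-signal
synthetic sequence generator so the whole pipeline can be exercised — and
its feature recovery verified against ground truth — without any external
data.

## Worked example

```r
library(wgdipc)

cfg  <- sim_config(seed = 42)              # 120 "pos" / 94 "neg" sequences,
sims <- generate_sequences(cfg)            # two planted pairs per class
feats <- encode_features(sims, alpha = 0.8)

ens <- lrmr_ri(feats, n = 100, seed = 42)
ens
#> <wgdipc_ensemble> LRMR-Ri, n = 100
#>   stage-1 sets: 100/100/100/100 | intersection: 18 | pooled: 224
#>   branch: common subset (stage 2 skipped) | final: 18 features

planted_truth(cfg)
#> # A tibble: 4 × 5
#>   class pair      k feature index
#> 1 pos   AC        0 AC          2
#> 2 pos   DE        1 DE         44
#> 3 neg   KL        0 KL        170
#> 4 neg   VW        1 VW        359

cv <- cross_validate(apply_selection(feats, ens), classifier = "svm",
                     seed = 42)
glance(cv)
#> # A tibble: 1 × 9
#>   classifier selector folds  seed   acc recall precision f_measure   mcc
#> 1 svm        none         5    42 0.930  0.933     0.942     0.937 0.860
```

The four filters agreed on 18 of their 100 picks, so the intersection
branch fired; the 18 features include all four planted dipeptides
(`AC`, `DE`, `KL`, `VW` — check `ens$final` against
`planted_truth(cfg)$index`), and a five-fold cross-validated SVM on the
selected columns reaches 93% accuracy with an MCC of 0.86 on this
synthetic set. `tidy()` / `glance()` methods return tibbles for every
result type, and `autoplot()` draws the fusion-coefficient sweep,
selection score profiles and per-fold CV metrics.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/wgdipc.R simulate --seed 5 --out-fasta sim.fa --out-labels sim.tsv
Rscript inst/cli/wgdipc.R encode   --fasta sim.fa --labels sim.tsv --alpha 0.8 --out feats.tsv
Rscript inst/cli/wgdipc.R select   --features feats.tsv --method lrmr-ri --n 100 --seed 5 --out sel.tsv
Rscript inst/cli/wgdipc.R evaluate --features feats.tsv --classifier svm --selector lrmr-ri --n 100 --seed 5 --out report.json
```

## Documentation

The methods vignette (`vignettes/wgdipc-methods.Rmd`) describes the
encoding, the four filters, the ensemble's branch semantics, the
evaluation conventions (zero-denominator handling, the generalized
multiclass MCC), what the synthetic generator does and does not emulate,
and the package's numerical choices and limitations.
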