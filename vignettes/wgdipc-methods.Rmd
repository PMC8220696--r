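---
title: "Weighted generalized dipeptide composition and the LRMR-Ri selection ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted generalized dipeptide composition and the LRMR-Ri selection ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sequence-based protein classifiers — for example, predictors that separate
antifreeze proteins (AFPs) from non-AFPs, or assign membrane proteins to one
of several topology classes — need a fixed-length numeric representation of
a variable-length amino-acid string, and then a way to discard the large
fraction of that representation that carries no class signal. `wgdipc`
implements one complete pipeline for this task: a composition-based
encoding (W-GDipC), four classical filter selectors, a two-stage selection
ensemble (LRMR-Ri), and a cross-validated evaluation harness, together with
a synthetic sequence generator that makes every stage testable without any
external dataset.

# The encoding

For a sequence $q_1 q_2 \dots q_n$ over the 20 standard residues, the
dipeptide composition is the frequency vector of the 400 ordered adjacent
pairs,

$$\mathrm{DipC}(i) = \frac{f(i)}{n-1}, \qquad i = 1, \dots, 400,$$

where $f(i)$ counts occurrences of the $i$-th ordered pair. The
generalized form counts pairs $(q_j, q_{j+1+k})$ separated by a gap of $k$
intervening residues and normalizes by the number of such pairs,

$$\mathrm{GDipC}(k)_i = \frac{f'(i)}{n-k-1},$$

so that $\mathrm{GDipC}(0) \equiv \mathrm{DipC}$. Both are probability
vectors: 400 components, each in $[0,1]$, summing to one for every valid
sequence. The package treats sequences shorter than $k+2$ as hard errors
rather than returning a zero vector — a zero vector would silently break
the sum-to-one invariant that downstream code relies on.

The weighted fusion combines the gap levels convexly with strictly
decreasing weights,

$$\text{W-GDipC} = \sum_{k=0}^{d} \alpha_k\, \mathrm{GDipC}(k), \qquad
\sum_k \alpha_k = 1,\; \alpha_k > \alpha_{k+1} \ge 0,$$

reflecting the assumption that adjacent pairs carry more information than
widely separated ones. The pipeline default is the two-term special case

$$\text{W-GDipC} = \alpha\, \mathrm{DipC} + (1-\alpha)\, \mathrm{GDipC}(1)$$

with fusion coefficient $\alpha = 0.8$, the setting that performed best in
the fusion-coefficient sweep on AFP data; `alpha_sweep()` reruns that
experiment (11 coefficients from 0 to 1 in steps of 0.1, three
classifiers) on any dataset. The general form is exposed as
`w_gdipc_general()` but the experiments and defaults use the two-term
fusion exclusively.

Feature indices are fixed once and for all: residues in alphabetical
one-letter order `ACDEFGHIKLMNPQRSTVWY`, dipeptide $ab$ at column
$20\,(\mathrm{idx}(a)-1) + \mathrm{idx}(b)$, giving the column order
`AA, AC, …, YY`. No ordering is canonical in the literature; fixing one is
what makes selections and feature tables reproducible and interoperable.

# The four filters

Each filter scores all 400 features against the class labels and returns
exactly `n` of them (ties always broken by ascending feature index, for
reproducibility):

* **Lasso** (`lasso_select()`). The L1 path is searched through a budget
  constant $c$, mapped monotonically to the penalty as $\lambda = 1/c$:
  a larger budget admits more variables. Because the requested count `n`
  cannot be set directly, $c$ is bisected over $[0, 10^6]$ until the number
  of selected variables lies in the band $[n, 1.05\,n]$, with at most 100
  bisection iterations per attempt; on failure the interval is magnified
  tenfold and the search restarts, up to 10 times, after which the
  selector reports non-convergence (an explicit error by default, with an
  opt-in fallback to the top-`n` absolute coefficients). A feature counts
  as *selected at budget $c$* once it has entered the lasso path at
  penalty $\ge 1/c$; entry points are interpolated between path knots
  (by extrapolating each coefficient's initial slope back to zero) so the
  count increases one feature at a time along the budget axis and the
  convergence band is reachable whenever enough features ever enter the
  path. The band members are then ranked by absolute coefficient and
  truncated to `n`.
* **Ridge** (`ridge_select()`). The closed-form coefficients
  $b(\lambda) = (X'X + \lambda I)^{-1} X'Y$ are computed on standardized
  features (one eigendecomposition serves the whole grid), the penalty is
  chosen by 5-fold cross-validated mean squared error over 50 log-spaced
  values in $[10^{-4}, 10^{4}]$, and the `n` features with largest
  $|b(\lambda^\*)|$ are kept. Standardization is what makes coefficient
  magnitudes comparable across features.
* **MIC** (`mic_select()`). The maximal information coefficient of each
  feature against the response: the maximum over two-dimensional grids
  ($x$ columns $\times$ $y$ rows, $x y \le \lfloor m^{0.6} \rfloor$) of the
  grid's mutual information normalized by $\log \min(x, y)$. The default
  estimator equipartitions the y-axis and optimizes the x-axis cut points
  by dynamic programming over *clumps* (maximal runs of points that an
  optimal partition never splits), in both grid orientations; a superclump
  cap of $5x$ candidate blocks bounds the cost. Mutual information
  decomposes additively over columns once the rows are fixed, which makes
  the clump DP exact — the test suite verifies it against exhaustive
  enumeration of every cut placement on small samples. A plain
  equal-frequency estimator (`estimator = "equipartition"`) is available
  as a cheaper alternative. Features with fewer than two distinct values
  score zero, and at least 8 samples are required (below that the grid cap
  $\lfloor m^{0.6} \rfloor$ is degenerate).
* **Relief** (`relief_select()`). Instance-based weighting: each sampled
  instance pulls every feature weight down by its mean normalized
  difference to the $k$ nearest same-class neighbours (hits) and up by the
  difference to the $k$ nearest other-class neighbours (misses),
  $W(A) \leftarrow W(A) - \overline{\mathrm{diff}}(A,R,H)/m +
  \overline{\mathrm{diff}}(A,R,M)/m$, with
  $\mathrm{diff} = |R[A]-H[A]| / (\max A - \min A)$ for continuous
  features (0 for a constant feature). Defaults, none of which are
  canonical: a deterministic pass over all samples ($m$ = sample count),
  $k = 5$, Euclidean distances on z-scored features, misses taken per
  class and weighted by class prior for multiclass problems
  (ReliefF-style). With averaged neighbour differences every weight obeys
  $|W(A)| \le 1$. Selection is top-`n` by weight; the classical threshold
  form ($W \ge \theta$) is available via `theta`.

Class labels enter the two regressions as a single 0/1 indicator (binary)
or one-vs-rest indicator columns with per-feature score
$\max_c |b_c|$ (multiclass); an integer coding would impose an arbitrary
class ordering. A numeric response column is accepted as a plain
regression target, which is how the lasso band is exercised on synthetic
regression problems.

# The LRMR-Ri ensemble

`lrmr_ri()` runs the four filters (stage 1), each selecting `n` features.
If the four selected sets have a non-empty four-way intersection, that
common subset — of whatever size — is the final selection and stage 2 is
skipped; the common subset is taken to be "optimal" directly, so it is
returned unchanged even when smaller than `n`. Otherwise the four sets are
pooled into their union and Ridge re-selects $\min(n, |\text{pool}|)$
features *from the pooled columns only* (stage 2). The branch condition is
exact set semantics, unit-tested on constructed selections. One seed is
split into per-selector streams, so the whole ensemble is reproducible
from a single integer.

Two genuinely open points were resolved as follows: a "common feature
subset" means the four-way intersection of **any** size $\ge 1$ (requiring
size `n` would almost always force stage 2 and make the first branch
dead code); and Relief interoperates with the ensemble through its top-`n`
cut, not the $\theta$ threshold, because the ensemble needs equally sized
stage-1 sets. The number of features `n` each filter selects is not fixed
by any external convention; the package default is `n = 100` out of 400,
and every user-facing function takes `n` explicitly.

# Evaluation

`cross_validate()` performs stratified 5-fold cross-validation: folds are
dealt round-robin within each class after a seeded shuffle, every sample
lands in exactly one test fold, and fold metrics are averaged
arithmetically (mean of folds, not pooled predictions). When a selector is
configured it is fitted on each fold's *training* split only and applied
to the test split; `paper_mode = TRUE` instead selects once on the full
matrix before splitting, reproducing the more optimistic protocol that
published pipelines sometimes use without saying so. Binary problems
report the five standard indices from the positive class

$$\mathrm{ACC},\quad \mathrm{RE} = \frac{TP}{TP+FN},\quad
\mathrm{PE} = \frac{TP}{TP+FP},\quad
F = \frac{2\,\mathrm{PE}\,\mathrm{RE}}{\mathrm{PE}+\mathrm{RE}},\quad
\mathrm{MCC} = \frac{TP\,TN - FP\,FN}
{\sqrt{(TP{+}FP)(TN{+}FN)(TP{+}FN)(TN{+}FP)}}.$$

Zero denominators use the standard conventions (PE, RE, F and MCC all 0),
which is exactly what a class that is never predicted produces — small
classes in imbalanced multiclass data genuinely show rows of zeros.
Multiclass runs report per-class one-vs-rest PE/RE/F, pooled accuracy, and
an overall MCC in its generalized multi-category form computed from the
full confusion matrix (it reduces exactly to the binary formula for two
classes); the macro-average of per-class MCCs is reported alongside under
`mcc_macro` for anyone who prefers that summary.

Three classifier backends are provided for demonstration: an RBF-kernel
SVM (`e1071`), a Gini decision tree grown without complexity pruning
(`rpart`, `cp = 0`), and a linear hinge-loss classifier trained by
stochastic gradient descent (Pegasos schedule, 10 epochs, $\lambda =
10^{-4}$, one-vs-rest for multiclass), since no SGD classifier exists in
the installed R stack. Features are standardized inside each backend with
training statistics only. The SVM kernel width uses the median heuristic
($\gamma = 1/\mathrm{median}\,\|x_i - x_j\|^2$) rather than the library's
$1/p$: on sparse standardized composition features the $1/p$ width is far
too peaky and depressed SVM accuracy by around ten points relative to the
other backends; the median heuristic is a standard data-driven default and
can be overridden through `hyperparameters`. These choices shape
demonstration numbers only — the encoding and selection methods are
classifier-agnostic.

# The synthetic generator

`generate_sequences()` draws residues i.i.d. from a background
distribution (uniform by default) at lengths uniform in a configured range,
then plants class signal by Bernoulli-inserting whole residue pairs at a
gap: for a planted `(pair, k, rho)`, each of the $L-k-1$ slots receives an
insertion with probability $(\rho-1) p_a p_b$, raising the pair's expected
composition by a factor of about $\rho$ relative to background. Insertion
of whole pairs (rather than, say, biasing a Markov chain) was chosen
because the resulting enrichment is analytically computable, which is what
makes the generator usable as a ground-truth oracle for selector-recovery
tests. `planted_truth()` maps each planted pair to its canonical column —
gapped and adjacent pairs share the same 400-column name space.

The default binary configuration mirrors the shape of the AFP benchmark —
two classes at roughly the 480:374 imbalance, scaled to 120/94, lengths
50–100 (the range where most AFP sequences fall), two planted pairs per
class (one adjacent, one at gap 1) at enrichment $\rho = 10$.
`sim_config_multiclass()` mirrors the 8-class membrane-protein benchmark
at one-tenth scale while keeping its two tiny classes (30 and 56 members),
which is enough to reproduce the zero-metric phenomenon for rarely
predicted classes. What the generator does *not* emulate: residue
autocorrelation, homology between sequences, compositional biases of real
proteomes, or genuine AFP motifs. Passing recovery tests on this generator
therefore demonstrates that the selectors find localized composition
signal of a known effect size — not that they would rank features
correctly on any real proteome.

# Numerical choices and problem sizes

* Tie-breaks everywhere are by ascending feature index; identical inputs
  plus identical seeds give identical outputs, which the suite asserts.
* Compositions are kept in double precision with no rounding at encode
  time; sum-to-one is tested to $10^{-9}$.
* The lasso path is fitted on an explicit 500-point log-spaced penalty
  grid down to $10^{-4}\lambda_{\max}$ (an internally generated grid would
  stop early once the deviance saturates, making large budgets
  unreachable).
* Degenerate inputs fail loudly: sequences shorter than $k+2$, non-standard
  residues under the strict policy, fusion weights that do not sum to one
  or are not strictly decreasing, classes smaller than the fold count or
  than Relief's neighbour count, selections outside $[1, 400]$.
* Test and demonstration problem sizes were chosen to exercise the method
  at the study's shape while staying small: recovery experiments use 200
  sequences per class over 50 (test suite) or 20 (acceptance script)
  generator seeds; the end-to-end pipeline runs on the default 120/94 set
  with per-fold ensemble selection.

# Known limitations

* The MIC clump DP is exact given the equal-frequency y-axis partition,
  but the y-axis partition itself is the usual heuristic, and the
  superclump cap makes very fine grids approximate; MIC values on ties-
  heavy data depend on how ties are grouped.
* The lasso budget search inherits the assumption that selected-variable
  count grows with the budget; with interpolated path entries this holds
  by construction, but the interpolation is itself an approximation to the
  exact entry points.
* Relief distances are Euclidean on all features, so its weights degrade
  when the informative subspace is a tiny fraction of a high-dimensional
  noise space — visible in the recovery tests as the slowest riser with
  enrichment.
* The stochastic end-to-end margin over a label-permuted control varies
  with the generator seed; single-seed comparisons of classifiers on data
  this small should not be over-read.
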