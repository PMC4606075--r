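---
title: "Imbalanced multiclass PLS classification and core-formula mining: methods"
author: "maplsc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imbalanced multiclass PLS classification and core-formula mining: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maplsc)
```

## The problem

Clinical case collections from Traditional Chinese Medicine (TCM)
practice have a characteristic statistical shape: a few dozen records,
a few dozen mostly binary symptom items, several syndrome classes of
which one dominates, and — attached to each visit — a prescription,
i.e. a set of herbs. Two analysis tasks recur:

1. **Syndrome classification**: predict the syndrome from the symptom
   vector, under severe class imbalance and small n, where a
   classifier that ignores the minority syndromes is clinically
   useless even if its overall accuracy looks good.
2. **Core-formula mining**: find the herb subset common to most
   prescriptions for a disease or syndrome, the "core formula", from
   the transaction view of the prescriptions.

This package implements a calibrated one-versus-one partial least
squares ensemble for the first task, frequency/Apriori mining with a
cutoff heuristic for the second, the evaluation harness that judges
the classifier the way such studies report results, and seeded
generators of synthetic case tables and prescriptions so the whole
pipeline can be exercised and tested without access to any clinical
records.

## The classifier

### PLS base learner

Each binary sub-problem is solved by single-response partial least
squares regression on the class code $y \in \{+1, -1\}$, extracted by
NIPALS with single-response deflation. With centered data, component
$a$ takes the weight vector $w_a \propto E_{a-1}' f_{a-1}$ (the
covariance direction between the current feature residual $E$ and
response residual $f$), scores $t_a = E_{a-1} w_a$, loadings
$p_a = E_{a-1}'t_a / t_a't_a$, $q_a = f_{a-1}'t_a / t_a't_a$, and
deflates both residuals. The coefficient vector folds the sequence
into one affine map

$$g(x) = \bar y + (x - \bar x)' B, \qquad
  B = W (P'W)^{-1} q .$$

Successive scores are orthogonal by construction, and with as many
components as the rank of the centered feature matrix the
coefficients coincide with ordinary least squares — the property the
test suite verifies against a directly solved normal-equation oracle.

The default is `ncomp = 3`, clamped to `min(p, n - 1)` and to the
numerical rank (with a warning). Three components is a conventional
low-dimensional choice for binary symptom tables whose signal is
concentrated in a few presence patterns; it is configurable
everywhere it appears.

### Asymmetric boundary

PLS used as a classifier thresholds $g$. On imbalanced pairs the
natural threshold is not the midpoint of the class score means: the
class with the larger score dispersion needs more room. With
per-class means and standard deviations $(m^+, \sigma^+)$,
$(m^-, \sigma^-)$ of $g$ on the training data, the decision boundary
is the dispersion-weighted point

$$b = \frac{\sigma^- m^+ + \sigma^+ m^-}{\sigma^+ + \sigma^-},$$

and the classifier output is $f(x) = g(x) - b$. The weights place $b$
farther from the class with larger spread (when
$\sigma^+ = \sigma^-$ it reduces to the midpoint), which is the
standard asymmetric correction for imbalance. A direct consequence,
covered by a property test, is that shrinking one class's dispersion
pulls the boundary toward that class's own mean, enlarging the other
class's margin. This boundary rule is a reconstruction of the
asymmetric-PLS idea from its published description rather than a
line-by-line port of any reference code; it is kept in one small
function (`aplsc_fit`) so a variant rule can be dropped in.

Degenerate cases: a single-member class has no dispersion, so its
standard deviation is floored at $10^{-9}$, which collapses the
formula toward the other class's side rather than failing; identical
class means trigger a degenerate-separation warning. Within each
pair the index-smaller class is always coded $+1$, making the
orientation deterministic.

### Sigmoid calibration

The continuous outputs of different pairs are not comparable, so each
pair is calibrated to a pairwise posterior with the sigmoid

$$r(f) = \frac{1}{1 + \exp(A f + B)},$$

with $(A, B)$ fitted by penalised maximum likelihood on the pair's
own training scores (resubstitution — deliberately, to match the
training procedure this ensemble is defined with; no held-out
calibration split is introduced). The targets are smoothed,
$t^+ = (N^+ + 1)/(N^+ + 2)$ and $t^- = 1/(N^- + 2)$, which keeps the
fit finite on separable data. The optimiser is Newton's method with
backtracking line search, initialised at $A = 0$,
$B = \ln\!\big((N^- + 1)/(N^+ + 1)\big)$, with a $10^{-12}$ ridge on
the Hessian; non-convergence after 100 iterations returns the best
iterate with a warning. If a pair sees only one class, the fallback
is the flat smoothed base-rate sigmoid ($A = 0$). The evaluation of
$r$ clamps the exponent to $\pm 500$ and bounds the result strictly
inside $(0, 1)$.

### Pairwise coupling

At prediction time the $k(k-1)/2$ calibrated posteriors
$r_{ij} = \Pr(C_i \mid x,\; C_i \text{ or } C_j)$ (completed by
$r_{ji} = 1 - r_{ij}$) are combined by the simplified closed-form
coupling rule

$$\tilde p_i = \frac{2 \sum_{j \neq i} r_{ij}}{k (k - 1)},$$

and the predicted class is $\arg\max_i \tilde p_i$, ties broken
toward the smallest class index. Because every unordered pair
contributes exactly 1 to the double sum, $\sum_i \tilde p_i = 1$
identically — no iterative coupling is needed, and the acceptance
checks confirm normalisation and permutation equivariance on random
posterior matrices. The completion $r_{ji} = 1 - r_{ij}$ is the only
convention under which that identity holds when only the upper
triangle is computed.

## Evaluation protocol

Three criteria, all in percent:

* **micro-average accuracy** — fraction of examples correct; weighs
  every example equally, so it is dominated by the majority class;
* **macro-average accuracy** — unweighted mean of per-class recall;
  a constant predictor scores exactly $100/k$ whatever the imbalance,
  which makes this the floor every method must beat;
* **macro F1** — unweighted mean of per-class
  $F1 = 2PR/(P+R)$ with the convention $F1 = 0$ when a class is
  never predicted and/or never true.

Two closed forms anchor the implementation: for a 3-class problem the
constant-majority predictor has macro accuracy $100/3 = 33.33$, and
with majority prevalence $p = 0.7188$ its macro F1 is
$\tfrac{100}{3}\cdot\frac{2p}{1+p} = 27.88$. Both are recomputed from
predictions (never hard-coded) in the tests and the acceptance
script.

Cross-validation is stratified: within every class the fold counts
differ by at most one, the assignment is a deterministic function of
`(y, n_folds, seed)`, and a class smaller than the fold count is
allowed with a warning (macro metrics then exclude classes absent
from a fold's truth, again with a warning). The default is **5
folds**: with around 63 records and a smallest class of roughly 8,
10-fold partitions would routinely produce folds without the smallest
class. The comparison table reports mean ± standard deviation across
folds; whether published "±" figures of this kind come from one
partition or repeated cross-validation is generally unstated, so both
are possible here (run `cross_validate_compare` with several seeds
for the repeated variant). Shipped baselines are the constant
majority predictor, a seeded uniform-random predictor, and the hard
majority-vote variant of the one-versus-one ensemble
(`alg_aplsc_vote`), which differs from the coupled ensemble only in
skipping calibration and coupling.

## Mining

`occurrence_frequency` counts each herb once per prescription and
normalises by the number of transactions (an alternative
count/max-count normalisation sits behind a flag; which denominator a
published frequency axis uses is often unstated).
`suggest_core_cutoff` formalises the expert's "the frequency drops
obviously after herb $m$" as the index maximising
$\mathrm{count}_m / \mathrm{count}_{m+1}$ (smallest index on ties,
$\varepsilon$-floored on zero counts); the ratio is returned rather
than silently applied because the cutoff is an expert-in-the-loop
decision — a ratio near 1 means "no confident cutoff", and the CLI
always allows a manual override.

`apriori` is a plain level-wise implementation with prefix-join
candidate generation and subset pruning, returning exact supports; it
is verified against brute-force enumeration over all itemsets on
small vocabularies. `most_frequent_by_size` reduces the result to the
"most frequent n-itemset" table layout (one support-maximal witness
per size, lexicographic tie-break); by anti-monotonicity the supports
in that table never increase with size. The default
`min_support = max(2, ceil(0.05 n))` only bounds the search — the
per-size maxima it reports are threshold-independent down to the
sizes shown. `remove_items` (used to strip an established basic core
formula before ranking the remaining herbs) keeps transactions that
become empty so supports remain comparable before and after removal.

`info_gain_rank` scores symptoms by $H(Y) - H(Y \mid X)$ in bits over
empirical frequencies — the standard information-gain ranking for
key-symptom discovery; continuous features must be discretised or
indicator-encoded first (`encode_features`). `recommend_formula`
composes the fitted classifier with a syndrome-to-formula map and is
purely a composition of tested parts.

## Synthetic data

The generators emulate the statistical shape described above, not any
particular clinic's records.

`gen_cases` draws labels from the class prior and then each symptom
independently as Bernoulli: rate `present_prob_signal` for the
class's own disjoint block of signal symptoms, `present_prob_background`
elsewhere. Defaults: $n = 63$, $p = 32$, $k = 3$, priors
$(0.72, 0.16, 0.12)$ — the majority prevalence matches the
zero-variance constant-predictor micro accuracy of 71.88 % that
anchors the metric closed forms, with the remainder split so the
third class is smallest — 5 signal symptoms per class, presence
rates 0.8 vs 0.1 ("strong signal"). Five signal symptoms per class
is a middle ground chosen once: few enough that most of the 32 items
are noise, many enough that a 3-member class can still be recognised.

`gen_prescriptions` builds each transaction as core formula (included
whole with probability `p_core`) ∪ the syndrome's addon set
(probability `p_addon`) ∪ Poisson-many noise herbs drawn from the
rest of the vocabulary. Defaults: 500 transactions, vocabulary of 30
herbs, an 8-herb core at `p_core = 0.9`, a 2-herb addon at
`p_addon = 0.45`, Poisson(6) noise over the remaining 20 herbs. The
rates were placed by expectation so the frequency ranking has its
largest relative drop exactly after the core: expected counts are
about 450 for core herbs, 225 for addon herbs and 150 for noise
herbs, giving consecutive-rank ratios of roughly 2.0 at rank 8, 1.5
at rank 10 and ≈1 elsewhere, robust to binomial fluctuation at
$n = 500$.

What the generators do **not** emulate: symptom co-occurrence
(symptoms are conditionally independent given the class; real
checklists are correlated), categorical examination items, dosages,
repeated visits of one patient, and label noise. Tests passing on
this synthetic structure therefore demonstrate that the algorithms
recover planted structure under the stated sampling model — not
clinical validity on real records.

## Problem sizes used by the tests and the acceptance script

Chosen as comfortable sizes for the properties being checked: 1 000
random posterior matrices ($k \le 6$) for coupling; 200 random
transaction sets (vocabulary ≤ 12, n ≤ 50) against the brute-force
oracle; 50 random full-rank regression problems ($p \le 8$,
$n \le 40$) against least squares; 10 generator seeds each for the
classification-recovery and mining-recovery pipelines at the default
generator sizes ($n = 63$ cases; 500 prescriptions).

## Known limitations

* Calibration by resubstitution is optimistic on tiny pair subsets;
  with a handful of minority examples the sigmoid can be steep. A
  held-out calibration split would change the procedure's definition,
  so it is not offered.
* All decision boundaries are linear in the features.
* At $n = 63$ with a 0.12 prior, the smallest class occasionally
  draws only 2–4 members; in such draws the cross-validated per-class
  F1 of the smallest class can be 0 for some seeds (the acceptance
  script reports the minimum and mean over seeds rather than hiding
  this).
* `apriori` is exact and therefore exponential in the worst case;
  it is intended for prescription vocabularies (tens to a few hundred
  herbs with moderate supports), not for dense market-basket data.
* The ARFF dialect is dense-only; sparse files and string attributes
  are rejected by design.
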