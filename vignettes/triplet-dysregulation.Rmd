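---
title: "Scoring dysregulated ceRNA triplets: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dysregulated ceRNA triplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAdys)
```

## The biological model

Under the competing endogenous RNA (ceRNA) hypothesis, transcripts that
share miRNA binding sites compete for a common miRNA pool, which couples
their abundances: a lncRNA that sponges a miRNA relieves repression of that
miRNA's mRNA targets. In expression data this predicts a characteristic
sign pattern for a lncRNA--miRNA--mRNA triplet: negative miRNA--mRNA and
miRNA--lncRNA correlations, and a positive lncRNA--mRNA correlation. This
package identifies triplets that display that pattern in a reference state
(e.g. controls) and quantifies how strongly the pattern — and the
expression of the three members — changes in a second state (e.g. disease,
or a disease stage).

## Candidate assembly

Candidates are assembled in the reference samples only, from
experimentally supported miRNA-target tables:

1. **Shared-miRNA test.** For each (mRNA, lncRNA) pair, the number of
   miRNAs targeting both is compared against a hypergeometric null. With
   `N` miRNAs in the universe (by default, miRNAs with at least one
   interaction of either kind, restricted to profiled miRNAs), `K`
   targeting the mRNA, `n` targeting the lncRNA and `k` shared, the
   p-value is the upper tail `P(X >= k)`; pairs with p < 0.05 pass.
   The universe is the least arbitrary choice we could justify and is
   configurable; restricting it to profiled miRNAs keeps the null
   comparable to what can actually be observed.
2. **Signed correlation filters.** Each of the three links must carry the
   ceRNA sign and be individually significant (two-sided t-transform
   p < 0.05, exact rather than permutation-based, for determinism).
3. **Top-correlation retention.** Each link must also exceed the 90th
   percentile of the overall |r| distribution of its pair class (all
   profiled miRNA--mRNA interaction pairs; all miRNA--lncRNA pairs; all
   (mRNA, lncRNA) pairs sharing at least one miRNA). Computing the
   threshold on the *overall* class distribution, not on the already
   sign-filtered subset, is deliberate: it measures "top correlated"
   against what interaction-supported pairs generically look like, and it
   keeps the filter meaningful when nearly all significant pairs are true
   positives. Pairs are filtered, not triplets; a triplet survives only if
   all three links survive. Raising the percentile can only shrink the
   candidate set.

## Dysregulation scoring

Each candidate triplet receives six component scores between two states
(state 1 = reference, state 2 = case; only magnitudes of change enter, so
the orientation does not affect results).

**Node scores** measure per-transcript differential expression. With
p-value $p$ and log2 fold change from a two-group test,
$D = (-\log_{10} p)\,|\log_2 FC|$, mapped to the standard-normal quantile
scale by the tail transform
$\Phi^{-1}\!\big(1 - 2(1 - \Phi(D))\big)$.

**Edge scores** measure differential co-expression of each link:
$$\xi = \frac{F(r_2)(-\log_{10} p_2) - F(r_1)(-\log_{10} p_1)}
{\sqrt{1/(n_2-3) + 1/(n_1-3)}},\qquad
F(r) = \tfrac12 \ln\frac{1+r}{1-r},$$
with the same tail transform applied to $|\xi|$. $F$ is the Fisher
z-transform (equal to `atanh`), the variance-stabilizing transform of a
Pearson correlation.

**Combined score.** With three nodes and three edges,
$\mathrm{Score} = \omega\,\overline{\mathrm{node}} +
(1-\omega)\,\overline{\mathrm{edge}}$; the default $\omega = 0.5$ weights
both information sources equally.

**Empirical significance.** One shared null distribution is built by
assembling random triplets — one lncRNA, one miRNA, one mRNA drawn
independently from the gene pools, regardless of interaction support — and
scoring them identically. The default is 10,000 draws. The empirical
p-value is the fraction of null scores *strictly* larger than the observed
score (no pseudo-count, matching the definition as printed; a `(x+1)/(n+1)`
variant would be a one-line change). Triplets with p < 0.05 are flagged
dysregulated. A single shared null (rather than one null per triplet) keeps
the cost at 10^4 scorings; pools default to the genes appearing in the
candidate set so that the null lives on comparable expression strata, with
an option to widen to all profiled genes.

### Numerical choices

- The tail transform hits exactly 0 at $D = 0$ (quantile $-\infty$), so the
  transformed probability is clamped into
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-15}$
  (configurable). All scores are finite; the transform is strictly
  increasing below the clamp and flat beyond it (at about $\pm 7.94$).
- Internally the transform is evaluated on the small-tail side
  (`-qnorm(p2)` / `qnorm(1 - p2)`), which is algebraically identical to
  the textbook expression but avoids catastrophic cancellation; the test
  suite verifies agreement with an independent quadrature-based
  re-evaluation to 1e-8 over a randomized grid.
- All p-values are floored at 1e-300 before any $-\log_{10}$, for both
  differential expression and correlations.
- Correlations with $|r| \to 1$ are clamped to $1 - 10^{-7}$ inside $F$.

### What the score can and cannot distinguish

Because the sampling variance of $F(r)(-\log_{10} p)$ grows with $r$, a
*strongly* correlated link that does not change between states still
produces substantial $|\xi|$; with stringent clamping both an unchanged and
a fully decoupled strong link can sit at the clamped ceiling. In that
regime discrimination between candidates comes primarily from the node
(differential expression) components, while the permutation null — built
from random, mostly uncorrelated triplets — mainly separates candidates
from arbitrary gene combinations. The calibration guarantee we state and
test is correspondingly precise: when observed triplets are exchangeable
with the permutation null (drawn from the same pools by the same
mechanism), the flagged fraction at $\alpha$ matches $\alpha$. Users should
interpret the empirical p-value as "extremity relative to random triplets",
not as a test of change for an individual strong link.

## The traditional comparator

`traditional_method()` implements the binary comparator: all three members
SDE between states, shared-miRNA p < 0.05, reference-state sign pattern
significant, and the lncRNA--mRNA link no longer positive-significant in
cases (operationalized as r <= 0 or p >= 0.05). It returns an unscored set,
which is precisely its limitation relative to the ranked scoring above.

## Differential expression

The `"moderated"` method is the empirical-Bayes moderated t (limma), the
standard for array-scale two-group comparisons; `"welch"` is a plain
unequal-variance t-test retained as a distribution-free fallback — the two
agree essentially perfectly at large balanced n. Calls use raw p < 0.05
(no multiple-testing correction), since the scoring consumes raw p and FC;
a BH-FDR column is emitted for information only. Stage comparisons treat
groups as independent (the pairing of patients across stages, if any, is
not modeled). Input matrices are assumed log2-scale and normalized; the
package performs no normalization.

## Time-course utilities

Stage profiles are per-stage group means, standardized gene-wise to mean 0
and sd 1 so clustering groups trend *shapes*. Fuzzy c-means uses fuzzifier
m = 2 (the conventional default; the clustering literature rarely reports
it) with seeded random membership initialization, convergence when the
largest membership change falls below 1e-6 (at most 500 iterations), and a
recorded, provably non-increasing objective. Cluster counts are user
inputs; there is no automatic model selection. Co-expression partners use
|r| > 0.7 and p < 0.01. Gene-set enrichment is hypergeometric over a
user-supplied GMT collection; when several sets share a parent pathway
label (the GMT description field), only the lowest-p one is retained — a
set-based stand-in for sub-pathway mining, which requires pathway graph
topology and is out of scope. The enrichment universe defaults to all
profiled mRNAs and is configurable, since the appropriate background
depends on the platform.

## Biomarker panels

Feature reduction fits a 500-tree random forest, ranks features by
out-of-bag permutation importance (mean decrease in OOB accuracy), and
drops the lowest-scoring third per round until `target_k` remain —
`target_k` is explicit because "balance between accuracy and panel size" is
not an algorithm, and the per-round OOB accuracy trace is returned so the
user can see the trade-off. The exhaustive search then evaluates all
$2^k - 1$ subsets (guarded at k <= 16) by stratified, seeded 5-fold
cross-validated accuracy of an RBF-kernel SVM with cost 1 and kernel width
1/#features (the long-standing defaults of this classifier family; a
linear kernel is available). AUC is computed from decision values pooled
across the five test folds. Ties are broken toward fewer features, then
lexicographically. Sample grouping uses agglomerative hierarchical
clustering (Euclidean, complete linkage) cut at two clusters, with
per-cluster label composition reported as percentages.

## The synthetic cohort generator

`generate_cohort()` emulates a two-state, sample-matched, three-class
cohort: 46 controls and 73 cases by default (the scale of the kind of
cohort this method targets), 200 mRNAs / 60 lncRNAs / 40 miRNAs, and 20
planted triplets. Planted triplets follow a per-sample latent factor with
loadings chosen so each pairwise correlation equals `rho` (default 0.9,
the regime that survives a 90th-percentile correlation filter), with the
miRNA loading negative — the ceRNA sign pattern holds by construction,
which is why a latent-factor design was chosen over sampling covariance
matrices. Dysregulated triplets lose the coupling in cases and shift by
`delta` (default 1 log2 unit, mRNA/lncRNA up and miRNA down); residual
noise is `sigma = 0.3`. Decoy interaction edges (default 300 per class)
among background genes make the percentile filter and hypergeometric test
operate against a realistic pair population; decoys never touch planted
genes, so ground truth is unambiguous. Baseline expression is drawn
U(6,12), U(4,8), U(2,6) for mRNA/lncRNA/miRNA, mirroring the observed
ordering of the three classes. `generate_stages()` adds a control group
plus independent per-stage case groups with a spike-and-decay mean
trajectory for planted genes, in two sign-flipped trend families.

What the generator does **not** emulate: probe-level and batch structure,
heavy-tailed microarray noise, correlated background genes, unbalanced
missingness, or miRNA-mediated *partial* decoupling. Passing tests
demonstrate correctness of the machinery under the stated generative
model, not performance on real cohorts.

## Problem sizes used in the shipped checks

The package's own verification runs at sizes chosen to finish in minutes
on one core while keeping the statistics meaningful: oracle equivalence on
a 10^4-point randomized grid; permutation calibration with 1,000 observed
triplets against 1,000 null draws on a 46/73-sample null cohort; recovery
of 20 dysregulated among 200 planted triplets (400/250/220 genes, 2,000
decoy edges per class); DE calibration on 1,000 null genes; panel searches
over 5-feature sets (31 subsets). The discovery workflow default remains
10,000 permutations, which is itself sub-second thanks to vectorized
scoring.

## Known limitations

- The hypergeometric universe, the enrichment background, and the
  permutation pools are all conventions; results can be sensitive to them,
  which is why each is configurable and recorded in the run manifest.
- The edge statistic saturates for strong links under stringent clamping
  (see above); ranking within saturated triplets is then node-driven.
- Interaction tables are taken at face value; no attempt is made to weigh
  evidence strength or tissue specificity.
- Groups are treated as independent in all two-state comparisons.
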