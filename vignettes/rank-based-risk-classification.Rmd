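---
title: "Rank-based single-sample risk classification: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based single-sample risk classification: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its method: the model and its
assumptions, every tunable that matters, what the synthetic-cohort generator
does and does not emulate, the numerical conventions, and the design choices
that were genuinely open.

## The model

A patient's risk call is produced by three frozen stages.

**Pathway scoring.** Each sample's expression vector is reduced to pathway
enrichment scores by a single-sample rank-weighted running sum (ssGSEA).
With genes ordered by descending expression within the sample, a set $S$
scores

$$ES(S) = \sum_{i=1}^{N}\left[P^w_{in}(i) - P_{out}(i)\right],
\qquad
P^w_{in}(i) = \frac{\sum_{g \in S,\; \mathrm{rank}(g) \le i} w_g}
                   {\sum_{g \in S} w_g},
\qquad
w_g = (N - \mathrm{rank}(g) + 1)^{\alpha},$$

and $P_{out}(i)$ is the uniform ECDF of the genes outside $S$. The sum is
evaluated in closed form — each gene contributes its step once per position
at or after it — which equals the explicit walk exactly; the test suite
checks this against a brute-force running sum to $10^{-9}$.

The weights are powers of the *rank*, not of the expression value. This is
the load-bearing choice: with rank weights, every quantity downstream of the
raw matrix is a function of within-sample order only, so any strictly
increasing per-sample transform (library-size scaling, log transforms,
quantile maps, platform recalibration) leaves every score, every pair vote
and every risk call bit-identical. Expression-value weights would make
scores scale-dependent and void the single-sample guarantee. Assumption
inherited from the scoring model: expression is measured on *some* common
monotone scale per sample; nothing else is assumed about it.

**Pair rules.** On pathway scores, a k-top-scoring-pairs classifier is
trained on two prognosis classes. The primary statistic for an ordered
pathway pair is
$\Delta_{ij} = |\,\hat P(ES_i < ES_j \mid \text{poor}) -
\hat P(ES_i < ES_j \mid \text{good})\,|$, with score equality counted as
"not less than". Candidate pairs are ranked by $\Delta$ descending, then by
a secondary statistic $\gamma$ (the between-class gap in mean within-sample
*rank* differences — ranks again, to keep the tie-break scale-free), then
lexicographically by pathway name in the C locale so selection is fully
deterministic. Pairs are accepted greedily under a pathway-disjointness
constraint. Each accepted pair votes "poor" when the sample shows the
ordering that was more frequent in the poor class.

**Ensemble.** Training labels come from survival windows: poor = event
within 36 months, good = event-free with at least 60 months of follow-up,
everything else excluded. Over $B$ resampling rounds the labeled cohort is
split 70/30, stratified by class; a k-TSP member is fit on the 70% and kept
only if its balanced accuracy on the 30% strictly exceeds 0.6. A new
sample's risk score $s$ is the number of retained members voting poor;
the sample is high-risk iff $s > \tau$, strictly. Every round's seed is
derived from the master seed and the round index, so increasing $B$ never
reshuffles earlier rounds and retraining with the same seed is bit-identical.

## Tunable parameters

| parameter | default | notes |
|---|---|---|
| $\alpha$ (rank-weight exponent) | 0.25 | standard ssGSEA weighting exponent; $\alpha = 0$ gives the unweighted Kolmogorov–Smirnov-style walk |
| min/max set size | 5 / 2000 | after intersection with the gene universe; dropped sets are listed in a manifest, never silent |
| $B$ (resampling rounds) | 100 | |
| split fraction | 0.70 | stratified by class |
| balanced-accuracy cut | 0.6, strict | member retention |
| $\tau$ (vote threshold) | $\lfloor |M|/2 \rfloor$ | strict majority of retained members; stored in the model file and overridable, since a deployment-fixed integer cut (e.g. "score > 17") presumes a particular retained count |
| k grid | {3, 5, 7, 9} | odd by construction; chosen per member by 5-fold stratified CV, ties to the smaller k |
| screening m | 1000 | pathways kept (by absolute standardized two-sample rank statistic) before the quadratic pair search; purely a tractability device, set `Inf` to disable |
| label windows | 36 / 60 months | the 3-year / 5-year prognosis windows |
| AUC horizon | 36 months | |

Open choices resolved here, with reasons:

* **Stratified splits.** Plain random 70/30 splits can empty the smaller
  class's test part at realistic class imbalance; stratification guarantees
  both classes in every held-out fold, which the balanced-accuracy filter
  requires.
* **Tie votes go to "good".** A pair whose two scores are exactly equal in a
  sample casts a low-risk vote: deterministic, and conservative toward not
  flagging high risk.
* **$\gamma$ on ranks, not raw scores.** Raw-score means would reintroduce
  scale dependence through the back door of tie-breaking.
* **Screening before the pair search.** A pair search over a full pathway
  collection is quadratic in tens of thousands of features; screening to the
  m most class-associated pathways (by a rank statistic, preserving
  invariance) makes it tractable and is applied inside each resampling
  round, on that round's training part only, to avoid test leakage.

## Numerical conventions

* Within-sample ranks are descending with average ties; the running-sum
  *positions* use first-occurrence tie-breaking, which is stable under
  monotone maps (ties map to ties, order preserved).
* Duplicate gene rows on load collapse by arithmetic mean (the common
  probe-collapse convention) with a warning; missing values are errors, not
  imputations.
* The D-index maps risk to normal scores $z_i = \Phi^{-1}((r_i - 3/8)/(n +
  1/4))$ from mid-ranks, scales by $\kappa = \sqrt{8/\pi}$, and maximizes
  the Cox partial likelihood with Breslow tie handling by Newton–Raphson to
  $|\Delta\beta| < 10^{-8}$ (max 100 iterations). A diverging coefficient
  ($|\beta| > 30$) is reported as a monotone-likelihood error rather than a
  huge estimate. The fit is checked against an independent partial-likelihood
  maximizer in the test suite.
* The horizon AUC uses the simple binary definition: positives are events at
  or before the horizon, negatives are samples still event-free at the
  horizon, and samples censored earlier without an event are excluded and
  counted. No IPCW correction is applied; with heavy early censoring the
  binary AUC can be optimistic, which is an accepted, documented limit.
* C-index confidence intervals use a seeded percentile bootstrap over
  samples (default 1000 replicates) rather than an analytic variance.
* At prediction time a model pathway is rescored on whatever of its genes
  the input provides. If *none* remain, its score is undefined (NA) and every
  comparison involving it counts as a tie — a low-risk vote — with a warning;
  only when every model pathway is empty does prediction fail. This keeps
  deep gene-dropout experiments well defined: at 90% deletion a 15-gene
  pathway empties with probability $\approx 0.9^{15} \approx 0.2$, so
  erroring on any single empty pathway would make the default dropout grid
  unrunnable.

## What the generator emulates — and what it does not

`simulate_cohort()` draws gene baselines $\mathcal N(\mu_g, 1)$ on a log
scale ($\mu_g \sim \mathcal N(6, 1.5)$), pathways of 15–50 genes sampled
independently from the gene pool (so sets overlap, as curated collections
do), a latent patient class (prevalence 0.5), an additive shift $\delta$ on
prognostic-pathway genes in the poor class, exponential survival with hazard
$\lambda_0 \cdot HR^{\text{class}}$, and uniform censoring on $(0, c_{max})$.
Defaults — 2000 genes, 200 pathways, 10 prognostic, $\delta = 1$, $HR = 3$,
$\lambda_0 = 0.01$/month, $c_{max} = 180$ months — give roughly 30%
censoring and realistic poor/good label counts under the 36/60-month
windows. An optional per-sample random strictly-monotone distortion emulates
platform differences; by construction it changes no prediction.

What passing tests on this generator demonstrate: correct plumbing of the
whole pipeline, exact determinism, the monotone-invariance guarantee,
recovery of planted pathway structure, and graceful degradation under gene
loss. What they do *not* demonstrate: performance on real cohorts. Real
expression has correlated genes within and across pathways, library-size
and probe effects beyond monotone distortion, graded (not binary) biological
risk, and non-exponential, covariate-dependent censoring. In particular,
because simulated survival depends on expression only through a *binary*
latent class, the achievable concordance is capped: for a binary risk factor
with hazard ratio $r$ and prevalence $\pi$, even the oracle classifier's
expected Harrell C (ties credited 0.5) is about
$0.5 + 2\pi(1-\pi)\left(\tfrac{r}{1+r} - \tfrac12\right)$, i.e. $\approx
0.625$ at $r = 3$, $\pi = 0.5$. Held-out C-indices around 0.62–0.64 on this
design therefore indicate near-oracle recovery, not a weak classifier; the
D-index, which measures separation between prognostic extremes rather than
pairwise ranking, does not saturate this way.

## Problem sizes used by the test suite

The suite trains the reference conditions (600 samples split 300/300,
$B = 100$) once and reuses the fitted ensemble across the invariance,
dropout and serialization checks; recovery and null-calibration checks run
5 and 10 independent seeds of the full pipeline; oracle comparisons
(running-sum scores, exhaustive pair search, partial-likelihood fits) use
small instances (≤ 30 features, ≤ 500 samples) where brute force is exact
and fast. These sizes are the package's chosen reference scale: large enough
that class structure, censoring and resampling behave realistically, small
enough that the whole suite is routinely rerunnable.

## Known limitations

* The vote-count score is an integer in $[0, |M|]$; it is a ranking score,
  not a calibrated probability, and no calibration layer is provided.
* Members are unweighted; a member that barely passed the retention cut
  counts as much as a perfect one.
* The pair search is greedy; it matches exhaustive search on the instances
  tested but carries no global optimality guarantee.
* The evaluation battery is univariable by design: no multivariable Cox
  reporting, no IPCW/time-dependent concordance estimators, no competing
  risks.
* Only the generic weighted-sum scorer is provided for comparator
  signatures; signature-specific pipelines (random-forest or
  enrichment-based scorers) are out of scope.
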