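---
title: "Methods: interpretable fetal-status analysis of CTG feature tables"
author: "ctginterp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable fetal-status analysis of CTG feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctginterp)
```

## The problem

Antepartum cardiotocography (CTG) records fetal heart rate (FHR) and uterine
contraction signals; automated processing condenses each monitoring session
into 21 diagnostic features (baseline, accelerations, decelerations,
short-/long-term variability, FHR-histogram statistics) plus an expert
consensus label `NSP` (1 normal, 2 suspicious, 3 pathology). Classifiers
reach high accuracy on such tables but say nothing about *why* a record is
pathological. This package implements an interpretability pipeline with
three stages:

1. **Screening** — Spearman rank correlations among the 21 features and with
   `NSP`, redundancy grouping, and per-bin class-proportion profiles.
2. **Rule mining** — supervised discretization followed by a
   forward-stepwise association-rule search that maximizes rule confidence,
   designed for the rare pathology class where frequent-itemset miners fail
   their support thresholds.
3. **Latent-variable modelling** — confirmatory factor and structural
   equation models (SEM) grouping the features into five clinical constructs
   (baseline `BCat`, variability `VCat`, acceleration `ACat`, deceleration
   `DCat`, uterine activity `UCat`) and estimating standardized causal path
   coefficients to the fetal-status outcome.

A synthetic-data generator with known ground truth (class imbalance, planted
rules, known latent covariance) makes every stage testable without any
external download.

## Screening

Spearman's rho is the Pearson correlation of mid-ranks; ties — ubiquitous in
these integer-valued features and in the heavily tied ordinal `NSP` — get
average ranks, and `NSP` is ranked like any other variable. Two-sided
p-values use the large-sample t approximation on `n - 2` degrees of freedom.
No multiple-testing correction is applied in the main output (a Bonferroni
column is emitted alongside). A constant column has no defined correlation
and is flagged `NA`, never silently zeroed.

Redundancy groups are connected components of the graph with edges where
`|rho| >= threshold`. The threshold default is 0.7, the conventional "high
correlation" mark; it is exposed in the configuration because reasonable
analyses use 0.6–0.8. Class-proportion profiles take explicit bin edges
(half-open `[lo, hi)`, last bin closed); the pipeline default is ten
equal-width bins per feature augmented with clinically meaningful landmark
cuts (`ASTV` 18 and 80; `LB` 111 and 120), so the landmark observations —
e.g. that low-`ASTV` bins are purely normal — are directly checkable.

## Class-distribution discretization

Continuous features are partitioned by the class distribution: candidate
cuts fall wherever the majority class of the sorted records changes, then
bins are merged until at most `max_bins` (default 6) remain and every bin
holds at least `min_frac` (default 5%) of the records. The merge policy is
two-tiered: an under-mass bin is absorbed into its more similar neighbor
(L1 distance of class-proportion vectors, ties toward the lower index)
first; only when all bins satisfy the mass floor is the globally most
similar adjacent pair merged. Running the mass constraint through the same
global most-similar-first queue was tried and rejected: it keeps merging
past `max_bins` and destroys informative cuts far away from the under-mass
bin. A constant feature yields a valid single-bin scheme.

## Forward-stepwise rule mining

For a target class, the miner grows a conjunctive antecedent greedily:
at each step it evaluates, for every unused feature, every bin and every
union of adjacent bins spanning at most half that feature's bins (unions
reaching the maximum render as one-sided `feature > cut` conditions), and
adds the condition maximizing the confidence of `antecedent -> class`
subject to a support floor (`min_support`, default 5 records — a small
absolute floor keeps rare-class rules reachable while barring singletons).
Ties break by higher support, then canonical feature order, then lower bin
start, then shorter span, so the search is fully deterministic. It stops at
confidence 1, when no candidate strictly improves confidence, when the
support floor blocks all candidates, or when features are exhausted. The
trace of every step is retained; confidence is non-decreasing and support
non-increasing along it by construction. No class re-weighting is applied:
re-weighting the minority class is known to bias rule confidences, and the
support floor plus confidence maximization handle imbalance directly.

An exhaustive search over all antecedents of bounded length (same candidate
conditions, guard at $10^6$ combinations) serves as an independent oracle:
greedy confidence can never exceed it at equal antecedent length, and on
planted purity-1 data both reach confidence 1.

The miner is forward-only (conditions are never removed); emitted reports
print each condition's standalone confidence next to the conjunction, so
both the conjunctive reading and the per-feature reading of a rule table
are available.

### What "recovering a planted rule" means

The synthetic testbed plants a pure two-condition suspicious-class region
and surrounds it with pathology decoy regions that overlap each planted
interval on exactly one feature, plus a guard band below the second
interval. The decoys serve two purposes: they make every single condition
impure (so the conjunction is genuinely required), and they keep the
discretizer's cut points identified at the region boundaries. The planted
class is *suspicious* deliberately: the generator's pathology class is
naturally separable (pure high-`Variance` regions exist), so a planted
pathology rule would not be the unique confidence-1 rule.

Recovery is asserted as: exact feature-set equality, confidence exactly 1,
and the snapped intervals matching at least 90% of the planted-region
records. The exhaustive oracle is the recovering search for the interval
check — among confidence-1 antecedents it maximizes support, which selects
the widest snapped bin union. The greedy miner is required to attain the
same maximal confidence; its intervals are not required to cover the
region, because confidence maximization legitimately prefers a
sampling-noise-favored sub-slice whenever a discretized slice fragments,
and asserting interval equality for the greedy path would amount to
asserting sampling noise away.

## Structural equation modelling

The engine uses the LISREL parameterization: measurement equations
$x = \Lambda_x \xi + \delta$, $y = \Lambda_y \eta + \epsilon$ and the
structural equation $\eta = \beta \eta + \Gamma \xi + \zeta$, with
exogenous latent covariance $\Phi$, disturbance covariance $\Psi$ and
unique-error covariances $\Theta_\delta$, $\Theta_\epsilon$. The implied
covariance propagates $\Phi$ and $\Psi$ through $(I-\beta)^{-1}$ and the
loadings. Estimation minimizes the maximum-likelihood discrepancy

$$F_{ML} = \ln|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1})
  - \ln|S| - p,$$

with $S$ the sample covariance on denominator $n-1$; the model chi-square
is $(n-1)F_{ML}$.

**Presets.** The measurement preset is an oblique five-factor model over 17
indicators (all ten latent covariances free); the structural preset drops
`MLTV` (whose loading fails the Wald test at the measurement stage), treats
the 1/2/3-scored `NSP` as a continuous single indicator of an errorless
outcome construct, and estimates the paths variability→baseline, uterine
activity→deceleration, and acceleration/baseline/deceleration→fetal status,
with the variability–uterine covariance free. Each latent is scaled by one
reference indicator fixed at 1 (`Variance`/`ALTV`, `LB`, `DP`, `AC`, `UC`,
`NSP`); the single-indicator `UC` construct has its unique error fixed at 0
by default (exposed as a knob). Treating `NSP` as continuous and the
$(n-1)$ scaling follow the conventions of the widely used commercial SEM
tools for this kind of analysis; an ordinal/polychoric mode is out of
scope. Model trimming is by preset, not automated modification-index
search.

**Optimization.** Starting values are deterministic covariance-based
proxies: each latent is proxied by its reference indicator with half that
indicator's variance; loadings, paths and latent covariances start at the
corresponding proxy-regression values. (A fixed `0.7*sd` loading start was
tried first and left the quasi-Newton iterations in a flat region on clean
data.) Estimation then runs PORT quasi-Newton iterations, a
central-difference-gradient polish, and up to three Newton steps on the
numerical Hessian, giving gradient norms near machine precision — this is
what makes noiseless-recovery errors below $10^{-6}$ and standardized
solutions reproducible to $10^{-8}$ under per-indicator affine rescaling.
Implied covariances that leave the positive-definite cone during search are
penalized; non-convergence is returned as a flagged fit, and negative
variance estimates (Heywood cases) are flagged, with an optional positive
floor. Standard errors come from the inverse numerical Hessian of $F_{ML}$
scaled by $2/(n-1)$; the Hessian uses a small fixed step because a
Richardson scheme with large initial steps crosses the admissibility
boundary when a latent correlation sits near $\pm 1$.

**Standardization and signs.** Loadings and paths are rescaled by
model-implied standard deviations; latent covariances become correlations.
Each latent's reference indicator must load positively: a violating
solution has that latent (and all its loadings, paths and correlations)
sign-flipped before reporting. This makes the reported solution unique even
for variance-scaled factors, whose loading signs are otherwise
unidentified, and resolves reference-indicator sign reversals
deterministically.

**Effects.** Standardized total effects accumulate over the acyclic path
system via $(I-B)^{-1} - I$; indirect = total − direct; two-step chains are
reported with their per-path products. Effects on an observed outcome pass
through its standardized loading. Cyclic systems are rejected.

**Fit indices.** Chi-square, CFI, TLI (baseline: the independence model,
whose ML solution is the diagonal of $S$ in closed form), RMSEA with a 90%
noncentral-chi-square interval, and SRMR on correlation-scale residuals.
Indices are reported without pass/fail gates; a just-identified model
reports RMSEA 0 with a flag.

## The synthetic generator

`generate_dataset()` draws class labels multinomially (default 78/14/8%,
the imbalance typical of antepartum screening populations) and then
per-class features: truncated normals for continuous features, Poisson
event counts over a nominal 1800-second trace for event rates, categorical
`Tendency`. The per-class locations encode the clinically expected monotone
shifts — pathology up in `ASTV`, `ALTV`, `DP`, `LB`, down in `AC`, `MSTV` —
with magnitudes chosen to give the same order of class overlap seen in real
CTG tables; they are configuration, not estimates. Histogram consistency
(`Width = Max - Min`, `Min <= Mode, Median <= Max`) holds exactly by
construction, and the variability block (`Variance`, `MSTV`, `DL`, `Nmax`)
is location-linked to the drawn `Width`, which induces a
variability-factor covariance. Planted rule regions are carved from
existing records (so `n` is exact), their values snapped to each feature's
natural granularity, and the stated purity applies to *every* record in
the region — records that fall into it naturally are relabelled too — so a
purity-1 antecedent has confidence exactly 1. A single root seed drives
deterministic stage-local substreams; identical configurations give
identical datasets.

What the generator does *not* emulate: the exact joint distribution of real
CTG tables, an exact five-factor structure in the tabular draws (the
measurement model is deliberately misspecified there, and its fit is
expected to carry a flagged non-convergent or boundary solution — the SEM
engine is validated instead on `generate_sem_sample()` draws, which follow
the latent model exactly), serial correlation between sessions of one
pregnancy, or missing data. Passing tests therefore certify the
*algorithms* — rank computations, discretization, search, estimation — on
data with known truth, not distributional fidelity to any clinical
population.

`generate_sem_sample()` simulates from an explicit latent model;
`structural_true_matrices()` converts a standardized parameterization
(unit-variance latents and indicators) into full matrices, solving the
disturbance variances recursively so every endogenous latent has unit
variance. The shipped reference parameterization uses standardized
coefficients characteristic of antepartum CTG data (dominant
acceleration→status path near −0.67, strong uterine→deceleration path near
0.95, variability–uterine correlation near −0.93), so that recovery
experiments run at realistic effect sizes.

## Numerical choices and problem sizes

Defaults and experiment sizes used by the test-suite and the acceptance
script, chosen as the smallest sizes at which the stochastic checks are
stable: screening oracle on 200 random tables (n ≤ 50, heavy ties,
tolerance 1e-12); miner-versus-oracle on 100 random tables (≤ 6 features ×
≤ 4 bins, n ≤ 200); rule recovery on 20 seeds at n = 1200 with region
fractions drawn in [0.05, 0.2]; SEM recovery on 20 simulated datasets of
n = 2000 (standardized-path MAE below 0.05, 95% Wald coverage within
[0.90, 0.99]); scale invariance at 1e-8. Population summaries use
n = 10000, where the multinomial standard error of the class mix is about
half a percentage point.

## Known limitations

- The association-rule stage presumes the discretization grid; rules are
  only as sharp as the bins, and interval boundaries are reported snapped.
- The SEM engine fits by normal-theory ML only — no robust, WLS or
  polychoric estimation, no modification indices, no multi-group models,
  no bootstrap standard errors — and treats the ordinal outcome as
  continuous, which is a fidelity choice, not a statistical recommendation.
- Missing values are rejected, not imputed; the canonical CTG table is
  complete and the reader enforces that.
- The reproduction of published coefficient tables from the original
  21-feature clinical dataset requires that dataset's file; the package
  reads it (`read_ctg_table()`, CSV or spreadsheet dialect) but does not
  download it.
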