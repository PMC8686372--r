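# ctginterp

Interpretable analysis of antepartum cardiotocography (CTG) feature tables
in R: who drives a fetal-status call, and through which pathways?

Automated CTG processing condenses each monitoring session into 21
diagnostic features — baseline heart rate (`LB`), accelerations (`AC`) and
decelerations (`DL`/`DS`/`DP`) as events per second, abnormal
short-/long-term variability (`ASTV`/`ALTV` as percentage of time,
`MSTV`/`MLTV` as means), and FHR-histogram statistics — plus an expert
consensus label `NSP` (1 normal, 2 suspicious, 3 pathology). Classifiers
predict `NSP` well but opaquely. This package implements the
interpretability side for clinical researchers and biostatisticians:

- **`ctg_data`** — read (CSV or spreadsheet), validate and summarize the
  21-feature table; histogram-consistency checks (`Width = Max − Min`,
  `Min ≤ Mode, Median ≤ Max`) at warn or strict level.
- **`feature_screen`** — Spearman rank-correlation matrix of all features
  and `NSP` (mid-ranks for ties, t-approximation p-values), redundancy
  grouping by connected components above an `|ρ|` threshold, and per-bin
  fetal-status proportion profiles (the numbers behind percentage stacked
  bar charts).
- **`discretize_ara`** — class-distribution-guided discretization and a
  forward-stepwise association-rule miner that maximizes rule confidence
  under a support floor. For a rule A → c, support is the fraction of
  records matching A and confidence the fraction of those with class c;
  greedy forward selection of discretized conditions targets exactly the
  sparse-pathology regime where frequent-itemset miners fail. An exhaustive
  bounded-length search provides an independent oracle.
- **`sem_engine`** — maximum-likelihood structural equation models in the
  LISREL parameterization (x = Λx ξ + δ, y = Λy η + ε, η = βη + Γξ + ζ),
  minimizing F = ln|Σ(θ)| + tr(S Σ(θ)⁻¹) − ln|S| − p. Ships a five-factor
  measurement preset (baseline/variability/acceleration/deceleration/
  uterine-activity constructs over 17 indicators) and a trimmed structural
  preset with paths to the fetal-status outcome; produces standardized
  solutions, Wald tables (C.R. = estimate/SE), CFI/TLI/RMSEA/SRMR, and
  direct/indirect/total effect decompositions.
- **`synthetic_ctg`** — a generator with known ground truth: the 78/14/8%
  class imbalance, clinically oriented per-class feature shifts, planted
  association rules with exact purity, and exact latent-model simulation
  (`generate_sem_sample`), so the whole pipeline is testable offline.
- **`run_pipeline()` / `export_report()`** — orchestrate all stages
  deterministically and export every table as CSV with a hashed manifest.

## Worked example

```r
library(ctginterp)

## synthetic population with the canonical class imbalance
d <- generate_dataset(synth_config(n = 2000, seed = 42))
d
#> <ctg_dataset> 2000 records, 21 features + NSP
#>   provenance: synthetic (n=2000, seed=42)
#>   NSP classes: normal 1559 (78%), suspicious 287 (14%), pathology 154 (8%)

## screening: which features track fetal status?
spearman_matrix(d)
#> <ctg_correlation> 22 variables, n = 2000
#>   strongest |rho| with NSP: AC=-0.68, DP=0.55, ALTV=0.51, DS=0.48, ASTV=0.45

## mine a pathology rule
bins <- lapply(setNames(ctg_feature_names(), ctg_feature_names()),
               function(f) fit_class_distribution_bins(d, f))
res <- forward_stepwise_rule(d, bins, target_class = 3, min_support = 5)
res$trace
#> <ctg_rule_trace> 2 step(s), stopped: confidence_1
#>   + DP: [0.00166667, 0.00611111] support 0.0690  confidence 0.9348  (n=138)
#>   + Variance: [61, 242]      support 0.0400  confidence 1.0000  (n=80)
```

Fewer accelerations (negative rho for `AC`) and more prolonged
decelerations (`DP`) accompany worse status, and the mined rule reads: of
the 4% of records with a prolonged-deceleration rate in the given range
*and* high histogram variance, every one is pathological (confidence 1.00).

```r
## structural model on data simulated from the shipped reference topology
model <- structural_model_preset()
mats  <- structural_true_matrices(model)
X     <- generate_sem_sample(model, mats, n = 2000, seed = 7)
fit   <- fit_ml(model, sem_data(X))
standardize_solution(fit)$paths
#>        from    to        est    est_std
#> BCat   VCat  BCat  0.5970527  0.5199979
#> DCat   UCat  DCat  0.5266772  0.9537858
#> FStat  ACat FStat -1.0099895 -0.6761596
#> FStat1 BCat FStat -0.3227012 -0.2414108
#> FStat2 DCat FStat  0.2874694  0.1609426

effect_decomposition(fit, outcome = "NSP")
#> <sem_effects> standardized effects on NSP
#>  source  direct indirect   total
#>    VCat  0.0000  -0.1255 -0.1255
#>    UCat  0.0000   0.1535  0.1535
#>    ACat -0.6762   0.0000 -0.6762
#>    BCat -0.2414   0.0000 -0.2414
#>    DCat  0.1609   0.0000  0.1609
```

The standardized solution recovers the generating topology: the
acceleration construct dominates the fetal-status outcome (−0.68, protective),
deceleration worsens it (+0.16), and variability and uterine activity act
only indirectly, through baseline and deceleration respectively (their
indirect effects are the products of the mediating paths).

The full pipeline is one call:

```r
cfg <- pipeline_config(synth = synth_config(2000, seed = 42), seed = 42)
report <- run_pipeline(cfg)
export_report(report, "ctg-report")   # CSVs + summary.txt + manifest.json
```

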