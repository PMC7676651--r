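# vasokinetics

Kinetics of circulating progenitor cells during cardiopulmonary bypass
(CPB), and their use as early markers of post-operative vasoplegia.

## The problem

Vasoplegia — profound vasodilation after CPB, managed by escalating
norepinephrine (NE) — carries substantial morbidity. Circulating
progenitors (CD34+, CD133+, VEGFR2+ cells, hematopoietic stem cells
HSC = CD34+CD133+, endothelial progenitor cells EPC = CD34+VEGFR2+) are
enumerated by flow cytometry as **counts per 10^6 lympho-monocytic
events** at six intra-operative time points: post-induction,
sternotomy, pump start (0 h), 1 h, 6 h and 24 h. Patients whose total
NE dose stays at or below 0.02 mg/kg form the clinically insignificant
vasoplegia group (G1); doses above the cutoff define the clinically
significant group (G2). The scientific question: does a blunted early
rise of progenitor counts mark the patients who go on to develop
clinically significant vasoplegia?

`vasokinetics` implements the complete analysis for this question, at
the small sample sizes where it actually has to work (8 vs 7 patients):

* **Features.** Per-patient natural-log fold changes of counts against
  three baselines: post-induction (B1), sternotomy (B2) and pump start
  (P0); `log_fc = ln((c_t + pc) / (c_b + pc))` with a 0.5 pseudocount
  applied only to zero counts.
* **Group statistics.** Mann-Whitney U and Wilcoxon signed-rank tests
  with *exact* enumerated null distributions at small n (all
  `choose(n1+n2, n1)` label arrangements, all `2^m` sign patterns), and
  a Kolmogorov-Smirnov normality check with the Lilliefors correction
  (simulated null table).
* **Effect size and power.** Cohen's
  `d = (mean1 - mean2) / pooled SD` with df-weighted pooling, power by
  simulation and by the noncentral-t closed form.
* **Classification.** Single-feature logistic regression (ridge IRLS)
  and gradient-boosted stumps (logistic loss, exact split scan, Newton
  leaves) — both implemented in the package — validated by
  leave-one-out; MAE on hard labels equals the misclassification rate.
* **Significance of classification.** Permutation null: the full
  leave-one-out loop is re-run on label-shuffled (or
  uniform-feature-resampled) data; `p` is the fraction of
  randomisations with MAE at or below the observed value.
* **Risk matching.** Optimal 1:1 EuroSCORE II pair matching by exact
  dynamic programming over score-sorted lists.
* **Synthetic cohorts.** A generator whose defaults reproduce the
  reference study conditions (8 vs 7 patients; CD34+ feature
  distributions with group means 1.23/-0.51, 0.68/-0.50, 0.37/-0.09
  and SDs 1.08/1.05, 0.53/0.96, 0.42/0.43), so the whole pipeline is
  testable without patient data.

## Worked example

```r
library(vasokinetics)

cohort <- generate_cohort(default_scenario(seed = 1))
fc     <- build_fold_change_matrix(cohort$counts, baseline = "B1")
cd34   <- fc[fc$population == "CD34" & fc$timepoint == "H0", ]

head(summarize_by_group(cd34, cohort$patients), 2)
#>   group population baseline timepoint n mean_log_fc sd_log_fc       sem
#> 1    G1       CD34       B1        H0 8   1.0202009 0.6925136 0.2448405
#> 2    G2       CD34       B1        H0 7  -0.7889371 0.7569960 0.2861176

x <- cd34$log_fc[match(cohort$patients$patient_id, cd34$patient_id)]
y <- as.integer(cohort$patients$group == "G2")

mann_whitney(x[y == 0], x[y == 1])
#> mann-whitney test (exact): statistic = 54, p = 0.0012432 (n1 = 8, n2 = 7, two.sided)

cohen_d(mean(x[y == 0]), mean(x[y == 1]), sd(x[y == 0]), sd(x[y == 1]), 8, 7)
#> Cohen's d = 2.502 (pooled SD 0.723; n = 8 vs 7)

loo_evaluate(x, y, ids = cohort$patients$patient_id, spec = classifier_spec("gbt"))
#> leave-one-out (gbt): MAE = 0.1333 (2/15 misclassified)

permutation_p(x, y, spec = classifier_spec("logistic"), reps = 1000, seed = 2)
#> permutation test (label-shuffle, 1000 reps): observed MAE = 0.1333, p = 0.002

simulate_power(1.5, 8, 7, reps = 10000, seed = 3)
#> simulated power 0.761 (MC SE 0.004) for d = 1.5, n = 8 vs 7, alpha = 0.05, t test, 10000 reps
```

Reading: in this simulated cohort the G1 patients mount a ~e^1.0
(~2.8-fold) CD34+ rise by pump start while G2 counts fall; the exact
rank test separates the groups (p = 0.0012), the standardised
separation is d = 2.5, boosted stumps misclassify 2 of 15 patients
under leave-one-out, and that error is far better than chance
(permutation p = 0.002). A pooled t-test at these sample sizes has 76%
power to detect d = 1.5 at alpha = 0.05.

`run_pipeline()` chains all stages (simulate → features → tests →
effect/power → classify → permute → match), writes every intermediate
CSV plus a checksummed manifest, and is byte-reproducible under a fixed
seed.

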