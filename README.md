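# contextrisk

Context-specific perinatal risk estimation with discrete Bayesian networks.

Fetal growth restriction (FGR; estimated fetal weight below the 10th
percentile) is a leading risk factor for stillbirth, but most growth-restricted
fetuses experience no morbidity at all, so the diagnosis by itself is a blunt
prognostic instrument. `contextrisk` implements an explainable-AI approach to
this problem: a discrete Bayesian network (probabilistic graphical model) over
categorical clinical variables — fetal sex, preexisting diabetes, progesterone
use, hypertensive disorders of pregnancy, EFW percentile category,
gestational-age category, and related factors — whose joint distribution

P(x₁, …, xₚ) = ∏ᵢ P(xᵢ | pa(xᵢ))

supports *exact* conditional queries: the absolute risk (AR) of composite
perinatal morbidity under any partial clinical scenario, relative risks (RR)
against the cohort background or a reference scenario, and queries with any
variable — not just the outcome — as the target. Missing data are handled by
modeling an explicit `"unknown"` state rather than dropping or imputing rows.

The package covers the full analysis pipeline:

* **Cohort model** — clinical encodings (EFW/GA categories, HDP
  dichotomization, the nine-component composite outcome), exclusion filters,
  one-hot families, "% (n)" summaries, CSV + schema I/O.
* **Structure learning** — BIC hill-climbing with random restarts and clinical
  edge blacklists (mutually exclusive one-hot siblings may not predict each
  other); maximum-likelihood or Dirichlet-smoothed CPT estimation.
* **Exact inference** — variable elimination with a min-fill ordering, checked
  against an independent full-enumeration oracle to 1e-10; vectorized
  per-record prediction.
* **Risk analysis** — scenario AR/RR, bootstrap percentile confidence
  intervals (resample, refit parameters on the fixed structure, re-query),
  cumulative scenario sequences, alternate-target panels, and an
  effect-modification scanner that flags strata with non-overlapping RR
  intervals (a "reversal" when the RRs straddle 1).
* **Evaluation** — stratified 80/20 splits and k-fold CV, Mann–Whitney AUC
  with bootstrap CIs and Youden thresholds, paired-bootstrap model comparison,
  rare-pattern ("N of 1") subset performance.
* **Synthetic cohort generator** — a calibrated ground-truth network matching
  the published cohort's marginal prevalences and missingness, with a planted
  fetal-sex × preexisting-diabetes effect reversal, so the whole pipeline is
  testable without access-restricted data.

## Worked example

```r
library(contextrisk)

net <- make_truth_network()                      # calibrated ground truth
x   <- sample_cohort(net, 20000, seed = 42)      # synthetic cohort
x   <- inject_missingness(x, list(efw = 0.064, bp_high = 0.049), seed = 43)
fit <- fit_parameters(net$dag, x, method = "mle")

absolute_risk(fit, list())                       # background risk
s <- scenario("EFW 3-9th + diabetes",
              list(efw = "p3to9", diabetes = "present"))
relative_risk(fit, s)                            # RR vs background
bootstrap_ci(x, net$dag, function(f) c(rr = relative_risk(f, s)),
             b = 200, seed = 1)

scan_interactions(fit, x, "female_sex", "diabetes", b = 200, seed = 2)
```

Output:

```
AR background: 8.3 %
AR scenario: 31.3 %  RR: 3.77
<bootstrap_ci> B = 200
          rr
point 3.7662
low   3.2235
high  4.2468
  context_var stratum        rr    ci_low  ci_high
1    diabetes  absent 0.6850682 0.6160485 0.743018
2    diabetes present 1.5838835 1.1915963 2.216521
  effect_var context_var stratum_a stratum_b      rr_a     rr_b     flag
1 female_sex    diabetes    absent   present 0.6850682 1.583884 reversal
```

Reading the numbers: the model's background morbidity risk is 8.3%; adding
non-severe growth restriction (EFW 3rd–9th percentile) and preexisting
diabetes raises the absolute risk to 31.3%, a 3.8-fold relative risk with a
bootstrap 95% CI of 3.2–4.2. The interaction scanner recovers the planted
effect reversal: female sex is protective without diabetes (RR 0.69,
0.62–0.74) but harmful with it (RR 1.58, 1.19–2.22), and the two intervals do
not overlap.

The same machinery is available as a configuration-driven pipeline
(`run_pipeline()` / `pipeline_config()`, stages `simulate → select → learn →
evaluate → query`, with a thin CLI at `inst/scripts/contextrisk`).

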