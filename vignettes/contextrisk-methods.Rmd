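---
title: "Context-specific perinatal risk estimation with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific perinatal risk estimation with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextrisk)
```

## The problem

Fetal growth restriction (FGR, an estimated fetal weight below the 10th
percentile) is a leading risk factor for stillbirth, yet most growth-restricted
fetuses do well: the diagnosis alone is a weak prognostic instrument, and
clinical guidelines stratify management by FGR severity only. The question this
package addresses is how to quantify *context-specific* risk — how the risk of
composite perinatal morbidity (stillbirth, neonatal death, mechanical
ventilation, RDS, NEC, confirmed sepsis, grade 3–4 IVH, seizures, or a NICU
stay beyond seven days) shifts as clinical factors combine: fetal sex, maternal
preexisting diabetes, progesterone use, hypertensive disorders of pregnancy
(HDP), gestational-age category, and so on.

The modeling vehicle is a discrete Bayesian network (a probabilistic graphical
model): a DAG over categorical clinical variables in which each node carries a
conditional probability table (CPT) given its parents. The joint distribution
factorizes as

$$P(x_1,\dots,x_p) \;=\; \prod_{i=1}^{p} P\!\left(x_i \mid \mathrm{pa}(x_i)\right),$$

so any conditional query — the absolute risk of morbidity given an arbitrary
partial scenario, or the probability of *any* variable given any other — is
answerable exactly, without refitting. This is what makes the model
"explainable": every estimate decomposes into inspectable CPT entries.

## Cohort model

A `cohort` is a flat categorical table with a designated binary outcome. Every
variable carries a `variable_spec` whose states include the reserved label
`"unknown"`: missingness is modeled as an ordinary category, never imputed or
dropped. Clinical encodings follow standard obstetric conventions:

* **EFW percentile**: `<3` → `lt3`, `[3,10)` → `p3to9`, `[10,90]` → `p10to90`,
  `>90` → `gt90`. The half-open lower boundary makes the four categories a
  partition that matches the printed labels "<3rd" and ">90th".
* **Gestational age**: `<34` completed weeks → early preterm, `[34,37)` → late
  preterm, `≥37` → term. "34–36 weeks" is read as completed weeks, the usual
  obstetric convention, again yielding a partition of the post-exclusion range.
* **HDP** is dichotomized as eclampsia, preeclampsia with severe features, or
  gestational hypertension with pre-labor onset; mild preeclampsia alone does
  not qualify.
* **Composite morbidity** is present when any of its nine components is
  present; a missing component flag defaults to absent with a logged warning
  (records missing outcome data entirely are excluded upstream, so residual
  component missingness is treated conservatively).
* **Exclusions** run in a fixed order — missing outcome data first, then
  delivery before 20 weeks — with each record counted at its first matching
  criterion, so the per-criterion removal counts are deterministic.

Multi-state variables are one-hot encoded into families of binary siblings
(`ga_term`, `ga_late_ptb`, …) sharing a `family` identifier. Siblings are
mutually exclusive and exhaustive on observed rows; an unknown source cell
makes every sibling unknown.

## Structure learning

Structures are scored by BIC with natural logarithms,

$$\mathrm{BIC}(G) \;=\; \sum_i \left[\,\ell_i(\hat\theta_i) \;-\;
\frac{d_i}{2}\,\ln N\right],$$

where $\ell_i$ is the maximized multinomial log-likelihood of node $i$ given
its parents and $d_i$ the number of free parameters. Two counting choices
matter and are deliberate:

* $d_i = (r_i^{\mathrm{obs}} - 1)\, q_i^{\mathrm{obs}}$ uses the number of
  *observed* states and *observed* parent configurations. Because every
  variable formally carries an `"unknown"` state even when fully observed, the
  declared product would inflate the penalty with structural zeros whose
  parameters are never estimated: an unobserved parent configuration takes a
  uniform fallback rather than a fitted value, and a never-observed state sits
  at the MLE boundary 0. Counting only estimated parameters keeps the penalty
  honest and leaves scores of fully observed binary data identical to the
  textbook binary-variable BIC.
* Zero counts contribute $0 \cdot \ln 0 := 0$ to the likelihood.

The search is greedy hill-climbing over single-edge add/delete/reverse moves,
never creating cycles or blacklisted edges, accepting the best strictly
improving move with ties broken lexicographically by (parent, child). After the
first climb from the empty graph, `restarts` further climbs (default 10) start
from the incumbent perturbed by two random feasible edge additions; the best
local optimum wins, and the whole procedure is deterministic given its seed.
Family blacklists forbid both directed edges within every one-hot family, so
that, e.g., the absence of term birth cannot be used to "predict" preterm
birth. Exact discrete models are capped below 20 variables; the learner refuses
larger inputs.

Parameters are fitted either by maximum likelihood (uniform fallback for
unobserved parent configurations, flagged) or Bayesian estimation with a
symmetric Dirichlet prior, $(\mathrm{count} + \alpha)/(\mathrm{total} +
\alpha r)$, with $\alpha = 1$ by default (the choice of prior strength is
otherwise unguided).

## Exact inference

`query_net()` answers conditional queries by variable elimination under a
min-fill ordering; `brute_force_query()` is a deliberately independent oracle
that enumerates the full joint (refusing beyond $10^7$ configurations), and the
two are required to agree to $10^{-10}$ in the test suite. Three conventions:

* Evidence on `"unknown"` is conditioned on literally — it is a learned state,
  and training and inference must agree. Prediction for a record conditions on
  *all* its non-target cells, unknowns included; because that covers the
  Markov blanket, batch prediction reduces to the target's own CPT row times
  its children's entries, vectorized over records.
* Evidence with zero probability under the model raises an error rather than
  returning a uniform or NaN answer; a silent fallback would corrupt every
  relative risk built on top.
* For the node counts involved here (< 20), variable elimination is always
  exact; there is no approximate path.

## Risk queries, bootstrap, interactions

The absolute risk (AR) of a scenario is $P(\mathrm{outcome} = \mathrm{present}
\mid \mathrm{evidence})$; a relative risk (RR) is a ratio of two ARs. The
default reference ("background") is the fitted model's marginal outcome risk —
the model-based quantity, with the empirical event rate reported alongside in
the cohort summary. Confidence intervals come from a nonparametric bootstrap:
resample the cohort's rows with replacement, refit the CPTs *on the fixed
learned structure*, recompute the query, and take the 2.5th/97.5th percentiles
over (by default) $B = 1000$ replicates. Structure is not relearned per
replicate — point estimates are tied to one network's MLEs, which is also why a
point estimate need not sit in the center of its interval; a full-relearn
variant is a matter of passing `learn_structure` output per replicate, but is
not the default. Replicates in which a query becomes inconsistent are dropped
and counted.

Effect modification is scanned by comparing stratum-specific RRs: for a binary
effect variable (e.g. female sex) within each level of a context variable
(e.g. preexisting diabetes), the scanner computes the RR of the outcome for
effect present vs absent, with bootstrap CIs sharing replicates across strata.
A context is flagged when two strata have non-overlapping 95% intervals —
`reversal` when the point RRs also sit on opposite sides of 1, `magnitude`
otherwise. No multiplicity correction is applied; the flag is a screening
rule, not a formal test.

## Feature selection

Binary candidates (post one-hot) are ranked by Pearson chi-square and plug-in
mutual information (bits) against the outcome, computed pairwise-complete.
"Mutual information criterion" is implemented as plain discrete MI: all
predictors are categorical after encoding, and MI is exactly the "information
shared with the target" notion required; the maximal-information-coefficient
reading would only differ for continuous predictors, which do not survive
encoding. The two per-metric ranks are combined by rank sum (no combination
rule is otherwise specified), ties broken by name. Redundancy is pruned by the
Jaccard similarity of "present" sets: within any pair at or above the
threshold (default 0.8, configurable; both-empty pairs defined as similarity
0), the variable with the worse clinical rank — or, unranked, the worse
combined rank — is dropped, in a deterministic pair order, so the result is
independent of input ordering. Continuous inputs get empirical thresholds by
maximizing Youden's J over observed cutpoints, ties toward the smaller value.

The final feature set comes from a best-AUC search over $k$-subsets of the top
$m$ candidates, each fitted as a maximum-likelihood logistic model and scored
in-sample by default (a stratified-CV scoring flag exists). Exhaustive mode
refuses politely when $\binom{m}{k}$ exceeds its budget — at the study's scale,
$\binom{30}{12} = 86{,}493{,}225$ logistic fits — in favor of seeded subset
sampling or forward selection. Complete separation falls back to a ridge fit
and is flagged. Significant features of the best model (two-sided Wald
$p < 0.05$) are united with forced clinical includes, and the result must stay
below the 20-variable cap.

## Evaluation

Derivation/validation splits are stratified on the outcome with per-class
rounding (`round(0.2 n_c)` records per class to validation), which preserves
the event rate to within one record per side. Note that per-class rounding
cannot reproduce every printed pair of subgroup sizes exactly; it is the
deterministic convention used throughout. Cross-validation is stratified
k-fold (default 5) with at-most-one refold if a fold lacks both classes. AUC
follows the Mann–Whitney pair-counting convention (ties one half), its CI a
stratified bootstrap percentile interval, and its operating threshold the
Youden maximizer. Two models are compared by paired bootstrap of the AUC
difference (twice the smaller tail fraction, capped at 1); DeLong's test is
deliberately not the default since all other intervals here are bootstrap
percentiles. Rare-scenario ("N of 1") evaluation counts each validation
record's full covariate pattern (unknowns included) over the *entire* cohort
and evaluates the subset at frequency cutoffs 1, 5, 10 — these subsets nest.

## The synthetic cohort generator

Real nulliparous-cohort data of this kind are access-restricted, so the
package ships a fully specified ground-truth network over the twelve model
variables — preexisting diabetes, progesterone use, fetal sex, congenital
anomaly, PPROM, HDP, visit-3 EFW category, visit-2 BP > 140/90,
gestational-age category, urgent cesarean, 5-minute Apgar < 7, and composite
morbidity — whose exact marginals are calibrated to the published cohort's
prevalences (diabetes 1.6%, progesterone 2.6%, female sex 50.9%, anomaly 5.9%,
HDP 10.0%, urgent cesarean 9.1%, Apgar < 7 4.0%, EFW lt3/p3to9/gt90 =
1.0/4.3/7.3%, early/late preterm 2.8/5.8%, BP 0.8%, PPROM 2.6%, outcome 8.2%).
Calibration is exact by construction: root nodes take their targets directly;
conditional nodes fix a clinically plausible effect size and solve the
remaining baseline from the marginal mixture (linearly where possible, by
root-finding on the outcome intercept, by fixed-point iteration for the
three-parent gestational-age node, whose rare all-risk-factor rows are capped
at 90% total preterm mass). `make_truth_network()` verifies every marginal by
exact inference and errors on infeasible configurations.

The truth DAG is: diabetes → {EFW, HDP, morbidity}; HDP → {GA, urgent
cesarean, BP}; progesterone → GA; PPROM → GA; GA → {morbidity, Apgar}; anomaly
→ morbidity; sex → morbidity. The BP and PPROM placements (HDP → BP, PPROM →
GA) reflect the obvious clinical dependencies — second-visit hypertension is a
manifestation of hypertensive disease, and membrane rupture drives preterm
delivery — and keep the graph small enough for exact enumeration everywhere.

Effect sizes are design constants chosen once for clinical plausibility, not
calibrated to any published stratum estimate: diabetes triples HDP odds and
shifts the EFW profile toward both growth restriction and macrosomia; HDP,
progesterone and PPROM multiply preterm-category probabilities (progesterone
is an *association* — it marks pregnancies under clinical concern for preterm
birth — not a causal claim); early/late preterm birth carry large outcome
log-odds (2.75/1.23); anomalies multiply outcome odds by 3.5. The planted
interaction gives female sex an odds ratio of 0.70 on morbidity without
diabetes and 1.80 with it — a genuine effect reversal of the kind the
interaction scanner is meant to detect. Setting `interaction = FALSE` holds
the female effect constant across strata and serves as the negative control.
Missingness is injected completely at random (EFW 6.4%, BP 4.9%; the
missingness mechanism of the real data is uncharacterized, so MCAR is the
only defensible default), and never touches the outcome. One-hot families are
sampled as single categorical nodes and expanded afterwards, which guarantees
mutual exclusivity. The configured EFW/GA marginals are the *pre-masking*
truth-network marginals; the post-masking observed shares are a factor
(1 − missingness) smaller, which is also how the published per-category
percentages relate to their cohort denominator.

What the generator does *not* emulate: the real cohort's full correlation
structure beyond the planted DAG, continuous biometry, informative
missingness, site effects, or the 907-variable candidate pool. Passing tests
on this synthetic cohort therefore demonstrate that the machinery recovers
planted structure under realistic prevalences and noise — not that the
specific published real-data estimates are reproduced, which restricted data
access precludes by design. In particular the synthetic Bayes-optimal AUC is
what it is; it is compared against itself (learned vs truth network), never
against the published value.

## Numerical conventions and degenerate inputs

* CPT columns must sum to 1 within $10^{-12}$; query distributions within
  $10^{-10}$ of the enumeration oracle.
* Jaccard similarity of two all-absent columns is 0; a single-observed-state
  variable is flagged degenerate with zero statistics rather than erroring.
* Hill-climbing accepts only strictly improving moves (tolerance $10^{-9}$),
  so its score trace is strictly increasing and termination is guaranteed.
* Youden ties break toward the smaller cutpoint; AUC ties count one half.
* The stratified split and every bootstrap, fold assignment, subset draw and
  sampler call restore the caller's RNG state and are reproducible from their
  seed arguments.
* Degenerate bootstrap inputs (identical rows) legitimately yield zero-width
  intervals.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at sizes chosen to make the
statistical checks sharp while keeping a full run comfortable on a laptop:
oracle equivalence on 200 random networks of up to 9 nodes; parameter
recovery at n = 200,000; structure recovery and interaction power at
n = 50,000 (50 planted and 50 control seeds, bootstrap B = 200); bootstrap
coverage over 200 cohorts of n = 5,000; and an end-to-end pipeline at
n = 20,000 with B = 200. One caveat is documented honestly: with MLE refits,
CPT rows conditioned on very rare parent configurations (joint probabilities
of order $10^{-4}$ and below, e.g. diabetes × early preterm × anomaly) cannot
be pinned to total-variation distance 0.01 at n = 200,000 — their expected
support is a handful of records — so the corresponding uniform-over-rows
recovery assertion fails by design, while the cohort-weighted recovery error
per node is an order of magnitude below the same bound.

## Limitations

All estimates are associational conditional probabilities under the fitted
joint — no causal (do-calculus) reading is intended, and the progesterone
association in particular reflects confounding by indication. The CI
non-overlap interaction rule is conservative and uncorrected for multiplicity.
Plug-in MI is biased upward at small n; the ranking only uses it ordinally.
In-sample subset AUC mildly favors larger models; the CV flag exists where
that matters. The bootstrap treats the learned structure as fixed, so
structural uncertainty is not propagated into the intervals.
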