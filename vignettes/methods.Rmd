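---
title: "Methods: emulated-trial survival analysis with weighted deep networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulated-trial survival analysis with weighted deep networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, the decisions
behind them, and what the synthetic-data evidence does and does not show.

## 1. The estimand and the pipeline

The package emulates a two-arm trial of endovascular versus open repair for
ruptured abdominal aortic aneurysm on inpatient-claims data. The estimand
is the marginal effect of treatment on two survival outcomes measured from
the treatment date: perioperative mortality (death during the index stay or
within 30 days of discharge, with everyone else censored at discharge + 30
days) and long-term all-cause mortality (censored at loss to follow-up or
the administrative study end, whichever comes first).

Identification rests on the usual assumptions of this design:
exchangeability given the measured covariates (age, sex, race, repair year,
20 comorbidity flags), positivity of the propensity score, consistency, and
non-informative censoring. None of these are testable from the data; the
package's synthetic generator satisfies them by construction, which is
exactly why recovery tests on it validate the machinery and not the
assumptions.

The analysis has three stages:

1. a neural propensity model for `P(Z = 1 | X)` and the IPT weights
   `w = 1/e` (treated) and `1/(1 - e)` (control);
2. an IPT-weighted survival network `g(X, Z)` trained on a weighted
   partial-likelihood loss, converted into marginal survival curves by a
   weighted Breslow baseline and counterfactual standardization;
3. a 0.632 subsample bootstrap that refits stages 1–2 and summarises the
   layer-accumulated effect weights and curve bands.

A weighted Cox regression (Newton–Raphson, Breslow ties) runs alongside as
a linear comparator with a scaled-Schoenfeld proportionality diagnostic.

## 2. The loss and its conventions

The survival network is trained on

$$ l(\theta) = -\frac{1}{\sum_i d_i} \sum_{i=1}^n d_i\, w_i \Big[
   g_\theta(X_i, Z_i) - \log \sum_{j \in R_i} \exp g_\theta(X_j, Z_j)
   \Big]. $$

Three conventions deserve explicit statement because they are easy to get
silently wrong:

* **Risk set.** `R_i = {j : Y_j >= Y_i}` on observed times with Breslow tie
  handling, so the event subject belongs to its own risk set and the
  one-subject loss is exactly zero. A strict-inequality reading
  (`risk_set = "gt"`) is available but degenerates: the largest event time
  has an empty risk set, which the implementation drops with a warning.
  The default is the only reading under which the loss is a partial
  likelihood.
* **Where the weights sit.** As written above, `w_i` multiplies the event
  terms only; the log-sum in the denominator is unweighted. This is the
  loss the package optimizes by default, and `fit_weighted_cox()` defaults
  to the *same* objective so that a zero-hidden-layer network and the
  Newton fit are two optimizers of one function — the test suite checks
  they agree to 1e-3 relative. The epidemiology-standard pseudo-population
  form, with weights inside the denominator as `coxph(weights = )`
  maximizes, is available everywhere via `weight_denominator = TRUE`; with
  unit weights the two coincide (and match `coxph` to 1e-6 in the tests).
  For strongly informative weights the two objectives estimate slightly
  different quantities; the default keeps faith with the displayed loss,
  the flag provides the textbook estimator.
* **Normalizer.** The `1 / sum(d)` prefactor makes the loss scale-free in
  the number of events but not in the weights: doubling every `w` doubles
  `l` while leaving the argmin unchanged (asserted numerically in the
  tests).

Shift-invariance (`g -> g + c` leaves `l` unchanged) is inherited from the
partial-likelihood structure, so the network's output level is not
identified — only contrasts matter, which is why effects are read from
accumulated weights and curve contrasts, never from raw `g` values.

## 3. Networks and optimization

Both networks are small dense rectifier stacks, written directly in R with
manual backpropagation — at these sizes (≤ 30 inputs, widths ≤ 64) dense
BLAS matrix algebra is fast and a framework dependency would buy nothing.

* **Propensity network**: one hidden layer, default width 16
  (`hidden = 0` gives a plain logistic model, used as a `glm` oracle in
  the tests); sigmoid output on the logit scale; binary cross-entropy;
  minibatch SGD (default batch 256) with Nesterov momentum 0.9; learning
  rate chosen from a log-spaced grid on 0.001–0.05 by held-out
  cross-entropy on a fixed 20% split; early stopping with patience 20,
  best-epoch weights kept. The published analysis this emulates reports
  only its selected rate (0.008), not its grid; the grid bounds here
  bracket that value a factor of ~6 either side.
* **Survival network**: default two hidden layers of widths 32/16 ("two
  hidden layers, width by tuning" is the published description), linear
  scalar output, full-batch Adam. Full-batch is deliberate: the loss
  couples subjects through risk sets, so minibatching would change the
  objective.
* **Cyclical learning rate.** A triangular cycle between `lr/4` and `lr`
  with period 20 epochs, whose amplitude decays by 0.9 per completed cycle
  (floored at `lr/1000`). The decay is this package's addition to the
  plain triangular schedule: full-batch Adam with a non-vanishing step
  orbits the optimum at step-size radius instead of converging, which
  breaks the linear-equivalence oracle; a decaying amplitude restores
  tight convergence while keeping the cyclical exploration early on.
* **Initialisation** is He-scaled Gaussian, seeded; every fit is a pure
  function of (data, hyperparameters, seed). Divergence (non-finite loss)
  is an error naming the epoch, learning rate and architecture, never a
  silent retry.

## 4. From network output to survival curves

The package chooses a Breslow route from `g` to curves (the published
analysis shows curves but not its estimator):

* **Weighted Breslow baseline**: increment at event time `t` equal to
  `sum(w over events at t) / sum(w * exp(g) over subjects at risk)`;
  invariant to rescaling all weights.
* **Counterfactual standardization**: for arm `a`, every subject's
  treatment input is set to `a`,
  `S_i(t) = exp(-H0(t) * exp(g(X_i, a)))`, and the marginal curve is the
  average of the `S_i`. Averaging individual curves (rather than plugging
  in mean covariates) matches the marginal estimand the IPT weighting
  targets.
* **Expected survival** is the restricted mean survival time: the
  trapezoidal integral of the curve to a horizon τ, in days. "Expected
  survival" is not further specified in the source analysis; RMST is the
  standard functional with that reading, and τ defaults to the last
  observed time of the analysis set for the outcome.

Accumulated weights multiply the layer weight matrices, omitting biases and
the rectifier nonlinearity. For a linear network this is exactly the
coefficient vector; with hidden layers it is a linearization whose *scale*
is not comparable to a log hazard ratio — the tests therefore assert its
sign and its bootstrap interval, never its magnitude.

## 5. The synthetic claims generator

`simulate_cohort()` / `simulate_claims()` define the study conditions for
every test. What they emulate:

* covariate marginals matching the published cohort table: age ~ N(77,
  7.2²) truncated at 65, 74.2% male, race 91.4/5.5/3.1% white/black/other,
  repair-year shares drifting across 2011–2015, and the 20 comorbidity
  prevalences;
* confounded assignment through a known logistic model whose default
  coefficients make the endovascular arm older, sicker and later in
  calendar time; the intercept (−0.70) is set so the mean treated fraction
  matches the cohort's ~50.6% treated share;
* a **single death time with a piecewise hazard**: a high-hazard
  perioperative Weibull segment (shape 0.8, scale 85 days, truncated at
  the 35-day horizon) followed by a late segment (shape 1.1, scale 3400
  days), each multiplied by `exp(Xβ + Zδ)`. The scales were chosen once so
  that the perioperative and all-cause event fractions land near the
  published ~36% and ~61–66%. An earlier design simulated the two outcomes
  as independent times, but a claims record has one death date, and
  independence can violate the structural facts that the short-term time
  never exceeds the long-term time and that a perioperative death is an
  all-cause event; the piecewise construction restores both by
  construction and keeps proportional hazards *exact* whenever both
  segments share δ — which is what the recovery and calibration tests
  simulate. Arm-specific shapes (and segment-specific δ) produce the
  non-proportional regime;
* exponential loss to follow-up (default rate 5e-5/day) plus
  administrative censoring at the study end (2019-06-30) given a treatment
  date uniform in the enrolment window (2011-01-01 – 2015-09-30);
* claims dressing: admission 0–1 days before treatment, Poisson lengths of
  stay, condition diagnosis codes, one repair procedure code, planted
  ineligible records for every exclusion criterion, exactly
  `floor(frac * n)` blanked treatment dates, and a small fraction of
  missing covariates (default 0.2%, echoing the 15-of-7826 deleted records
  in the emulated cohort).

What it does **not** emulate: correlated comorbidities, non-logistic
assignment, informative censoring, coding noise, transfers, or multiple
claims per stay. Tests passing on this generator therefore demonstrate
correctness of the machinery under the design's own assumptions, not
robustness to their violation.

Stand-in code strings (`DX_RUPT`, `PROC_EVAR`, ...) are used throughout
because the real ICD-9-CM lists are not bundled; real lists drop in
through the same code-list configuration.

## 6. Cohort assembly decisions

* Age eligibility is evaluated at the index admission date.
* The 12-month prior-enrolment check is plain calendar arithmetic:
  `enrollment_start <= admission - 365` days, no leap handling —
  deterministic and documented beats calendar-perfect here.
* "First eligible claim" orders by admission date with ties broken by file
  order (a stable sort), and the exclusion log records every criterion in
  protocol order with counts that must reconcile step by step.
* Concurrent exclusion codes are checked on the index claim only; whether
  prior claims should also disqualify is unresolved in the source
  protocol, and index-claim-only is this package's reading.
* Same-day deaths would produce survival time 0; they are counted as half
  a day so times stay positive and `S(0) = 1` remains meaningful.
* Categorical percentage denominators in the descriptive table exclude
  missing values — required to reproduce the published race percentages —
  and chi-squared tests use the full contingency table without continuity
  correction. A zero-variance continuous covariate yields an `NA` p-value
  rather than an error.
* The emulated cohort's published table prints one treated-arm size in its
  header (3930) that disagrees with the text and with every percentage in
  the table (3960); the package uses 3960 and documents rather than
  resolves the discrepancy.

## 7. Inference

* **Weights clipping**: scores are clipped to `[0.01, 0.99]` by default
  before inversion, bounding every weight by 100. The source analysis is
  silent on trimming; `clip = 0` reproduces its literal rule.
* **Standard errors**: the Cox comparator reports model-based (inverse
  information) and robust sandwich standard errors; under IPT weighting
  the sandwich form is the defensible one and `tidy()` uses it by default.
* **Proportionality diagnostic**: per covariate, the correlation of
  weighted Schoenfeld residuals with the rank of event time, with
  chi-squared statistics `z_j^2 m / (sum(u^2) I_jj)` and a global
  `(m/sum(u^2)) z' I^{-1} z` on p degrees of freedom — the classical
  scaled-residual approximation, cross-checked against
  `survival::cox.zph(transform = "rank")` and calibrated by simulation in
  the test suite (≈5% null rejection over 200 seeds). With fewer than 3
  events the test reports itself undefined instead of erroring.
* **Bootstrap**: `floor(0.632 n)` subjects without replacement (floor is
  this package's choice for fractional sizes), per-replicate seeds derived
  deterministically from one base seed, full stage-1+2 refit per replicate
  by default (a survival-only fast mode exists and is labelled
  non-default). Hyperparameters are reused from the full-data fit, not
  re-tuned per replicate. Quantiles are type-7; curves are compared on a
  common grid (the full cohort's distinct event times) with step
  interpolation. Replicates failing structurally (single-arm subsample,
  fewer than 2 events) are skipped and counted; more than 10% failures
  aborts.

## 8. Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make each property
measurable while keeping a full run in the tens of minutes on one CPU:
marginal and propensity fidelity at n = 50,000; IPTW balance at n = 20,000
with true-propensity weights (max weighted SMD < 0.1); parameter recovery
at n = 5,000 with true hazard ratio 0.7 over 20 seeds (sign of the
accumulated treatment weight, pointwise curve dominance); proportionality
calibration over 200 seeds at n = 400 and power over 20 seeds at n = 5,000
under arm-specific shapes; a B = 50 null-effect bootstrap at n = 800. The
oracle equivalences (Newton Cox vs `coxph`, linear network vs Newton Cox)
run on a fixed 50-row fixture.

## 9. Known limitations

* The accumulated-weight effect measure ignores activations; it is a
  first-order summary whose magnitude has no hazard-ratio interpretation.
* The default loss weights only the event terms (Section 2); users wanting
  the classical IPTW Cox estimand should set `weight_denominator = TRUE`.
* Bootstrap validity for network weights has no theory behind it here (or
  in the literature this mirrors); the intervals are descriptive.
* The generator's comorbidities are independent Bernoulli draws, which
  understates the collinearity of real claims covariates.
* Networks are trained full-batch on one CPU; the implementation is sized
  for cohorts of thousands, not millions.
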