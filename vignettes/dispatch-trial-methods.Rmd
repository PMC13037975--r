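---
title: "Simulating and analysing dispatch prioritization trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing dispatch prioritization trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcstrial)
```

## The problem

Emergency medical dispatch centres routinely face *resource constrained
situations* (RCS): two or more patients are simultaneously waiting for an
ambulance when only one becomes available. One patient must be prioritized
for the immediate response; the others wait. `rcstrial` implements the full
computational machinery of a parallel-group randomized trial of a
machine-learning prioritization aid in this setting — synthetic trial
generation, NEWS 2 scoring, composite risk scoring, randomization and
protocol-exclusion logic, multiple imputation, Rubin's-rules pooled
inference, and compliance counterfactuals — so that every analysis can be
exercised, tested and calibrated on synthetic data with known ground truth.

The quality measure throughout is whether the *prioritized* patient (the
first to be assigned an ambulance after randomization) turns out to have the
highest National Early Warning Score (NEWS 2) in the RCS, computed from the
first vital signs subsequently measured. Ties count as correct: when the
immediate and a delayed patient have the same NEWS, no wrong choice was
available.

## The generative model

### Latent acuity

Each patient carries a single latent acuity scalar $a \sim N(0,
\sigma_a^2)$, unobserved by every decision-maker. It drives everything that
should be correlated in a coherent trial:

* **Vital signs** — each of the seven NEWS 2 components is drawn by *ordinal
  band sampling*: a proportional-odds model on $a$ selects a severity level
  worth 0–3 NEWS points, and a measurement is then drawn uniformly within a
  chart band carrying those points. This gives direct control over the NEWS
  distribution instead of requiring a physiological simulator. The
  level-probability constants were calibrated once so that the population
  mean NEWS is about 3 (with an SD near 3 and a heavily right-skewed
  distribution, typical of a low-priority cohort) and the Spearman
  correlation between acuity and NEWS is about 0.72. The expected NEWS of
  the acuity-0 patient is about 2.6; the population mean is higher because
  the band probabilities are convex in acuity. The `news_baseline`
  configuration shifts all band cutpoints on the log scale and should be
  read as an approximate population-level target.
* **Proxy outcomes** — four binary flags (abnormal primary assessment,
  lights-and-sirens transport, prehospital intervention, 72-hour admission
  or 30-day mortality) are Bernoulli draws whose logits are linear in $a$,
  with base rates of roughly 25%, 8%, 18% and 35%.
* **The nurse** perceives $a + \varepsilon$, $\varepsilon \sim N(0,
  \sigma_\text{nurse}^2)$, and the control-arm dispatcher prioritizes the
  patient perceived as sickest.
* **The model** sees $a + \eta$, $\eta \sim N(0, \sigma_\text{model}^2)$
  (shared across its four outcome predictions, plus a small per-outcome
  wobble proportional to $\sigma_\text{model}$), and converts it through
  the same outcome logits into four predicted probabilities, combined into
  the composite risk score.

### Composite score and confidence

The composite risk score is the weighted mean of the four predicted outcome
probabilities at the ratio 4:2:1:1 (weights normalized to sum to one). Only
ranks matter downstream, so any strictly monotone variant of the
combination rule is equivalent for the trial; the weighted mean is the
simplest choice consistent with a fixed weighting ratio, and is documented
as an assumption. Model confidence for a comparison is the gap between the
top and runner-up composite scores; the cutoff is the *median* gap of a
calibration set, which by construction splits that set 50/50 to within one
element. The package classifies each run's comparisons against the median
gap of the run itself. Whether confidence should be a patient-level or a
comparison-level notion is genuinely open; the comparison-level gap is the
simplest statistic expressing "how sure is the model about *this*
comparison" and is the package's documented choice.

### Calibration of the noise scales

The three behavioural parameters were calibrated once, by simulation at
n = 20,000 pairs, and frozen as package defaults:

| parameter | default | operating point |
|---|---|---|
| `nurse_noise_sd` | 3.5 | nurse picks the highest-NEWS member of a pair ~63% of the time |
| `model_noise_sd` | 1.35 | model's composite ranks the highest-NEWS member first ~70% of the time |
| `compliance_prob` | 0.602 | observed intervention-arm agreement with the model ~81% |

The noise SDs look large relative to $\sigma_a = 1$ because NEWS is itself
a noisy function of acuity: even a noiseless ranker identifies the
highest-NEWS pair member only ~86% of the time, and ties (counted correct)
put the random-guess floor near 55%.

`compliance_prob` is the probability that the intervention-arm dispatcher
*defers* to the model; otherwise the decision falls back to the nurse
choice. Observed agreement with the model exceeds the deferral probability
because independent nurse choices sometimes coincide with the model's top
pick — about 52–54% of the time in the control arm, where scores are
computed and stored but never displayed. `calibrate_compliance(target,
chance)` inverts `observed = c + (1 - c) * chance`; the default 0.602
reproduces an observed agreement near 0.81 under the default noise scales.
Keeping the behavioural parameter (deferral) distinct from the observed
rate is deliberate: it is the deferral probability that a trial
intervention can hope to change.

### Protocol machinery

Each RCS is randomized 1:1 by a registry keyed on the sorted member-id set,
so repeating the identical comparison always returns the same arm.
Dispatchers unhappy with an allocation are emulated by a re-roll: with
arm-dependent probability (defaults 0.166 after control, 0.124 after
intervention) the comparison is repeated with one newly recruited patient
added. The grown set is a different key and draws a fresh coin.
`resolve_repeats()` then applies the protocol rules: within a group of
events linked by shared patients, if all arms agree only the last event is
analyzable (earlier ones are *superseded* — no ambulance was dispatched
before the members reappeared); if any arms disagree, every linked event is
excluded as a protocol violation. The defaults produce roughly 19% protocol
exclusions with the observed asymmetry (more re-rolls after control
allocations). Opt-outs are independent per-patient flags (default 8%); any
RCS containing an opted-out patient is excluded, removing ~16–17% of the
remaining comparisons. `consort_flow()` reconciles the counts exactly and
fails loudly if they do not add up.

### Missingness

Vital-sign components go missing in two stages: ambulance documentation
(per-component rates 11–14%) and hospital supplementation, which restores
enough cells to leave final rates of 3.7–4.8%. Missingness is mildly MAR by
default: the logit of each component's missingness decreases by
`miss_acuity_slope` (default 0.3) per unit acuity — sicker patients are
better documented — which exercises the imputation machinery non-trivially;
setting the slope to 0 gives MCAR. The marginal rates are preserved by
construction.

## Imputation and pooled inference

Missing components are multiply imputed by chained equations on their
measurement scales, and NEWS totals are always computed from completed
components, never imputed directly. The default engine draws each
imputation from the terminal-node donors of a random forest (a tree is
chosen at random and an observed response is sampled from the missing row's
leaf); the fallback is predictive mean matching with five donors. Both are
donor-based, so imputed values are always observed values — valid ACVPU
levels, in-range measurements. The ordinal components (consciousness,
supplemental oxygen) are modelled on ordered integer codes. Defaults are
m = 10 chains and 10 iterations per chain; auxiliary predictors default to
age and sex plus all other vitals columns (which auxiliary variables belong
in the imputation model is an assumption, documented here).

Mixing is diagnosed per component with a between/within variance ratio on
the chain means of the imputed cells, discarding two burn-in iterations:
`sqrt(1 + max(0, B - W/I)/W)`. The `W/I` correction removes the sampling
noise a well-mixed chain mean necessarily carries, so the statistic centres
on 1 at stationarity instead of drifting upward with autocorrelation;
identical chains give exactly 1, and chains stuck at different levels
explode the ratio. Values above 1.2 are flagged.

Estimates are pooled with Rubin's rules: pooled point = mean of the
per-imputation estimates, total variance $T = \bar U + (1 + 1/m)B$, with
Barnard–Rubin small-sample degrees of freedom (complete-data df = n −
parameters). The primary and composite-outcome hypotheses are pooled
logistic regressions of correctness on arm; a per-imputation fit showing
perfect separation is refitted by Firth-penalized likelihood and flagged.
The NEWS-difference hypothesis pools Wilcoxon rank-sum z statistics
(tie-corrected, no continuity correction) as unit-variance estimates:
$z_\text{pool} = \bar z / \sqrt{1 + (1 + 1/m)\,\mathrm{var}(z)}$. An
alternative, simpler evaluation rule — analyse each patient's *median*
NEWS across imputations as a single dataset — is available through
`median_news()` for sensitivity analysis only: collapsing the imputations
before analysis discards between-imputation variance and risks inflating
type-I error, which is why Rubin pooling is the implemented primary path.
For RCS
with more than two members, the NEWS difference is the prioritized
patient's NEWS minus the *mean* of the delayed members' NEWS (the maximum
of the delayed members is the obvious alternative; the mean was chosen
because it uses every delayed member and reduces to the pair definition at
size 2).

## Counterfactual and ancillary analyses

* **Full compliance** replaces every intervention-arm prioritization with
  the model's top pick and re-runs the pooled primary analysis; the control
  arm is untouched. When the observed run was already fully compliant the
  result is identical to the observed analysis (asserted exactly in the
  tests).
* **Blended strategy** follows the model only where its confidence was
  high, keeping the dispatcher's observed choice otherwise; it equals the
  observed analysis when everything is low-confidence and the
  full-compliance counterfactual when everything is high-confidence.
* **Random baseline**: if the ambulance were assigned uniformly at random,
  the probability of a correct prioritization is (winner-set size)/(RCS
  size), averaged over RCS and imputations — an exact expectation, not a
  simulation.
* **Time trends** regress compliance (intervention arm) and correctness
  (control arm, spillover) on study month; **drift monitoring** computes a
  monthly Spearman correlation between the composite score and NEWS
  (months with under 10 patients dropped) and regresses it on months since
  the most recent model update, the clock resetting at each update (default
  update months 10 and 40 of a 46-month study); **calibration** fits
  NEWS ~ score + age + sex + complaint-category indicators in each
  imputation and pools each coefficient, flagging covariates with residual
  predictive value.
* **Sample size**: `power_proportions()` reports the closed-form
  normal-approximation two-proportion sample size in both the unpooled and
  pooled-variance variants. At 65.3% vs 70.3%, α = 0.05 and power 0.8 the
  unpooled formula gives 1,367 per group (~2,700 total); a total
  requirement of ~1,500 is *not* reproduced by either variant, so the
  utility reports both rather than forcing agreement.

## Numerical and design notes

* One master seed is expanded into independent per-stage streams (cohort,
  vitals, predictions, events, decisions, missingness, imputation), so each
  stage is reproducible in isolation and changing one stage's parameters
  cannot perturb another's draws.
* Ties in dispatcher or model argmax choices are broken by a seeded uniform
  draw; composite scores are continuous so model ties are measure-zero.
* SpO2 is scored on NEWS 2 scale 1 only; there is no data field for the
  hypercapnic-failure target range, so scale 2 is out of scope. New
  confusion scores 3 (ACVPU "C"). Temperature is banded to one decimal
  place, matching the published chart's closed intervals.
* The trained gradient-boosting text model behind the real risk scores is
  deliberately out of scope: it cannot be retrained without the dispatch
  corpus, and nothing downstream depends on more than the rank behaviour of
  its scores, which `model_noise_sd` controls directly.
* The generator is single-site; the restriction of the composite-outcome
  hypothesis to one site in the trial design is therefore a no-op here.
* Dispatch timing is an ordering plus lognormal delays; only the ordering
  affects any hypothesis test.

## What the synthetic cohort does and does not show

The generator reproduces the *statistical structure* the analyses assume —
group sizes, arm imbalance mechanisms, behavioural accuracy levels,
missingness rates, MAR dependence — with a single latent severity axis. It
does not model call text, geography, queueing, seasonal case-mix, or
multi-dimensional acuity, and its vital-sign bands are sampled uniformly
within chart bands rather than from physiological distributions. Passing
tests therefore demonstrate that the analysis machinery is correct and
calibrated under the stated assumptions, not that those assumptions hold in
any real dispatch system.

Problem sizes used in the test suite are chosen to make Monte-Carlo checks
sharp but cheap: the type-I-error study uses 1,000 replicates of 200-RCS
trials with m = 5 (PMM engine, 3 iterations); parameter recovery uses one
10,000-RCS run plus 200 replicates of 400-RCS trials; distributional
calibration checks use cohorts of 10,000–20,000 patients.

## A worked run

```{r example, eval = FALSE}
cfg <- trial_config(seed = 1)
sim <- simulate_trial(cfg)
res <- analyze_trial(sim, m = 10, engine = "rf")
print(res)
```

`run_pipeline(cfg, "out/")` performs the same steps and writes the patient,
event, decision, dispatch and long-format imputation tables, a results
JSON, rendered cohort/hypothesis tables and a run manifest; re-running with
the same configuration reproduces byte-identical outputs.
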