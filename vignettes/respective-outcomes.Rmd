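---
title: "Respective patient-selected primary outcomes: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respective patient-selected primary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respectr)
```

## The problem

In multisymptom conditions such as long COVID, patients differ in which
symptom dominates their life: fatigue for most, but breathlessness, pain,
anxiety/depression or something else entirely (brain fog, insomnia,
palpitations, ...) for many. A trial that fixes one instrument as its primary
outcome measures the wrong thing for a large fraction of participants. The
*respective* primary outcome solves this: each participant nominates at
baseline the symptom they would most like to see improve, that symptom is
measured with its own validated instrument at every visit, and the scores are
placed on a common scale by standardization.

## The model

Let $y_i(t)$ be the chosen-symptom raw score of participant $i$ at visit
$t$, measured by the instrument attached to the chosen symptom $s(i)$:
Chalder fatigue total (0–33, Likert 0–3 scoring) for fatigue, MRC dyspnea
grade (1–5) for breathlessness, P4 total (0–40) for pain, HADS total (0–42)
for anxiety/depression, and for an "other" choice the 10-point VAS rating of
the specific free-text symptom named at baseline, tracked by label across
visits. All instruments are oriented so that higher = worse.

For each symptom subgroup $s$, the baseline scores of **all randomized
participants** (both arms) who chose $s$ give a reference mean $m_s$ and
sample standard deviation $\mathrm{sd}_s$ ($n-1$ denominator). The primary
outcome is

$$ z_i(t) \;=\; \frac{y_i(t) - m_{s(i)}}{\mathrm{sd}_{s(i)}} , $$

with the *baseline* reference applied at every visit. Consequences that the
test-suite checks as invariants:

* the baseline mean of $z$ over the whole cohort is exactly 0, and each
  subgroup's baseline s.d. is exactly 1 (the pooled baseline s.d. is
  $\sqrt{(N-G)/(N-1)}$ for $G$ strata, slightly below 1);
* $z$ is invariant under positive affine rescaling of any instrument;
* a raw-score decrease (improvement) always yields a negative $z$ change.

The treatment effect at a visit is estimated by ANCOVA: least squares of
$z_i(t)$ on a treatment indicator, the five stratification variables (age
band, deprivation band, sex, ethnicity coded South Asian vs other, chosen
symptom) and the baseline $z_i(0)$, on complete cases, with CIs and two-sided
p-values from the $t$ distribution on the residual degrees of freedom and no
multiplicity adjustment. Repeated "other"-symptom VAS ratings (several per
participant) are analyzed per visit with a random intercept per participant
(REML via lme4), collapsing to ordinary least squares with a notice when
every participant has a single row.

## Tunable parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `p_deterministic` (minimization) | 0.8 | 80:20 deterministic:random mix; 0.5 reduces to a fair coin, 1 is fully deterministic |
| factor weights in the imbalance metric | equal | the marginal Pocock–Simon metric with equal weights is the field default; the trial's exact metric is unpublished |
| `alpha` | 0.05 | two-sided significance level for all CIs/p-values |
| imputation count `m` | 100 | the analysis plan's value; tests use m = 5 for runtime only (Rubin pooling is valid for any m ≥ 2) |
| chained-equation cycles | 10 | standard burn-in for one imputable block |
| PMM donors | 5 | standard predictive-mean-matching pool |
| IPW probability floor | 0.02 | positivity safeguard; truncations are counted and reported |
| baseline–follow-up correlation `rho` | 0.5 | generator default; only indirectly hinted at by the design's power reasoning |

## Power and sample size

`power_t` computes two-sample noncentral-$t$ power,
$1-F_{t,\nu,\lambda}(t_{crit})+F_{t,\nu,\lambda}(-t_{crit})$ with
$\nu=n_1+n_2-2$ and $\lambda=\delta/(\mathrm{sd}\sqrt{1/n_1+1/n_2})$;
`sample_size_t` inverts it for the smallest equal per-group $n$. For the
design values (0.5 s.d., 90% power, $\alpha=0.05$) the solver returns 86 per
group, and at the realized analysis sizes 97 vs 117 the power for a 0.5-s.d.
difference is 95.2%.

## What the synthetic generator emulates — and what it does not

`simulation_spec()` encodes the reference cohort: 234 participants; chosen
symptoms fatigue/breathlessness/pain/anxiety-depression/other at
54/16/12/1/17%; 85% female, 90% white, age 46.3 (s.d. 9.8) banded at 50,
deprivation bands 53/47%; ~3.5 free-text symptoms per participant; visits at
months 0/3/6; standardized treatment effects −0.90 (month 3) and −0.34
(month 6); secondary-outcome changes of the reported magnitudes (e.g. weight
−9.8 kg at month 3 in the intervention arm); and monotone attrition
calibrated so month-6 primary-outcome availability is ≈ 97/116 in the
intervention arm and 117/118 in control, with extra dropout log-odds (+1.0)
in the deprived band. Follow-up scores are generated on the standardized
scale — $z(t) = \text{drift}_t + \text{effect}_t \cdot \text{arm} + \rho
z(0) + \sqrt{1-\rho^2}\,\varepsilon$ — and mapped back to instrument units
through the instrument s.d., so the ANCOVA estimand equals the injected
effect by construction.

Stated-world choices the data do not pin down, made once and documented
here:

* **Baseline instrument distributions.** Per-subgroup baseline means/s.d.s
  are not published; plausible mid-scale values are used (Chalder 23 (4.5),
  MRC 3.4 (0.9), P4 22 (7), HADS 21 (7), VAS 7 (1.8)), truncated to
  instrument ranges and rounded to instrument resolution. Item-level
  responses are back-filled from totals by constrained allocation (items
  differ by at most one point), so totals — the only quantities the pipeline
  consumes — are distribution-matched, while item-level correlation
  structure is *not* emulated.
* **Control-arm drift.** Within-arm secular improvement (−0.30 s.d. at month
  3, −0.83 at month 6, the latter matching the reported control change) is
  shared by both arms and does not affect the between-group estimand.
* **Minimum stratum size.** With a 1% anxiety/depression choice probability,
  roughly a third of n = 234 multinomial draws would contain fewer than two
  choosers and make standardization impossible (the real cohort happened to
  contain three). The generator tops up every positive-probability stratum
  to `min_subgroup = 3` from the largest stratum. Replication harnesses
  still guard against the residual possibility of a zero-s.d. stratum by
  catching and counting (not silencing) the intended degenerate-reference
  error.
* **Attrition is MAR given arm and deprivation band** — matching the
  observed pattern (losses concentrated among deprived intervention
  participants). The generator's default outcome model is independent of
  deprivation, so complete-case ANCOVA stays unbiased; an
  `imd_outcome_shift` field turns on a deprivation-linked outcome shift for
  stress-testing IPW.

A green calibration test therefore establishes that the *pipeline* recovers
known effects under a cohort that is realistic in its margins and missing
patterns; it cannot establish anything about item-level psychometrics,
nonlinear symptom trajectories, or informative (MNAR) dropout, none of which
are generated.

## Numerical and design decisions

* **Chalder scoring** uses the 0–3 Likert method (0–33): reported
  fatigue changes of several points are only consistent with the 33-point
  scale. Bimodal 0/1 scoring is available (`method = "bimodal"`) but unused.
* **No proration**: an instrument with any missing item is missing at that
  visit. The source analysis is silent here; this is the simplest defensible
  rule and is applied uniformly.
* **"Other" references are pooled** across labels by default: all VAS
  ratings share the 0–10 scale and per-label subgroups are too sparse for a
  stable s.d. A `per_label = TRUE` mode exists.
* **Degenerate references** (n < 2 or zero s.d.) are a hard error by
  default; `on_degenerate = "drop"` omits the stratum with a warning. No
  silent fallback reference is ever substituted.
* **Recoding sensitivity analysis refits references** on the recoded cohort
  before re-standardization. Whether the original analysis refitted or
  reused its references is not stated; refitting is the self-consistent
  choice (the recoded dataset is "a cohort" in its own right) and both
  paths are exercised in tests.
* **Minimization details**: the first participant faces a tied imbalance and
  is assigned by fair coin; ties are always a fair coin; arm totals are not
  a sixth balancing factor by default (`include_arm_size` adds them).
* **CIs use t quantiles**, not normal, matching linear-regression reporting
  conventions; Barnard–Rubin degrees of freedom are used for pooled CIs when
  complete-data df are supplied, Rubin's large-sample formula otherwise.
* **Sex "other"** (and any factor level with a single participant) is merged
  into the modal level before regression, with a notice; ethnicity enters
  the model as South Asian vs other.
* **BMI subgrouping** uses tertiles computed on the analyzed cohort; no cut
  points are published.
* **MICE conditionals**: predictive mean matching (5 donors,
  approximate-Bayesian coefficient draws) for numeric columns, logistic for
  binary, normalized one-vs-rest logistic for unordered multi-level factors
  (no multinomial backend is assumed available); design matrices are built
  over observed and missing rows jointly so unseen factor levels cannot
  break prediction, and rank-deficient columns are dropped against the
  observed rows.
* **IPW with randomized arms**: dropout depending on a baseline covariate
  alone cannot bias the marginal complete-case contrast (randomization makes
  arm independent of the covariate). The IPW stress test therefore uses
  dropout depending on arm *and* deprivation jointly — precisely the
  observed attrition pattern — with a deprivation-linked outcome shift, and
  compares IPW against a crude complete-case model omitting the deprivation
  covariate.
* **Positive-control simulations** (sex-restricted effect, weight-change
  interaction) use contrasts chosen a priori to give the detection test
  adequate power (e.g. a 50/50 sex mix rather than the cohort's 85/15,
  which cannot support 80% power at a 0.7-s.d. interaction contrast at
  n = 234).

## Known limitations

* The headline effect estimates of the motivating trial depend on restricted
  participant-level data and are *not* reproducible here; they enter only as
  simulation ground truth.
* The EQ-5D-5L→3L utility crosswalk is not bundled (third-party licensed
  coefficients); utilities are consumed as numbers.
* The mixed model's arm-contrast degrees of freedom use a between-participant
  convention (participants minus fixed effects), not Satterthwaite.
* `simulate_balance` measures marginal (per-level) imbalance only, matching
  the minimization metric; joint (cross-classified) balance is not tracked.
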