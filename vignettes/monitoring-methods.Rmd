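---
title: "Methods: expected treatment response, failure boundaries and CST alerts"
author: "romnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expected treatment response, failure boundaries and CST alerts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romnav)
```

## The problem

A sizeable minority of psychotherapy patients deteriorate or fail to improve,
and therapists are poor at noticing this in time. Routine outcome monitoring
(ROM) addresses this by measuring symptom distress at every session and
comparing each patient's observed course with a statistically *expected*
recovery curve. Patients whose impairment rises above a failure boundary
around that curve are flagged not-on-track (NOT); clinical support tools
(CSTs) then point the therapist at candidate obstacles — suicidality/risk,
motivation, therapeutic alliance, stressful life events, social support and
emotion regulation — via domain and item cut-offs.

`romnav` implements that computational chain end to end: instrument scoring,
the nearest-neighbour expected-trajectory model with a dynamic failure
boundary, the on-track/not-on-track state machine with a reliable-change
return rule, the CST alert logic, and the OT-vs-NOT group statistics.
Because clinical ROM data cannot be redistributed, the package ships a
synthetic-cohort generator that emulates the study design the analyses
assume, so every stage is testable.

## Instruments and cut-offs

* **HSCL-11** — 11 depression/anxiety items on a 0–3 scale, administered
  every session; it is the tracked outcome. The total is scored as the
  **mean** of the items (range 0–3). The instruments' sources do not fix sum
  vs mean for this total; the mean keeps partial batteries comparable and
  keeps the score on the item anchors, so boundaries are interpretable in
  Likert units. Its suicide item (cut-off ≥ 2) feeds the risk domain and the
  immediate red-bar alert.
* **ASC** — four subscales (alliance 11 items, motivation 9, social support
  11, life events 9) on 1–5 anchors, **summed**, with published cut-offs
  TA ≤ 39, MO ≤ 32, SS ≤ 23, LE ≤ 23. The printed cut-offs exceed the item
  range, which is what implies sum scoring. Item cut-off ≤ 2 after recoding.
* **ASQ** — concealing (8), tolerating (5), adjusting (7) on 1–5 anchors,
  scored as **means** (the cut-offs lie inside the item range). Domain
  cut-offs are constructed as archival mean − 1 SD: 3.01 − 0.74 = 2.27,
  2.97 − 0.68 = 2.29, 2.45 − 0.75 = 1.70. The catalog derives them from the
  stored moments at load time, rounded to the printed 2-dp precision at
  which the deployed cut-offs are defined.
* **OQ-30** — only items 5 and 18 enter any computation here (cut-off ≥ 3);
  they back up the risk/suicidality domain between sessions.

Reversal recoding reflects 1–5 items as `6 − v` (an involution; the 0–4
anchor reading was rejected because all battery instruments here use 1–5
anchors). Missing data follow the >80% rule: a scale score is valid only if
more than 80% of its items are observed, in which case missing items are
imputed with the mean of the observed items — which never changes the mean
of the observed items, only rescales sums.

The risk/suicidality *predictor* used in the regressions is the severity
count of risk items at/above cut-off (0–3). The alternative binary
any-item coding is available through the same machinery (`flag`); the count
was chosen as the simplest monotone score since the original coding is not
published. Between batteries the OQ risk items carry forward their last
battery value while the HSCL suicide item refreshes every session.

## The expected-trajectory model and the failure boundary

For a patient at session $s$ with observed HSCL history $y_1,\dots,y_s$, the
engine:

1. **Selects neighbours.** From an archival pool (default 1234 completed
   treatments) restricted to *improving* patients — negative OLS slope of
   impairment on $\ln(\text{session})$, i.e. a successful course — it picks
   the $k = 50$ trajectories minimising the root-mean-square distance to the
   patient's observed values over the jointly observed sessions
   (intake through $s$). Scaling by the number of shared sessions keeps
   early and late queries comparable. Archival patients missing any required
   session are excluded before ranking; ties break by archival id. $k$
   trades bias against variance; 50 out of ~1000 improving candidates keeps
   neighbourhoods local while giving the growth model enough patients, and
   is configurable throughout.
2. **Fits a two-level growth model** on the neighbours' full trajectories:
   $$y_{is} = \beta_0 + \beta_1 \ln s + \beta_2 T_i + \beta_3 \ln(s)\,T_i +
   b_i + \varepsilon_{is},$$
   with random intercepts $b_i$ per neighbour (lme4). If the intercept
   variance is estimated at zero the fit falls back to pooled OLS; if all
   neighbours share one $T$ the rank-deficient $T$ terms are dropped. A
   single-neighbour pool degenerates to that patient's own fitted curve.
3. **Computes the boundary** at $(s, T_q)$, where $T_q$ is the index
   patient's (planned) total session count, falling back to the pool median
   when unknown:
   $$u(s) = \hat y(s) + z_{0.95}\,\mathrm{SE}(s), \qquad
   \mathrm{SE}^2 = x^\top V x + \hat\tau^2 + \hat\sigma^2 .$$
   The "upper limit of the 90% interval" is the one-sided 95% point
   ($z = 1.645$) of a *new-patient prediction* distribution. A mean-only
   confidence band was rejected deliberately: its width shrinks like
   $1/\sqrt{k}$ and would flag nearly every patient; the prediction form
   keeps the boundary anchored to between-patient variability.

The boundary is defined for sessions 6–30 and is recomputed at every
session from the updated history (the fitted model is reused unchanged when
the reselected neighbour set is identical, which is an exact shortcut, not
an approximation).

## The OT/NOT state machine

Before session 6 every patient is on track. From session 6, *surpassing*
the boundary is read strictly (`observed > upper`; ties stay OT) and turns
the state NOT, logging a `went_off_track` signal and recording the
impairment at the first crossing. To return on track the observation must
fall below the boundary **and** the improvement from that first-crossing
level must be reliable in the Jacobson–Truax sense:
$$\mathrm{RCI} = \frac{x_{\text{first crossing}} - x_{\text{now}}}
{SD\sqrt{2}\sqrt{1-\alpha}} \ge 1.96,$$
with the archival intake SD and $\alpha = .87$ (the session-six HSCL-11
reliability). Reliability 1 is rejected (zero denominator). Missing
observations carry the state forward without an event. For group analyses a
patient is NOT if any session in 6–30 was NOT ("ever-NOT"); patients may
toggle NOT→OT→NOT, and every transition stays in the signal log.

## Alert logic

At a battery session, domain inputs are: risk/suicidality — the OR of the
three risk items at their cut-offs; motivation, alliance, life events,
social support — the matching ASC subscale at/below its cut-off; emotion
regulation — **any** of the three ASQ subscales at/below its cut-off (the
domain is reported as one unit, so the OR is the natural aggregation and
can only shrink if a subscale is removed). For OT patients all domains stay
green and no CST is accessible, whatever the cut-offs say. For NOT patients
a domain is orange exactly when its input is crossed, and the critical
items (item cut-offs, recoded) are attached. The suicide red bar (HSCL
item ≥ 2) fires immediately and independently of track status, and is
modelled as a log event, not a domain flag.

The session-6 group comparison pairs session-6 track status with the
battery administered at session 5 — batteries run at sessions 1, 5, 10, …,
so session 5 is the nearest battery at or before the first feedback
session; the pairing rule is configurable (`at_session`).

## Group statistics

* Pearson chi-square on 2×2 crossing tables **without** Yates continuity
  correction — the published statistics reproduce only without it, so the
  correction is not even configurable.
* Student (pooled-variance) t-tests, consistent with pooled-SD Cohen's
  $d = |m_2 - m_1| / s_{\text{pooled}}$, reported as magnitudes. Pairwise
  deletion at item level, listwise (via the >80% rule) at scale level.
* Multilevel logistic regression on the per-session NOT indicator with
  random intercepts for patients and therapists, grand-mean-centered
  continuous predictors, and the latent-scale level-2 ICC
  $\sigma^2_p / (\sigma^2_p + \sigma^2_t + \pi^2/3)$. Model building: an
  intercept-only model, then + session; AIC picks the winner (AIC and BIC
  agreed in the motivating analyses, so AIC is the designated tie-breaker).
  Each domain is then screened in its own model (base + domain) at the
  liberal $p \le .10$; retained domains form the final model. The screen is
  marginal per domain by construction — no joint selection. No
  multiple-testing correction is applied anywhere, matching the reporting
  convention of the design; the test suite asserts this is not silently
  configurable.
* Battery scores are carried forward between battery sessions so every
  session row has predictor values; emotion regulation enters as the mean
  of the three ASQ subscale means (one continuous predictor for one
  reported domain).

## The synthetic-cohort generator

The generator emulates the study conditions: 413 patients, 65 therapists,
an archival pool of 1234, a latent NOT prevalence of 140/413, and
group-specific treatment lengths (truncated normal, OT 24.09 (14.25) vs NOT
32.07 (14.17) sessions, hence a standardized difference of ≈ 0.56).
Trajectories follow the same log-time law the expected-trajectory model
assumes, with therapist, patient and residual components. The study
reports no trajectory variance components, so the defaults
($\sigma_t = 0.07$, $\sigma_p = 0.30$, $\sigma_e = 0.20$ HSCL units,
$\beta_0 = 1.75$, $\beta_1 = -0.30$, $\beta_2 = 0.005$, $\beta_3 = 0.004$)
are free parameters chosen once to give clinically plausible intakes
(~1.8), end-of-treatment change (~0.6 HSCL points) and mostly-improving
archival slopes; they are documented as such and are not tuned thereafter.

Deterioration is modelled as an additive bump on the latent HSCL trajectory
from a random onset (uniform over sessions 4–20), default 0.8 HSCL points =
4 residual SDs — the minimal mechanism that produces boundary crossings.
An onset can fall after a short treatment ends; sensitivity statements
therefore condition on the onset falling inside the classified window.

Battery items are graded discretisations of per-patient latent traits
(loading 0.7). The per-scale locations and the NOT trait shifts were
calibrated once, analytically against the published session-6 crossing
marginals (e.g. risk 26.7% OT vs 38.6% NOT; life events 5.1% vs 14.3%),
and then frozen as defaults. The suicide item is pinned to a ~5% cut-off
rate so the immediate-alert path is exercised. `discretize = FALSE` is a
continuous validation mode in which every HSCL item equals the latent
score, used for noise-free boundary checks.

What the generator does **not** emulate: diagnosis mixtures, informative
dropout beyond group-specific treatment length, item-level local dependence,
battery nonresponse patterns, or therapist drift over time. Passing tests
therefore demonstrate internal correctness of the chain under the assumed
data-generating law, not performance on real clinical data.

## Numerical and design notes

* Battery timing is intake plus every fifth session ({1, 5, 10, …}); the
  session-6 feedback comparison uses the session-5 battery.
* "Positive slope" for pool filtering means symptom *improvement*, i.e. a
  negative OLS coefficient of impairment on $\ln s$.
* Degenerate inputs are legal states, not errors, wherever the monitoring
  flow needs to continue (invalid scale scores surface as missing; empty
  neighbour sets yield undefined boundary rows that carry the track state
  forward).
* With three truly null domains screened at a calibrated 10% level, the
  probability that *no* null domain is retained is about $0.9^3 \approx
  0.73$; retention statements about active domains are therefore made about
  the active set, not about exact recovery of it.
* Simulation problem sizes in the test suite are the package's own choices:
  parameter recovery uses 400 patients × 100 replicates; screening
  calibration and power use 200–300 patients × 50 seeds; end-to-end
  determinism and boundary checks use cohorts of 25–100 patients with pools
  of 150–400. The defaults of `cohort_config()` remain the full study-sized
  conditions.

## Known limitations

* Repeatedly testing a per-session 95% one-sided bound over up to 25
  sessions inflates the ever-crossing rate: with the default generator the
  realized NOT share exceeds the latent prevalence of 0.34. The deployed
  system this models reports its boundary machinery in external technical
  material; where that machinery differs (neighbour features, $k$, interval
  mechanics), this package exposes the corresponding knobs rather than
  guessing fixed truths.
* Published regression coefficients and AIC values from the motivating
  analyses depend on non-deposited patient data; the package validates its
  models by parameter recovery, calibration and qualitative-pattern
  simulations instead of coefficient matching.
* The ASC item layout and reversal key in the shipped catalog are synthetic
  placeholders (the licensed form's layout is not public); swap in the real
  key via `instrument_catalog(path = ...)` for use with actual ASC data.

## A minimal worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_patients = 100, n_therapists = 20, archival_n = 400)
pp <- run_pipeline(cfg, seed = 1, nAGQ = 0)
print(pp)
pp$signal_tests          # session-6 OT/NOT crossing comparison
pp$model_trace           # model-building trace and retained domains
plot(pp$boundaries[[1]]) # one patient's observed course vs boundary
```
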