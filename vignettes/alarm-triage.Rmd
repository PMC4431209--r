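---
title: "Triage of monitor alarms: prediction, dynamic thresholds, majority voting"
author: "vitalsentry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of monitor alarms: prediction, dynamic thresholds, majority voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalsentry)
```

## The model

A monitored patient produces, at each instant $t$, a vector
$A_t = (a_{t,1}, \dots, a_{t,n})$ of physiological parameters — here the
five MIMIC-numerics-style channels ABPmean (mmHg), HR (bpm), Pulse (bpm),
Respiration (breaths/min) and SpO₂ (%). The triage question is whether an
aberrant reading reflects the patient (a true alarm) or the sensor (a false
alarm). The pipeline answers it with three per-instant stages.

**One-step forecasting.** Each parameter is forecast from its own recent
past by ε-insensitive support-vector regression: find
$f(x) = \langle w, x\rangle + b$ minimizing

$$\tfrac12\lVert w\rVert^2 + C\sum_{i}(\xi_i + \xi_i^*)$$

subject to every training target lying within $\varepsilon$ of $f(x_i)$ up
to the slacks $\xi_i, \xi_i^*$. The model is refit each step on a sliding
window of the last $W_p = 30$ values, and predicts only the next instant.
Training residuals smaller than $\varepsilon$ are ignored by design — the
tube absorbs measurement jitter so the fit follows the physiological level,
not the noise.

**Dynamic thresholding.** The anomaly cutoff for a parameter is
$T_d = k \cdot S_d$, where $S_d$ is the sample standard deviation (n−1
denominator) of a sliding window of the last $W_t = 30$ accepted values and
$k = 1$ by default. Because a patient's variability changes over time (and
differs between patients), a threshold tied to the *current* window adapts
where any fixed cutoff $T_f$ — the frozen-initial-window special case,
available as `thresholdMode = "fixed"` — eventually misjudges the scale.
`thresholdModeComparison()` measures this on any labeled stream.

**Majority voting.** At instant $t$, parameter $i$ votes
$v(i) = 1$ iff its native-unit residual $|S_a(t) - S_p(t)|$ *strictly*
exceeds its $T_d$. With $Y = \sum_i v(i)$ over the $n$ parameters that could
vote: $Y = 0$ is `normal`; $Y > n/2$ — a strict majority, the signature of a
physiologically correlated change — is `true_alarm`; any minority, including
an exact tie at even $n$, is `false_alarm`. The tie rule is deliberately
conservative: a split vote is not treated as a medical emergency, it is
treated as suspect instrumentation. Scoring treats the true alarm as the
positive class: $DR = TP/(TP+FN)$, $FPR = FP/(FP+TN)$, and an ROC is traced
by re-running detection with only the first $k$ parameters voting
(`rocSweep()`).

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `predictionWindow` ($W_p$) | 30 | samples | forecaster training window |
| `thresholdWindow` ($W_t$) | 30 | samples | SD window for $T_d$ |
| `detectionWindow` | 80 | samples | reporting batch only; no effect on decisions |
| `kMult` ($k$) | 1 | — | threshold multiplier, $T_d = k S_d$ |
| `cost` ($C$) | 1 | — | SVR regularization |
| `epsilon` ($\varepsilon$) | `0.1 * sd(window)` | native | tube half-width, scale-adaptive so it is meaningful across channels with different units |
| `featureMode` | `"lags"` (order 3) | — | regressors for the SVR |
| `updatePolicy` | `"accept_all"` | — | what enters the sliding windows |

Two of these deserve their rationale spelled out.

**Feature construction.** The SVR can regress the value on the
window-local time index (trend extrapolation) or on its `lagOrder` previous
values. We measured both on the synthetic streams: time-index extrapolation
flags 35–44 % of *normal* instants against the $1\cdot S_d$ threshold —
curvature over a 30-sample window defeats a linear trend — while lagged
features track autocorrelated vitals near their innovation floor (≈1 %
false flags). Lags are therefore the default; `"time_index"` remains
available and is used by the comparison harness when a purely trend-based
baseline is wanted.

**Update policy.** Under `accept_all` the sliding windows always advance on
the sensed values: the forecast is used for anomaly detection only, never to
replace data. The alternative `accept_normal_only` pushes the *predicted*
value whenever a parameter is flagged, which keeps a fault's wild values out
of the windows — but it is self-locking on drifting signals: after one
spurious flag the model stops seeing the patient, its forecasts detach, and
every subsequent instant is flagged. Both policies are implemented;
`accept_all` is the default because value replacement is exactly what this
style of triage sets out to avoid, and because it is robust.

## What the generator emulates — and what it does not

`generateVitals()` models each channel as

$$x_{t,p} = \mu_p + s_p\,(\rho Z_t + \sqrt{1-\rho^2}\,U_{t,p}) + n_{t,p},$$

a baseline $\mu_p$ inside normal adult resting ranges (HR 60–100 bpm,
Respiration 12–20 breaths/min, SpO₂ 95–100 %), a smooth drift of amplitude
$s_p$, and AR(1) observation noise $n_{t,p}$. The drifts $Z$ (shared;
$\rho = 0.7$ couples the channels) and $U_p$ (channel-own) are AR(1) levels
driven by persistent AR(1) velocities, standardized to unit stationary SD —
the simplest process that wanders smoothly the way numerics-rate vitals do,
with the cross-channel coupling the voting stage exploits. SpO₂ is clipped
to $[0, 100]$ and all channels to $\ge 0$.

The defaults (drift SDs 5/4/4/1.5/0.8 native units, noise SDs
0.5/0.35/0.35/0.2/0.12, noise AR coefficient 0.9) were chosen once for
realism: they reproduce the regime in which real numerics sit, where the
one-step prediction error of a good forecaster is a small fraction of a
percent of the signal level — far below the local window SD. That regime is
a *presupposition* of the method, not a convenience: short-term variation
that is white rather than persistent bounds the window-SD-to-innovation
ratio at $1/\sqrt{1-\phi^2}$ during drift stalls, and a $1 \cdot S_d$
threshold then flags normal data at a double-digit rate no matter how small
the noise amplitude is. A monitor whose jitter is genuinely unpredictable
needs $k > 1$.

Events are multiplicative steps $x \mapsto x(1 + d\cdot m)$ at the
conventional magnitudes $m \in \{0.20, 0.30, 0.50\}$: a sensor fault
perturbs exactly one channel, a medical event co-perturbs all five with the
clinical deterioration signature (pressure up; HR, pulse, respiration and
SpO₂ down). A dropout fault is the special case $m = 1, d = -1$. Injected
values are not clipped — the aberrant reading is the point.

What the generator does **not** emulate: waveform-level structure (ECG/PPG
morphology), quantization plateaus, gradual sensor degradation (drifting
bias rather than a step), missingness bursts correlated with patient
movement, and medical events whose channel signature differs from the
deterioration template. Passing the packaged tests therefore demonstrates
that the pipeline recovers step-shaped, correlation-separable anomalies in
smooth streams — it does not certify performance on real ICU archives,
where event shapes and artifact structure are richer.

## Numerical choices and degenerate inputs

- Every window is centered at its mean before the SMO solve. For the linear
  kernel the problem is translation-equivariant and for the RBF kernel
  distance-preserving, so the solution is unchanged, but the solver sees
  well-conditioned values instead of raw vitals near 100 with a tube of
  hundredths.
- A window whose targets are all equal, or whose targets all sit inside the
  ε tube at $w = 0$ (zero support vectors), yields a constant model; in the
  second case the intercept is the midpoint of the feasible band
  $[\max(y)-\varepsilon,\ \min(y)+\varepsilon]$.
- Flagging is strict (`residual > T_d`): a zero-variance window gives
  $T_d = 0$ and flags any nonzero residual; exact ties are not flagged.
- Division guards: the percentage error is stored as missing when
  $S_a = 0$ (a real monitor can emit SpO₂ = 0), and DR/FPR are reported
  missing with a warning when their denominators are empty — never a silent
  0/0.
- Missing readings never enter windows and never vote: the parameter
  abstains, and $n$ for the majority rule is the count of non-abstaining
  parameters at that instant. Decisions are skipped (and recorded) only if
  every parameter abstains.
- All indices are 1-based, R's convention, including event windows and the
  `t` column of decisions.

## Problem sizes

The packaged test suite and the acceptance script run entirely on generated
data: benchmarks of 600 instants × 5 parameters (15 events), shorter
120–400-sample fixtures for unit tests, and 100 forecasts per parameter for
the predictor comparison. One 600-sample pipeline pass refits ≈2 850
30-sample SVRs and completes in a few seconds on one core; these sizes give
every stage at least an order of magnitude more normal data than event data,
which is the regime the scoring assumes.

## Known limitations

- The ROC has few operating points: only $k$ (parameters voting) is swept,
  as the threshold's own scale is held at $k_{mult} = 1$ per the method; a
  finer curve would sweep `kMult`.
- Event-level scoring counts each planted event once; instant-level scoring
  is available (`mode = "instant"`) but normal instants are outside both
  alarm classes and are not scored.
- The forecaster comparison fixes the Gaussian-process kernel width by a
  deterministic plug-in rule rather than marginal-likelihood optimization;
  it is a baseline, not a tuned competitor.
- `accept_normal_only` should only be used on short horizons or with
  `kMult` well above 1; see the update-policy discussion above.
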