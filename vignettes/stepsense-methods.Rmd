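---
title: "Measuring sensorimotor uncertainty in stepping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sensorimotor uncertainty in stepping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepsense)
library(dplyr)
```

## The paradigm and the generative model

stepsense analyses a virtual-reality stepping task in which a cursor driven
by the participant's centre of mass must be stepped into a target, while an
unseen backward radial shift $s$ — drawn fresh each trial from
$N(\mu_s, \sigma_s^2)$, by default $N(-7.5\,\mathrm{cm}, 2.5^2)$ — is added
to the cursor. The participant sees the shifted cursor only briefly
mid-movement, so the final placement must combine that noisy glimpse with
the expectation of the shift learned over preceding trials. This is the
classic cue-combination setting: a Gaussian prior over the shift and a
Gaussian likelihood from vision.

The package's ideal observer (`observer_params()`) formalises one
participant-visit with four noise quantities, all in centimetres:

* $\sigma_s$ — SD of the true shift distribution (the task);
* $\sigma_b$ — SD of the observer's *believed* prior (defaults to
  $\sigma_s$: learning has converged during the training block);
* $\sigma_v$ — SD of the noise on the brief visual feedback;
* $\sigma_m$ — SD of execution (motor) noise added to the landing position.

On each trial the observer receives $s + e_v$, $e_v \sim N(0, \sigma_v^2)$,
and forms the posterior-mean estimate
$\hat{s} = w\,\mu_b + (1 - w)(s + e_v)$ with prior weight

$$ w = \frac{\sigma_v^2}{\sigma_v^2 + \sigma_b^2}. $$

It compensates by stepping $-\hat{s}$ beyond the target, so the recorded
radial deviation is

$$ y = s - \hat{s} + e_m = w\,(s - \mu_b) - (1 - w)\,e_v + e_m. $$

Regressing $y$ on $s$ across trials therefore has population slope $w$
(how strongly the learned expectation pulls responses) and residual
root-mean-square

$$ \mathrm{RMSE} = \sqrt{(1 - w)^2 \sigma_v^2 + \sigma_m^2}, $$

which is the behavioural uncertainty metric: the spread of the nervous
system's position estimates that survives after the linear effect of the
shift is accounted for. `expected_regression()` returns these closed forms;
`fit_deviation_regression()` recovers them empirically (tests verify
agreement within Monte-Carlo error on $10^5$-trial simulations).

Two consequences of the algebra matter for interpretation:

* With $\sigma_m = 0$ the RMSE equals
  $\sigma_v \sigma_b^2 / (\sigma_v^2 + \sigma_b^2) \le \sigma_b / 2$.
  With $\sigma_b = 2.5$ cm, visual noise alone can never push the RMSE past
  1.25 cm; observed uncertainties of 2–3 cm *require* motor noise. The
  default observer therefore carries $\sigma_m > 0$.
* The believed prior mean enters only the intercept ($-w\,\mu_b$), so slope
  and RMSE are insensitive to a miscalibrated prior mean — a useful
  robustness property of the statistic.

The inverse mapping `recover_sensory_noise()` reads
$\sigma_v = \sigma_b \sqrt{w / (1 - w)}$ off the slope and attributes the
remaining residual variance to $\sigma_m$, clamping at zero (with a flag)
when a sampled RMSE falls below the visual floor. It requires
$0 < w < 1$; slopes at or outside those ends carry no information about
$\sigma_v$.

## The synthetic crossover cohort

`simulate_cohort()` emulates the study design end to end: three groups of
10 participants (NN never stimulated, NT stimulated on visit 2, TN
stimulated on visit 1), two visits, five assessment blocks of 100 trials.
Participant baselines for $(\sigma_v, \sigma_m)$ are drawn once per
participant from lognormal distributions (mean = the design baseline,
SD = the between-participant SD, 0.4 cm each by default), keeping noise
SDs positive. Three additive reductions then encode the study's effect
structure:

| parameter | default | meaning |
|---|---|---|
| `tens_effect` | 0.3 cm | noise reduction while stimulation is on |
| `visit_effect` | 0.3 cm | practice-related reduction on visit 2 |
| `retention_effect` | 0.4 cm | extra visit-2 reduction for TN only (the benefit of having *learned* the task under stimulation is retained) |

By default the reductions act on both $\sigma_v$ and $\sigma_m$
(`effect_target = "both"`). This is a deliberate design choice: the
residual-SD bound above means adjustments to $\sigma_v$ alone can move the
expected RMSE by at most a few tenths of a centimetre at these magnitudes,
far less than the spread the group-by-visit cells must cover. Restricting
the effects to one noise source (`"visual"` or `"motor"`) remains available
for sensitivity analyses of the interpretation that stimulation acts on
sensory noise specifically.

The defaults were calibrated once, from the closed-form expected RMSE, so
that the six expected group-by-visit cell means are 2.68 (unstimulated
visit 1), 2.41 (TN visit 1 and NN visit 2), 2.14 (NT visit 2) and 2.04 cm
(TN visit 2) — the ordering and approximate magnitudes of the uncertainty
cells the paradigm is designed to exhibit: both stimulated groups improve
across visits by more than the control does, and TN retains its advantage.
What passing simulations show is that the *pipeline* detects effects of
this structure and size; they are silent about human data, which the
generator does not claim to reproduce (no trial-order learning dynamics,
no direction-specific biases, no session fatigue).

## Balance traces and virtual time-to-contact

The balance assessment stands a participant on a force plate under four
sensory conditions (rigid/compliant surface × eyes open/closed) for 30 s.
`simulate_cop()` generates centre-of-pressure sway as independent
Ornstein–Uhlenbeck processes per axis (time constant 1 s), zero-phase
low-pass filtered at 2 Hz to confine the trace to the slow physiological
sway band, centred, and rescaled so the radial RMS equals the condition's
`sway_scale` (defaults 0.9, 1.2, 1.3, 2.0 cm — non-decreasing across
conditions, with conditions 2 and 3 nearly tied, the pattern balance
batteries typically show). Traces are redrawn if any sample would leave
the base of support. Sampling is 25 Hz, typical of portable plates.

Virtual time-to-contact (VTC) asks, for every sample: projected
ballistically from its instantaneous position, velocity and acceleration,

$$ p(\tau) = p + v\,\tau + \tfrac{1}{2} a\,\tau^2, $$

how long until the centre of pressure reaches the boundary of the base of
support? Larger values mean greater stability. The pipeline is:

1. centre the trace on its mean CoP (the boundary is anchored there);
2. zero-phase 4th-order-effective Butterworth low-pass at 10 Hz
   (`preprocess_cop()`) — double differentiation amplifies noise, so
   filtering precedes it;
3. central finite differences for velocity and acceleration
   (`cop_kinematics()`);
4. for each sample, find the smallest $\tau > 0$ at which the projected
   path crosses the boundary (`contact_time()`).

The boundary is an ellipse by default — semi-axes 5 cm (medio-lateral) and
12 cm (antero-posterior), a feet-together stance of half stance width and
half foot length — with convex polygons supported; both are exposed in the
configuration because the geometry is a modelling choice, not a measured
quantity. The crossing is found by scanning a dense grid
($\tau_{max}/2000$ steps) for the first sign change of the signed boundary
function and refining by bisection to $10^{-6}$ s; tests verify agreement
with the closed-form conic intersection to $10^{-5}$ s for
zero-acceleration states. The projection is along the instantaneous
trajectory, matching the question "how long until the CoP *gets* there",
rather than a minimum over boundary points. Paths that never cross within
the horizon $\tau_{max} = 10$ s are capped there and flagged;
`mean_vtc()` includes capped samples by default (a capped sample is
evidence of stability, and excluding it would bias the trial mean
downward) and always reports the capped fraction so the policy's reach is
visible.

## The inferential layer

The uncertainty analysis unit is the participant-visit-*block* regression
(five RMSE values per visit), so each participant contributes repeated
observations and the group-by-visit analysis is fit as a linear mixed
model, `rmse ~ group * visit + (1 | participant_id)`, with Type III F
tests and Satterthwaite denominator degrees of freedom
(`fit_rm_anova()`). Per-visit pooling is available by flag. On balanced
one-observation-per-cell data the mixed model reproduces the classical
repeated-measures sums-of-squares decomposition exactly; the test suite
asserts this against an independently coded oracle. Pairwise follow-ups
use Tukey's honest significant difference on estimated marginal means
(`tukey_pairwise()`), verified in tests against direct studentized-range
evaluation.

Two planned contrasts target the stimulation effect specifically:

* **Visit 1 only** (`tens_contrast_visit1()`):
  $(\bar{\mu}_{NT1} + \bar{\mu}_{NN1})/2 - \bar{\mu}_{TN1}$ — on visit 1
  the TN group is the only stimulated one, so the average of the two
  unstimulated cells minus the stimulated cell estimates the concurrent
  effect.
* **Difference in differences** (`tens_contrast_crossover()`):
  $(\bar{\mu}_{NT1} - \bar{\mu}_{NT2}) - (\bar{\mu}_{NN1} - \bar{\mu}_{NN2})$
  — NN's across-visit change estimates the practice effect, NT's change
  estimates practice plus stimulation, and subtracting isolates the
  stimulation component.

Both are reported unadjusted for multiplicity, as single planned
contrasts; with a fitted model the SE, Wald 95% CI and p value come from
the model's marginal-mean covariance, and in balanced designs the
model-based estimate equals the raw cell-mean arithmetic (asserted to
1e-10 in tests). Effect sizes use the pooled-SD two-cell Cohen's d; note
that repeated-measures d variants standardised by the within-participant
change SD give systematically larger values when visits correlate
positively, so pooled-SD d values are not comparable to those without
knowing the correlation.

The balance analysis mirrors the design's second question with
`mean_vtc ~ tens * condition + (1 | participant_id)` over the four
conditions (`balance_anova()`), with condition-wise Tukey follow-ups.

## Numerical and design choices

* **RMSE denominator** is $n$ (literal root *mean* squared error), not
  $n - 2$; at 100-trial blocks the difference is under 1%, and it is
  documented at the API.
* **No outlier trimming** is applied to trials; the regression consumes
  every assessment trial, and the five target directions are pooled (the
  statistic is radial-scalar; direction is bookkeeping).
* **Filter implementation**: forward–backward `signal::butter(2)` with
  odd-symmetric end reflection, so constants and slow trends pass without
  end transients; with the 10 Hz cutoff, attenuation is <1% at 1 Hz and
  >95% at 20 Hz, verified in tests.
* **Degenerate inputs** are typed errors, not NAs: constant shifts
  (no regression), fewer than 3 trials, slopes outside $(0,1)$ at
  inversion, CoP states outside the boundary, empty means under
  `exclude_capped`.
* **Determinism**: the cohort and sway generators are pure functions of
  their seeds and restore the caller's RNG state; the pipeline writes its
  resolved configuration next to its outputs.

## Problem sizes used in the shipped checks

The test suite exercises the Monte-Carlo claims at the sizes the analysis
is designed around: $10^5$-trial regressions for closed-form agreement
(10 noise settings), 20 participant-visits at 500 and $10^5$ trials for
noise recovery, 500 reduced null cohorts (5 participants per group, one
block) for the type-I error of the interaction test, 20 seeded cohorts at
the full default design for the sign of the crossover contrast, and 20
seeded balance cohorts of 12 stances per condition for the VTC ordering.
These sizes were chosen to make the sampling error of each check small
relative to its tolerance.

## Known limitations

* The observer is static within a visit: no trial-by-trial prior updating
  and no learning curve across the training block. The belief parameters
  can be set off-truth for sensitivity studies, but their dynamics are out
  of scope.
* The sway model is a filtered stationary OU process: it reproduces
  amplitude, smoothness and boundedness, not the intermittent corrective
  dynamics or drift of real posturography, so VTC comparisons across its
  conditions validate the computation and ordering, not physiological
  magnitudes.
* The base-of-support geometry is configuration, not measurement; absolute
  VTC values scale with it and should only be compared within a fixed
  boundary.
* Mixed-model denominator df use the Satterthwaite approximation;
  containment-style df from other software will differ on unbalanced
  data.
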