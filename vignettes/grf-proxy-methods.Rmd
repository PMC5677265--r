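---
title: "Methods: proxy measurement of vertical ground reaction forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proxy measurement of vertical ground reaction forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grfproxy)
```

## The problem and the model

During walking, the vertical ground reaction force (vGRF) under each foot
traces an M-shaped curve per stance: a loading peak (VP1), a mid-stance
trough (TR), and a push-off peak (VP2). `grfproxy` reconstructs both feet's
vGRF from a single trunk-worn 3-axis accelerometer, after a calibration
recording in which reference vGRF (e.g. pressure insoles) is available to
identify a subject-specific model.

The pipeline has three stages.

**1. Membership decomposition.** One sensor serves two feet, so each
acceleration axis is split into a left and a right component by
complementary weights in \[0, 1\]. The *exact* weights are the per-foot
force shares `w_left = GRF_left / (GRF_left + GRF_right)`; at prediction
time, when no force is available, they are approximated from gait events
alone: 1 during the foot's single support, 0 during its swing, and linear
ramps across each double support. Initial contact (IC) and final contact
(FC) are detected from the reference vGRF as crossings of a 10 N threshold.
The decomposition conserves the signal exactly
(`a_left + a_right = a` per axis) and the two constructions agree everywhere
outside double support.

**2. Nonlinear moving-average (Volterra) model.** Each foot's force is a
multivariate polynomial in current and lagged decomposed channels:

$$ \mathrm{vGRF}(k) \;=\; \sum_i \theta_i\,\varphi_i\!\big(u(k),\dots,u(k-L)\big), $$

where the $\varphi_i$ are monomials of total degree at most 2 over the six
channels $\{a_x,a_y,a_z\}\times\{\text{left},\text{right}\}$ and lags
$0..L$. No output or noise terms enter the model: prediction is a pure
feed-forward map of the inputs, so errors never accumulate through
feedback. With $m$ lagged variables the candidate dictionary holds
$1 + m + m(m+1)/2$ terms; at the defaults (6 channels, $L = 18$) that is
$m = 114$ and 6670 candidates.

**3. Structure selection by orthogonal forward regression.** FROLS ranks
candidates by the error reduction ratio
$\mathrm{ERR}_i = g_i^2\,\langle w_i, w_i\rangle / \langle y, y\rangle$,
the fraction of target energy explained by the candidate after
orthogonalization against the already-selected terms, and admits the best
term until the stopping rule fires. The *iterative* OFR then re-runs the
selection once per selected term with that term forced first and accepts
the minimal-RSS model of equal size when strictly better; restarting from a
different first term is what lets the search escape a misleading early pick
among correlated candidates. Published descriptions of the iterative scheme
differ in scheduling detail; the forced-first-restart variant with
best-RSS acceptance implemented here is documented as this package's
interpretation, and its guarantee — never worse than plain greedy selection
— is enforced by construction and by test.

## Accuracy analysis

Predictions are compared with the reference per gait cycle (IC-to-IC of the
same foot). Errors are RMSE (N) and relative RMSE — RMSE over the mean of
the two signals' peak-to-peak amplitudes, in percent — for the full cycle,
the foot's single-support samples, the double-support samples, and the
three critical points. The critical-point reduction is an interpretation
choice: VP1/TR/VP2 are extracted independently from the reference and the
predicted curve of each cycle (within the reference stance window, so
swing-phase prediction ripple cannot pose as a peak), the per-cycle
absolute differences are normalized by the same peak-to-peak denominator as
the cycle's other errors, and aggregates are mean ± SD over cycles. If
extraction from a predicted cycle is degenerate (fewer than two local
maxima), the predicted value at the reference critical index is used and
the cycle is counted in `n_degenerate`. The correlation coefficient ρ is
computed over all cycle-covered test samples; samples outside the
segmented cycles (e.g. transitory stretches at the recording edges) never
enter any metric. Group comparisons (tasks, sensor locations, subjects) use
the two-sided pooled-variance Student's t-test.

Two diagnostics support model-class choices: a normalized input–output
cross-correlation over lags 0..L, returning the smallest window containing
95 % of the significant squared-correlation mass (used to justify the
default L = 18); and a higher-order correlation test that fits the best
linear-in-lags model and cross-correlates squared centred input with the
residuals — excursions beyond the ±1.96/√N band indicate structure a linear
model cannot capture. The band is per lag; across many lags the any-lag
verdict is deliberately liberal, as is conventional for these model
validity traces.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `event_threshold` | 10 N | force level defining IC/FC crossings |
| `min_phase` | 0.1 s | debounce guard: shorter stance/swing runs are chatter |
| `max_lag` | 18 samples | dictionary memory at 128 Hz (~140 ms) |
| `degree` | 2 | polynomial order of the dictionary (1 or 2) |
| `n_terms` | 64 | fixed model size of the default stopping rule |
| `iofr_iterations` | 1 | restart sweeps of the iterative refinement |
| `rrmse_scope` | "cycle" | peak-to-peak normalization per cycle or global |

The stopping rule also offers an unexplained-energy threshold
(`err_threshold`, used with tolerance ~1e-12 for exact-recovery analyses)
and a BIC-like penalized mode, since a fixed 64-term budget is a
convention, not a derived optimum. Whether the relative error should be
normalized per cycle or by the whole validation segment's range is
underdetermined; per-cycle is the default and both are exposed.

## The synthetic generator

Real calibration data are subject-specific recordings that cannot ship with
a package, so every analysis here runs on seeded synthetic data with the
statistical structure the method assumes.

**Biomechanical mode.** Per-stance vGRF is a smooth M-curve through the
three critical-point amplitudes: a quarter-sine rise to VP1 at 25 % of
stance (nonzero contact slope, so threshold crossings are sharp),
raised-cosine segments through TR at 50 % and VP2 at 75 %, and a
quarter-cosine fall to zero. Defaults — 1.1 s cycles, stance fraction 0.62,
double-support fraction 0.10, 700 N body weight, peaks 770/750 N, trough
525 N, 128 Hz — are typical adult walking values. Both feet share the cycle
period; the contralateral IC is offset by (stance − double-support)
fractions of a cycle so the double support following each contralateral IC
lasts exactly the configured fraction (its mirror-image companion then
lasts `2·stance − ds − 1`, slightly asymmetric — the price of keeping both
timing parameters independent). Per-stance Gaussian timing and relative
amplitude jitter model stride variability; additive white Gaussian noise
applies to the *acceleration channels only*, never to the reference vGRF,
which keeps swing samples exactly zero and forces nonnegative.

The acceleration coupling is a fixed, documented causal map chosen so the
inverse lies inside the degree-2 NMA class: `ax` is the total-force
fluctuation about body weight through a 3-tap exponential kernel
(1, ρ, ρ², ρ = 0.4), whose inverse decays geometrically and is negligible
beyond lag 18; `az` carries a gravity offset plus a small stride harmonic,
so its decomposed components approximately encode the membership weight
itself; `ay` is a stride harmonic. This guarantees the end-to-end accuracy
regime is attainable by construction. What the generator does **not**
emulate: soft-tissue artefact, turning and terrain effects, sensor drift or
misalignment, running (flight phases are rejected as unsupported), or
inter-subject anatomy. Passing the synthetic benchmark therefore
demonstrates that the pipeline's machinery is correct and well-conditioned
at realistic signal scales — not that any particular accuracy will be met
on a given subject's field recording.

**Oracle mode.** The six decomposed channels are drawn directly as white
noise gated by alternating stance-like windows (bypassing the circularity
that membership needs forces), and outputs are computed exactly from a
known sparse polynomial. This supports exact tests: structure recovery must
return precisely the generating support, coefficients to 1e-8, and the ERR
sum must close to 1 within 1e-9 on noiseless data.

## Numerical choices

* Orthogonalization is modified Gram–Schmidt realized in its inner-product
  (fast FROLS) form: per step one product of the design with the new
  orthonormal direction; candidate residual norms and target correlations
  are downdated, and the admitted column is explicitly re-orthogonalized
  once so the retained basis stays orthonormal to machine precision.
* Candidates whose orthogonalized relative norm falls below 1e-10 are
  skipped as degenerate; if nothing selectable remains the result carries a
  truncation flag. ERR ties break toward the lowest column index.
* Final coefficients come from back-substitution and are verified (in
  tests) against direct least squares on the selected support to 1e-8
  relative; the reported RSS is recomputed from the residual, not from the
  downdated running value.
* The iterative refinement accepts a candidate only if its RSS improves on
  the incumbent by more than 1e-12 of the target energy, so machine-noise
  differences between already-perfect fits cannot cycle.
* Indices are 0-based and intervals half-open (`[IC, FC)` stance,
  IC-to-IC cycles); membership ramps run from 1 at the contralateral-IC
  sample to 0 at the last double-support sample, evaluated at integer
  samples (a one-sample double support takes the ramp's end value).
* Exact membership is undefined where both forces are zero; the last
  defined value is carried forward (0.5 before any defined sample).
* Design-matrix rows start at `k = max_lag`: no pre-recording samples are
  fabricated, and the first `max_lag` predictions are `NA`. Evaluation
  excludes them.
* The printed size of the paper-scale dictionary follows the closed form
  `1 + m + m(m+1)/2`; counts under other conventions are reported as
  configuration, not asserted.

## Problem sizes used in the shipped analyses

The synthetic half-split benchmark uses 110 gait cycles (~15,500 samples at
128 Hz), the default 64-term, lag-18, degree-2 configuration, and the
greedy selection stage (`iofr_iterations = 0`): with 6670 candidates the
restart sweep multiplies cost by the model size while the greedy stage
already reaches the benchmark's accuracy regime, so the refinement is
exercised instead on the dictionary-scale structure-recovery and
greedy-adverse analyses, where its effect is decisive and exhaustively
checkable. Oracle recovery runs at N = 500 over the full 6670-term
dictionary; the greedy-adverse comparison uses 20 seeded 10-candidate
problems against exhaustive best-subset enumeration.

## Known limitations

* The model is subject- and placement-specific; nothing here addresses
  transfer across subjects or sensor sites beyond re-running the pipeline
  per channel set.
* Event-based membership needs gait events at prediction time — from any
  source (the reference here; IMU-based detectors in deployment) — and
  assumes walking: simultaneous flight of both feet is rejected.
* Degree-3+ nonlinearities, output-feedback (full NARMAX) terms, noise-model
  estimation, and the mediolateral/anterior–posterior force components are
  out of scope.
* The critical-point error definition, the membership ramp endpoints, and
  the per-cycle rRMSE normalization are documented interpretations of
  underdetermined conventions; alternatives are exposed through
  configuration where they matter.
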