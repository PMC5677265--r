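# grfproxy

Proxy measurement of bilateral vertical ground reaction forces (vGRF) from a
single 3-axis accelerometer.

Measuring the force each foot exerts on the ground normally requires force
plates or pressure insoles — equipment that is expensive, fragile, or
impractical outside the lab. `grfproxy` implements a proxy-measurement
pipeline for gait analysts and wearable-sensor researchers: after a short
calibration session in which a trunk-worn accelerometer is recorded alongside
reference insoles, the per-foot vGRF can be reconstructed from the
accelerometer alone, sample by sample, during ordinary walking.

## The model

Walking is periodic and both feet load the same shared sensor, so the first
step splits each acceleration axis *a* into left- and right-foot components
with a pair of membership weights

    w_left(k) = GRF_left(k) / (GRF_left(k) + GRF_right(k)),   w_right = 1 − w_left
    a_left = a · w_left,   a_right = a · w_right   (pointwise),

approximated at prediction time from gait events only (weight 1 in single
support, 0 in swing, linear ramps across double support). Initial and final
contacts are detected from the reference vGRF with a 10 N threshold.

Each foot's force is then modelled as a polynomial **nonlinear moving-average
(Volterra) model** — a NARMAX model restricted to input terms only, so
prediction never feeds back its own output and errors cannot accumulate:

    vGRF(k) = Σ_i θ_i φ_i( u(k), u(k−1), …, u(k−L) ),

where the `φ_i` are monomials of total degree ≤ 2 in the six decomposed
channels `{ax,ay,az} × {left,right}` at lags `0..L` (default `L = 18` at
128 Hz; 6670 candidate terms). The sparse structure is selected by
**orthogonal forward regression** (FROLS): candidates are orthogonalized
against the selected set and ranked by the error reduction ratio

    ERR_i = g_i² ⟨w_i, w_i⟩ / ⟨y, y⟩,

the fraction of target energy a term explains. An **iterative OFR** restarts
the selection once per selected term (that term forced first) and keeps the
best equal-size model, escaping greedy suboptima. Accuracy is reported per
gait cycle as RMSE and relative RMSE (RMSE over the mean peak-to-peak
amplitude, in %), split by full cycle, single support, double support and
the three stance critical points (peaks VP1/VP2, trough TR), with
pooled-variance t-tests for group comparisons.

A seeded synthetic-gait generator makes the whole pipeline testable without
recordings: a biomechanically shaped mode (M-shaped stance profiles,
configurable timing/amplitude jitter and sensor noise, acceleration channels
causally coupled to the force) and an oracle mode (known NMA model, for
exact structure/parameter recovery tests).

## Worked example

```r
library(grfproxy)

params <- gait_params(timing_jitter_sd = 0.01, amplitude_jitter_sd = 0.03)
rec <- generate_biomech_recording(params, n_cycles = 40, seed = 1)
rec
#> # gait recording: 5632 samples at 128 Hz (with reference vGRF)
#> # A tibble: 5,632 × 6
#>       k     ax     ay    az grf_left grf_right
#>   <int>  <dbl>  <dbl> <dbl>    <dbl>     <dbl>
#> 1     0 -0.937 0       9.81     43.8         0
#> 2     1 -1.23  0.0112  9.82     98.1         0
#> 3     2 -1.28  0.0223  9.83    152.          0

halves <- split_half(rec)
fit <- fit_proxy(halves$train,
                 proxy_config(stop = stopping_rule("fixed_terms", 16),
                              iofr_iterations = 0))
fit
#> # proxy fit: 16-term left / 16-term right NMA models (max lag 18, degree 2)
#> #   sum ERR: left 0.9979, right 0.9978

head(tidy(fit$left), 3)[, 1:4]
#>    term label         estimate    err
#> 1    78 az_left(k)        131. 0.933
#> 2     2 ax_left(k)       -206. 0.0248
#> 3  4554 ay_left(k-11)*az_left(k-1) 197. 0.0277

ev <- evaluate_proxy(fit, halves$test)
tidy(ev$left)
#> # A tibble: 6 × 5
#>   phase  rmse_mean rmse_sd rrmse_mean rrmse_sd
#> 1 full        14.9    3.60       1.91    0.439
#> 2 single      14.4    3.84       1.84    0.461
#> 3 double      24.3    6.62       3.12    0.833
#> 4 vp1         18.0   18.5        2.33    2.42
#> 5 vp2         17.5   20.7        2.26    2.71
#> 6 tr          10.2    6.19       1.31    0.788

glance(ev)
#> # A tibble: 2 × 5
#>   foot    rho n_cycles n_degenerate rrmse_full_mean
#> 1 left  0.999       19            0            1.91
#> 2 right 0.998       18            1            2.45
```

Read the `tidy(ev$left)` table as the per-phase error profile of the
held-out half: the 16-term model reconstructs the left-foot force with a
mean per-cycle error of 14.9 N — 1.91 % of the signal's peak-to-peak
amplitude — with the double-support phase hardest (3.1 %), and per-cycle
peak/trough amplitudes recovered within ~2 %. `rho` is the correlation
between predicted and reference force over the whole test segment;
`autoplot(ev)` overlays the two traces.

A command-line front end wrapping the same functions ships in
`inst/cli/grfproxy.R` (`simulate`, `fit`, `predict`, `evaluate`
subcommands; see its header for the YAML config layout).

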