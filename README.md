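# pcwaves

Hierarchical predictive coding with communication delays: alpha-band
oscillations, perceptual echoes, and forward/backward traveling-wave
analysis of multichannel recordings.

## The science

In a predictive-coding hierarchy, each level L holds a prediction
`y_L(t)` of the activity below it and receives the unexplained residual
(prediction error) from below:

```
x_L(t)    = y_{L-1}(t) - y_L(t - ΔT)                       (residual)
dy_L/dt   = x_L(t - ΔT)/τ + (y_{L+1}(t - ΔT) - y_L(t))/τ_D (prediction)
```

with `y_0 = INPUT(t)` the sensory drive, `y_{N+1}` an optional top-down
prior, `ΔT` the inter-level communication delay, `τ` the neuronal
integration time constant, and `τ_D` a slower decay/top-down constant.
The delayed negative-feedback loop makes the circuit ring: a purely
oscillatory solution of the reduced equation `dy/dt = -y(t - 2ΔT)/τ`
exists when `τ = (4/π)·ΔT ≈ 1.27·ΔT`, with period exactly `8·ΔT` — in
the alpha band (8–13 Hz) for physiological delays of 10–15 ms.

Stacked into a hierarchy and driven by white noise, the same circuit
produces *traveling* alpha waves: forward (low → high levels) under
sensory input, backward under a top-down prior. The package quantifies
them with the 2D-FFT quadrant statistic: stack an ordered channel set
into a channels × time map, take the 2D FFT amplitude, extract the
maximum in the forward and backward quadrants, and form
`log_ratio = log(max_FW / max_BW)` (positive = forward). Significance
comes from a channel-order shuffle surrogate null; wave speed from the
dominant off-axis spectral peak. All of this applies equally to plain
multichannel matrices (e.g. an Oz…Fz electrode line), so real recordings
can be analysed with the same functions.

## Worked example

```r
library(pcwaves)

# the delay sets the rhythm: closed forms
oscillation_frequency(12)   # 10.41667 Hz  (period = 8 * 12 ms)
optimal_tau(12)             # 15.27887 ms  (= 1.2732 * 12)

# a 7-level model driven by white-noise input, analysed end to end
rep <- wave_report(pc_config(n_levels = 7, delta_t = 12, tau = 20,
                             tau_d = 200),
                   drive = "input", n_trials = 20, duration_s = 6,
                   seed = 1, n_shuffles = 500)
glance(rep)
#> # A tibble: 2 × 8
#>   drive path  n_epochs n_shuffles fw_significant_pct bw_significant_pct  ks_d     ks_p
#>   <chr> <chr>    <int>      <dbl>              <dbl>              <dbl> <dbl>    <dbl>
#> 1 input irf         20        500               99.2                  0 0.988 1.11e-16
#> 2 input eeg        220        500               83.3                  0 0.837 0
```

The IRF rows are per-trial maps of each level's cross-correlation with
the stimulus (the "perceptual echo", which reverberates at ~10 Hz); the
EEG rows are 1-s sliding windows of the raw prediction signals.
`fw_significant_pct` is the share of epochs whose forward log ratio
exceeds what channel-shuffled surrogates produce; `ks_d` the
Kolmogorov–Smirnov distance between the real and surrogate log-ratio
distributions. Under an input drive essentially all wave evidence is
forward; swap `drive = "prior"` and it reverses.

```r
# wave speed: ~0.6-0.7 m/s at 2-cm level spacing, several-fold faster
# after scalp-style source mixing at 4-cm spacing
rep <- wave_report(pc_config(), "input", n_trials = 20, duration_s = 6,
                   seed = 1, n_shuffles = 500, keep_maps = TRUE)
speed_summary(rep$eeg_maps, spacing_m = 0.02)
#>   mean_speed_m_s median_speed_m_s n_maps spacing_m mixed
#> 1          0.720              0.7    220      0.02 FALSE
speed_summary(rep$eeg_maps, spacing_m = 0.04, mix = TRUE)
#>   mean_speed_m_s median_speed_m_s n_maps spacing_m mixed
#> 1           2.65             2.52    220      0.04 TRUE
```

A thin command-line wrapper lives at `inst/cli/pcwaves`
(`simulate`, `analytics`, `waves`, `synth`, `report` subcommands).

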