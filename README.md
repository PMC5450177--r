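# ecgwave

Single-lead ECG analysis for people who need both *where* the beats are
and *what the myocardium was doing*: `ecgwave` detects QRS complexes and
T waves from discrete-wavelet subbands chosen by a principled frequency
scheduler, assembles per-beat eigenvalues, and inverts a scaled
epicardial action-potential model to estimate the time-scale and
amplitude factors used to flag myocardial ischemia and heart failure.
It is aimed at biomedical-signal researchers and method developers; it
is not a clinical device.

## The method

**Subband scheduling.** One level of orthogonal wavelet decomposition
splits a band `[0, f_s/2]` into an approximation (low-pass) and a detail
(high-pass) half, each downsampled by 2, which doubles a band's
normalized center frequency `c0 = f_center / f_s`. The scheduler picks
the smallest level `l >= 1` minimizing `|2^l c0 - 0.5|` subject to
`2^l c0 <= 0.75`, i.e. the depth at which the target band sits in the
middle of a detail branch. For a 200 Hz record this places the QRS band
(10–20 Hz, `c0 = 0.075`) in the level-3 detail branch and the T band
(3–8 Hz, `c0 = 0.0275`) in the level-4 branch with mapped center 0.44.

**Localization.** The extracted coefficients `chi(t)` are reduced to a
trailing windowed energy `E(t) = sum_{j=0}^{L} chi^2(t-j)` and binarized
by an adaptive threshold: `Z(t) = 1` iff `E(t) >= M^2`, with
`M^2 <- M^2 (1 - lambda) + lambda E(t)` on every trigger
(`lambda <= 0.25`). Run midpoints, mapped back through the decimation
and filter delay, localize the R and T peaks; amplitudes are read from
the baseline-corrected signal.

**Inverse AP fit.** With standard left/right epicardial templates
`C_L`, `C_R` (rest 0, peak 1), the model
`F(t; k, h) = h C(k t)` scales time by `k` and amplitude by `h`. Per
beat, the T amplitude and the energy integral satisfy

    T_i     = h_R C_R(k lat_i) - h_L C_L(k lat_i),   lat_i = t_T - t_R
    Delta_i = (h_R Phi_R - h_L Phi_L) / k,           Phi = integral of C

and `(k, h_R, h_L)` are estimated by iterated least squares (a profiled
joint solve plus alternating refinement). The decision rule is on the
time scale alone: `k < 0.9` flags myocardial ischemia, `k > 1.2` heart
failure; reduced `h_R`/`h_L` are reported as advisory flags.

## Worked example

```r
library(ecgwave)

plan_subband(ecg_band(3, 8, 200))
#> <subband_plan> 3-8 Hz @ fs 200: level 4 (detail), mapped center 0.44

# a 40 s record driven by scaled AP templates with known parameters
rec <- generate_from_ap(list(k = 0.75, h_R = 0.90, h_L = 0.93),
                        config = sim_config(fs = 500, duration = 40,
                                            qrs_amplitude = 4,
                                            hr_jitter_bpm = 4, seed = 3))
beats <- detect_beats(rec$signal, rec$fs)
head(beats[, c("r_time", "r_amp", "t_time", "t_amp", "delta")], 3)
#>      r_time    r_amp    t_time     t_amp      delta
#> 1 0.4999665 4.000011 0.7919964 0.7712547 0.07123628
#> 2 1.5684924 3.999739 1.8692710 0.7711901 0.07334659
#> 3 2.5883792 3.999773 2.8823174 0.7711990 0.07167455

fit_ap(beats)
#> <ap_fit> k = 0.751, h_R = 0.913, h_L = 0.945 (38 beats, 3 rounds, residual 0.0728)
#> label: myocardial_ischemia
```

The fit recovers the generating `k = 0.75` to three decimals and the
amplitude factors within ~2%; `k < 0.9` yields the ischemia label.
Detection quality against the generator's annotations:

```r
m <- match_events(beats$r_time, rec$annotations$r_time, tol_s = 0.075)
metrics(m$tp, m$fn, m$fp)
#> <detection_report> TP 38 / FN 1 / FP 0 | Se 97.44% DER 2.63% Acc 97.44%
```

A command-line interface with `simulate`, `detect`, `fit`, `classify`,
`evaluate` and `pipeline` subcommands lives at `inst/cli/ecgwave`.

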