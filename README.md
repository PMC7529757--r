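# tcsmlm

Time-correlated single-molecule localization microscopy (tcSMLM) in R.

## The problem

SMLM reconstructs super-resolved images by localizing sparse blinking
fluorophores frame by frame, and ordinarily throws away the *temporal*
signature each fluorophore leaves on its own pixels. A two-state
photoswitching emitter with mean on/off dwell times `t_on`, `t_off`
produces intensity fluctuations whose autocorrelation decays exponentially
with correlation time `tau_c = t_on * t_off / (t_on + t_off)`. This
package implements a preprocessing transform that scores every pixel, in a
sliding window of `mw` frames, by the covariance between its windowed
(unnormalized) intensity autocovariance and a normalized model decay
`exp(-k * T / tau_c)`:

```
v_j = Cov[ AC(I_j), AC(f) ]        (one value per pixel per window)
```

Stacking these images yields a "time-correlated" movie in which an
emitter's footprint is its PSF *squared* — `sqrt(2)` narrower — and in
which pixels whose fluctuations do not decay like the fluorophore model
(static background, shot noise, slow out-of-focus drifts) are suppressed.
Any conventional localizer can then be run on the transformed movie. The
package is aimed at microscopists and methods developers who want to
reproduce, stress-test, or extend this reconstruction strategy without any
experimental data: a full blinking-emitter simulator, a baseline
wavelet + Gaussian-fit localizer, and the standard evaluation metrics
(Fourier ring correlation, Jaccard index, coordinate-based colocalization,
precision) are included.

## Worked example

Simulate the fast Siemens-star condition (250 emitters on a 10-wing star,
25 x 25 px at 165 nm/px, 2000 fps for 2 s, on/off 180/120 ms, bleaching
5 s), reconstruct both ways, and compare against ground truth:

```r
library(tcsmlm)
report <- run_pipeline(study_config("fast_star"), seed = 101)
report$mw
#> [1] 48
c(smlm = report$smlm$frc_nm, tcsmlm = report$tcsmlm$frc_nm)
#>      smlm    tcsmlm
#> 223.23484  21.72407
c(smlm = report$smlm$jaccard, tcsmlm = report$tcsmlm$jaccard)
#>      smlm    tcsmlm
#> 0.1742313 0.2368421
c(smlm = report$smlm$precision_nm, tcsmlm = report$tcsmlm$precision_nm)
#>      smlm    tcsmlm
#> 13.081700  1.509013
```

The moving window (48 frames) is `tau_c / 3` at 2000 fps — the package's
kinetics-matched default. The time-correlated arm resolves ~22 nm by FRC
against the ground-truth rendering where the identically parameterized
conventional reconstruction of the same movie reaches ~223 nm; its Jaccard
index is higher at every matching radius and its median Thompson
uncertainty several-fold lower. Individual steps are exposed as ordinary
functions (`simulate_movie()`, `tc_transform()`, `localize_stack()`,
`frc_resolution()`, `optimal_mw()`, ...), and `run_sweep()` repeats any of
it over a parameter grid with replicate means and SEMs.

See `vignettes/tcsmlm-methods.Rmd` for the model, the moving-window rules,
all tunable parameters, and the design decisions (including what the
simulator does not emulate).

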