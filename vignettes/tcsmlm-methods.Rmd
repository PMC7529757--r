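---
title: "Time-correlated SMLM: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-correlated SMLM: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tcsmlm)
```

## The idea

Single-molecule localization microscopy (SMLM) reconstructs a
super-resolved image by fitting the positions of sparse, photoswitching
("blinking") emitters frame by frame. Conventional reconstruction treats
every frame independently and discards the temporal signature that each
fluorophore imprints on its own pixel trajectory. The time-correlation
transform implemented here exploits that signature.

A fluorophore that switches between an emitting (on) and a dark (off)
state with exponential dwell times $\tau_{on}$ and $\tau_{off}$ produces
intensity fluctuations whose autocorrelation decays as a single
exponential with correlation time

$$\tau_c = \frac{\tau_{on}\,\tau_{off}}{\tau_{on} + \tau_{off}},$$

e.g. $\tau_c = 72$ ms for 180/120 ms dwell times. The transform slides a
moving window (MW) of $\tau$ frames along the movie. Inside each window it
reduces every pixel trajectory $I_j(t)$ to its *unnormalized*
autocovariance $AC_{I_j}(k)$ over lags $k = 0..L-1$, and scores the pixel
by the covariance of that curve with a *normalized* model decay
$AC_f(k) = e^{-k\,T/\tau_c}$ ($T$ the frame period):

$$v_j = \mathrm{Cov}\left[AC_{I_j},\, AC_f\right].$$

Pixels whose fluctuations decay like the model score highly; pixels
dominated by static background, shot noise, or much slower decays score
near zero. Stacking $v_j$ images for window starts $1, 1+s, \dots$ yields
the time-correlated movie ("tcData", $N - \tau$ frames at step $s = 1$),
which is then localized with an ordinary SMLM pipeline.

**Why the asymmetric normalization matters.** The pixel autocovariance
scales with the *square* of the pixel's signal amplitude, and the
covariance is linear in it. A point emitter with Gaussian PSF of width
$\sigma$ therefore appears in tcData with profile $\mathrm{PSF}^2$, i.e.
width $\sigma/\sqrt{2}$ — the same $\sqrt2$ sharpening as a second-order
intensity cumulant. Normalizing the pixel curve as well would destroy the
spatial contrast (every pixel with *any* matching fluctuation would score
1) and the sharpening with it. The package's test suite verifies the
$\sqrt2$ ratio on a noiseless single emitter to 5%. Note that this holds
in the continuous domain: on a camera that undersamples the PSF
($\sigma \lesssim$ 0.6 px) the *pixel-integrated* profile squares to
something slightly narrower than the integrated
$\sigma/\sqrt2$ Gaussian, so the property is checked on a well-sampled
grid (55 nm pixels).

## Choosing the moving window

Three rules are provided.

* `theoretical_mw()` — the closed form $\tau_c / (s\,T)$ rounded to
  frames, with $s$ the tcData time step. For 180/120 ms at 1000 fps and
  $s = 2$ it gives 36 frames.
* `optimal_mw()` — the data-driven probe-pixel procedure: pick four pixels
  at spread quantiles of the sum-intensity image (0.999, 0.99, 0.9, and a
  low 0.2 quantile expected to contain only background), smooth each
  full-trajectory autocovariance with a centred moving average (window
  5–15, default 9), and find where the log-ACF stops being linear — the
  longest prefix over which the absolute Pearson correlation of
  $\log AC(k)$ against $k$ stays $\ge 0.9$ (prefixes shorter than 5 lags
  are not trusted). A cutoff of 0 marks a background-like probe; the
  selected MW is the minimum over the non-zero cutoffs, because cutoffs
  grow with the amount of slow interference a pixel sees and the window
  must suit the *cleanest* emitters.
* `matched_mw()` — the pipeline default when the blink kinetics are known:
  $\tau_c / (3\,T)$ frames. In our replications the reconstruction quality
  (Jaccard index and FRC resolution versus MW) forms a broad plateau whose
  peak sits near one third of the correlation time — about 24 frames at
  1000 fps for 180/120 ms kinetics — and degrades once the window
  approaches $\tau_c$, because a
  long window admits several overlapping bursts per window and blurs the
  tcData frames.

The probe-pixel procedure deserves a caveat that our simulations expose
clearly: its cutoffs measure where *interference breaks log-linearity*,
not where reconstruction quality peaks. On clean, bright movies (little
background, high photon flux) nothing breaks linearity for hundreds of
lags and the procedure returns windows near or above $\tau_c$ — honest
output of the rule, but far from the quality optimum. It is most useful on
data with appreciable background, the regime it is designed for.

## The simulator

`simulate_movie()` composes four parts, each exposed and tested on its
own:

* **Phantoms** — a Siemens star (alternating sectors of width
  $\pi/\mathrm{wings}$, emitters placed by rejection sampling), nanoruler
  pairs separated by exactly 50 nm at random orientation, or a uniform
  field.
* **Blinking** — a continuous-time two-state telegraph process started
  from its stationary state, killed at an exponential bleaching time
  (default mean 5 s). Per-frame values are the *fraction of the frame
  spent emitting*, so kinetics faster than the frame period are integrated
  rather than snapshotted.
* **Optics** — an integrated 2-D Gaussian PSF of width
  $\sigma = 0.21\,\lambda/\mathrm{NA}$ (96.9 nm for 600 nm at NA 1.3; the
  0.21 factor is a configurable Gaussian approximation of a widefield
  PSF). Sample-plane pixel size is `detector_pixel * 1000 / magnification`
  (165 nm for 16.5 µm at 100x).
* **Camera** — `counts = baseline + gain * Poisson(QE * photons +
  dark * T) + Normal(0, readout * gain)`, rounded and clipped at zero,
  with defaults readout 1.6 e- rms, dark 0.06 e-/px/s, QE 0.7, gain 6.
  The gain is deterministic; the EM excess-noise factor is deliberately
  omitted.

Out-of-focus background is modelled as a second emitter population with
the PSF widened by a defocus factor (default 4) and five-fold slower
blinking, plus an optional uniform photon rate — together these produce
the low signal-to-background regime. SBR here means mean in-focus peak
amplitude over mean background level per pixel; other simulators define
SBR differently, so SBR values should be compared qualitatively across
tools.

**Photon flux.** The emission rate while on is a free parameter with no
canonical value; we fix the default at $5\times10^5$ photons/s — a
typical detected flux for a bright organic dye under strong excitation,
bright enough that fast acquisition stays in the low-noise regime (at
2000 fps this gives ~250 photons/frame, peak-pixel SNR well above the
read noise). Every quantity that scales with photon
count — Thompson uncertainties in particular, which scale as
$1/\sqrt{N}$ — inherits this choice; reported uncertainty medians should
be read on that flux scale.

What the generator deliberately does **not** emulate: 3-D PSFs, drift,
sCMOS pixel-dependent noise maps, dipole orientation effects, and
heterogeneous per-emitter kinetics. Passing tests therefore demonstrate
correctness of the transform and pipeline under idealized blinking, not
robustness to every artefact of real acquisitions.

## Localization and evaluation

The baseline localizer follows the common wavelet workflow: à-trous
B-spline filtering (order 3, scale 2 — kernel `[1,4,6,4,1]/16`), local
maxima over the 8-neighbourhood above `threshold_factor` times the first
wavelet level's standard deviation, then Levenberg–Marquardt least squares
of a pixel-integrated symmetric Gaussian with constant offset. The
integrated model matters here because the default optics undersample the
PSF (sigma 97 nm on 165 nm pixels). Uncertainty is Thompson's closed form
$\sigma_{loc}^2 = (s^2 + a^2/12)/N + 8\pi s^4 b^2/(a^2 N^2)$ — chosen over
later refinements because only medians are compared. Identical parameters
are applied to raw and time-correlated movies; tcData values are mapped to
a photon-equivalent scale by a robust affine calibration (median-to-median,
upper-quantile-to-upper-quantile against the raw movie) before fitting,
since covariance units are not photons.

The pipeline applies one post-fit quality filter, shared verbatim by both
arms: fitted widths must lie within 0.6–1.5 of the optical PSF width,
which accepts both the raw width $\sigma$ and the transformed width
$\sigma/\sqrt2$ while rejecting multi-emitter blob fits. Grouping merges
detections within 60 nm of a track's running intensity-weighted mean
across gaps of up to 20 dark frames; merged uncertainty pools as
$1/\sqrt{\sum \sigma_i^{-2}}$.

Evaluation renders localizations and ground truth as unit-mass Gaussians
(2 nm width, 5 nm render pixels) and compares them by Fourier ring
correlation; resolution is read at the first crossing of 1/7 after a
3-ring moving average, with the Nyquist bound returned (and flagged) when
no crossing exists. We validated the FRC machinery against the closed
form for Gaussian-jittered point sets — the 1/7 crossing sits at
$\approx 3.2\sigma_{err}$ — and it agrees within a few percent. Fidelity
uses greedy distance-sorted one-to-one matching (within one pair of the
exhaustive optimum on small instances, deterministic at any size),
Jaccard index $TP/(TP+FN+FP)$ over the 13.75–137.5 nm radius grid, the
coordinate-based colocalization score with Spearman rank correlation of
area-normalized neighbour distributions (10 nm steps to 200 nm) damped by
$e^{-d/r_{max}}$, and precision as the median uncertainty over true
positives.

## Numerical and design choices

* Lags per window default to $\lfloor\tau/2\rfloor$; lags beyond half the
  window average too few samples. Lag 0 (which carries shot-noise
  variance) is included by default and can be dropped
  (`include_lag0 = FALSE`). Selectivity *against faster decays* requires
  lags extending beyond the model correlation time; with short windows the
  squared-amplitude weighting, not the decay shape, carries most of the
  contrast.
* Negative covariances are clipped to zero (`clip_negative = TRUE`)
  because downstream localizers assume non-negative intensities.
* Windows advance only while complete windows fit; no partial windows.
* The probe-pixel minimum excludes zero cutoffs: a zero marks a
  background probe, and including it would collapse the minimum to zero
  whenever any probe lands on background.
* Merging uses greedy chaining against the running weighted mean; ties in
  peak detection resolve to the first pixel in (row, column) order.
* Degenerate inputs: constant trajectories give all-zero autocovariance
  (not an error); a constant movie is a degenerate-model error for the
  empirical ACF; an all-background probe set is a no-signal error with
  per-probe diagnostics attached.

## Problem sizes used in the checks

The benchmark conditions are deliberately desk-scale: the fast-star
condition is 25 × 25 px × 4000 frames (about 18 s per seed end-to-end),
the large-field condition 100 × 100 px × 2000 frames (about 80 s per
seed), and the dense-background condition 25 × 25 px × 2000 frames with
1340 emitters. Replicate averages use 5 seeds in the acceptance script
and 3 for the large-field condition in the test suite.

## Known limitations

* Single-emitter least-squares fitting only: in crowded regimes
  (several active emitters per diffraction-limited area),
  raw-movie localization carries crowding bias that no parameter choice
  removes; multi-emitter fitting is out of scope. Comparisons between the
  two arms remain valid because both use the identical localizer.
* Absolute uncertainty medians scale with the configured photon flux (see
  above); orderings and ratios between arms are the robust read-outs.
* The probe-pixel MW rule returns long windows on very clean data (see
  the caveat above); prefer `matched_mw()` when kinetics are known.
* CBC is quadratic in the number of points; subsample beyond ~10^4
  localizations.
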