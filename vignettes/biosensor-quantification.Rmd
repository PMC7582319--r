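---
title: "Quantifying filter-disk biosensor bioluminescence from smartphone and CMOS imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying filter-disk biosensor bioluminescence from smartphone and CMOS imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luxdisk)
```

## The measurement problem

Whole-cell biosensors couple a stress-responsive bacterial promoter to a
`lux` reporter: when an engineered *E. coli* strain immobilized on a
filter-membrane disk meets a toxicant, its bioluminescence rises above the
control level. The quantity of interest is the **induction factor**

$$\mathrm{IF} = B_i / B_c,$$

the ratio of the treated sample's signal readout $B_i$ to the control's
$B_c$, and its replicate **signal-to-noise ratio**, the mean induction
factor across at least three replicates divided by their sample standard
deviation ($n-1$ denominator).

The signal is faint, so the readout route depends on the detector:

* **Plate reader** — a kinetic trace in relative light units (RLU); the
  readout is the trace maximum.
* **Smartphone camera** — tens of long-exposure RGB frames centered on the
  kinetic peak; frames are averaged into one stacked image, the green and
  blue channels are merged (lux emission is blue-green; red is discarded),
  disk regions are measured, and a background level is subtracted. The
  stacked net intensity over the measuring window is the readout.
* **Ultra-low-light CMOS sensor** — a 4-channel stream of 24×24-pixel
  records with a temperature reading per record; the dark background is
  predicted from a temperature→counts standard curve fitted on dark
  records, subtracted per record, and the window-mean net signal is the
  readout.

`luxdisk` implements all three routes plus the statistics on top of them
(dose–response tables, paired/two-sample *t* tests, one-way ANOVA with
Fisher's LSD and compact letters), and a forward simulator that generates
kinetic traces, frame stacks and CMOS streams with known ground truth, so
each stage can be validated without laboratory data.

## Kinetic model

No functional form for the kinetics is established beyond "a single peak at
time $t_p$", so the simulator uses an asymmetric Gaussian,

$$v(t) = b + \mathrm{IF}\cdot A \exp\!\left(-\frac{(t-t_p)^2}{2\sigma^2(t)}\right),
\qquad \sigma(t) = \begin{cases}\sigma_\text{rise} & t \le t_p\\
\sigma_\text{decay} & t > t_p\end{cases}$$

which is smooth, single-peaked, attains its maximum exactly at $t_p$, and
relaxes to the baseline $b$ away from the peak. The bundled strain library
fixes $t_p$ at the published peak times — 2.5 h (TV1061), 2.3 h
(grpE::lux), 0.3 h (DPD2794), mid-0.55 h for soxS::lux whose peak spans
0.3–0.8 h — and carries the published per-detector induction tables as
ground truth. The rise/decay widths (0.7/1.0 h for the slow cytotoxicant
reporters, 0.15–0.35 h for the fast ones) are the package's own choice of a
realistic shape; nothing downstream depends on their exact values because
the analysis never fits the curve.

**Baseline choice.** The default profiles use $b = 0$: the basal glow of
uninduced cells is folded into the detector background term. This is a
deliberate modeling decision, not a simplification of convenience. Image
background subtraction removes the *detector* dark level measured outside
the disks; it cannot remove a disk-local basal glow. With $b = 0$ the
treated and control radiances are proportional at every instant, so the
ratio of background-subtracted window means equals the ground-truth
induction factor exactly — which is what makes exact end-to-end recovery a
meaningful test of the photometry. A nonzero baseline compresses recovered
ratios toward 1 in *any* background-subtracted readout; users can set
`baseline_rlu > 0` to study exactly that effect.

## Sensor model and noise

Expected counts follow `dark + gain · radiance · exposure`, with the
bacterial signal placed in the green and blue channels only. Noise is
Poisson shot noise on the expected counts, then additive Gaussian read
noise, then rounding to integer counts and clipping to the bit depth
(8 or 16). Rounding is applied **only when a noise source is enabled**:
noiseless renders keep real-valued expected counts so that the noiseless
pipeline is exactly linear, while realistic frames honor the
integer-pixel contract. The CMOS stream uses the same model with a
temperature-dependent dark background in place of the constant dark level.

The default simulated study conditions mirror the published acquisition:
16-bit frames, 32 s integration, a 2000 s measuring window with 3 s shutter
delay and 1 s frame interval (60 frames), a window centered on the
plate-reader peak time. The simulator's default photometric gain (0.05
counts/RLU/s) keeps the brightest published condition (induction 7.6 at
amplitude 2000 RLU) far from 16-bit saturation.

What the generator does **not** emulate: lens effects (PSF, vignetting,
focus), Bayer demosaicing, frame-to-frame motion, hot pixels,
fixed-pattern noise, and any biology beyond the single-peak kinetics. Tests
that pass on simulated data therefore validate the *computational chain* —
stacking, merging, photometry, calibration, statistics — not the optical or
biological fidelity of a specific bench setup.

## Image chain choices

* **Stacking** is the per-pixel arithmetic mean in real arithmetic, never
  re-quantized, so that low-light rounding cannot bias the stack.
* **Channel merge** is the arithmetic mean of G and B (not the sum): it
  keeps the output on the input intensity scale, and any fixed linear
  combination rescales induction numerator and denominator identically.
* **Disk detection** thresholds at median + 5·MAD (MAD with the standard
  1.4826 consistency factor), labels connected components
  (`EBImage::bwlabel`), and assigns each a centroid and equivalent-radius
  circle. Five MADs is conservative enough that stacked low-light
  background rarely crosses it, yet the disks (tens to hundreds of counts
  above background after stacking) always do. With a layout hint, detected
  regions snap to the nearest hinted center within two radii and adopt the
  hinted geometry exactly — mirroring how regions were selected manually
  around known disk positions on the bench.
* **Circle membership** is pixel-center distance ≤ radius in 0-based,
  row-major coordinates, the same rule in the renderer and the photometry,
  so noiseless simulation and measurement agree to machine precision.
* **Background** defaults to the median of all pixels farther than two
  radii from every disk; an explicit rectangle overrides it. Negative net
  intensities are retained (clamping would bias induction factors upward
  near the detection limit) and reported via a message.
* **Row-major ROI ordering** buckets centroid rows that differ by less
  than a typical radius before sorting by column, so sub-pixel centroid
  jitter cannot scramble the disk order.

## Windows and planning

The measuring window is the kinetic peak ± 1000 s, clamped at zero.
Internal arithmetic is exact; *reported* bounds are truncated to 0.1 h,
which reproduces the conventionally quoted intervals (peak 2.5 h → 2.2 to
2.7 h; peak 2.3 h → 2.0 to 2.5 h). Strains whose published window does not
follow the rule (soxS::lux, 0.3–0.8 h) carry an explicit override in the
strain library. Frame planning is
`n = floor((measuring − delay) / (integration + interval))`, and a frame
belongs to the window by its start time (intervalometer semantics). The
published schedule yields 60 frames. For a constant or noiseless signal,
averaging per-frame net intensities over the window is identical to
measuring the stacked image once; the pipeline uses the stacked route and
tests the equivalence.

## Statistics

Induction factors and SNR follow the definitions above (sample SD, ratio
undefined — an error, not infinity — at zero variance). Two-group
comparisons use Student's *t* (paired or Welch two-sample), two-sided.
Multi-group comparisons use one-way ANOVA with Fisher's LSD: unadjusted
pairwise *t* tests on the pooled mean-square error with its residual
degrees of freedom. No multiple-testing correction is applied beyond LSD,
matching standard practice for this assay. Compact letters are assigned by
sweeping groups in decreasing mean order and lettering maximal runs of
mutually non-significant groups; tests verify that sharing a letter
coincides with pairwise non-significance on all fixtures.

## CMOS pipeline choices

The published analysis references an external standard curve without
printed coefficients, so the curve is always fitted here: a least-squares
polynomial (degree 2 by default) of the per-record mean pixel value against
temperature, from user- or simulator-supplied dark records at three or more
distinct temperatures. The per-record scalar is the mean over the 24×24
grid — the sensor is used as a photometer, one induction value per channel —
with per-pixel dark correction noted as a possible extension. Records
outside the curve's fitted temperature range are extrapolated with a
warning. Composite images tile the four channel grids 2×2, row-major by
channel id.

## Numerical and degenerate-input policy

Ties in peak detection resolve to the earliest time; a maximum at either
end of a trace is flagged as a boundary peak. Peak smoothing defaults to a
3-sample centered moving average with shrinking windows at the edges (so a
strictly increasing trace peaks at its last point rather than at a
NA-padded interior point). Degenerate statistics — fewer than three
replicates for SNR, zero variance, fewer than two observations per group —
raise errors rather than returning infinities. Malformed CMOS stream lines
abort parsing with their line numbers.

## Problem sizes used in validation

The test-suite simulations are sized for quick, repeated runs while keeping
every estimate well-conditioned: photometry checks use 100×160 to 160×220
frames with 2–6 disks; the stacking noise-reduction check uses sixty
480×640 frames; recovery-under-noise properties use 100 seeded runs of a
200 s schedule (5 frames each); CMOS checks use 50–202 records. These sizes
are the package's validation choices; all scale linearly if users rerun
them larger.

## Known limitations

* The asymmetric-Gaussian kinetic form is a modeling convenience; real
  traces may be multi-phasic. Peak detection (smoothed argmax) does not
  depend on the form, but simulated recovery numbers do.
* Disk size is treated purely in pixels; no physical pixel scale is
  assumed (the physical disk diameter is ambiguous in the source
  protocol).
* Frames are assumed aligned and already demosaiced RGB; there is no
  registration or flat-field correction.
* The detection threshold (5 MADs) assumes the disks occupy a minority of
  the frame; a frame dominated by signal would inflate the median and MAD.
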