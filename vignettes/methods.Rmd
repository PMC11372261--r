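---
title: "Models and methods behind patlakr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind patlakr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patlakr)
```

`patlakr` quantifies tumor tracer uptake on dynamic PET three ways — the
Patlak net influx rate K_i, the static SUV/SUR, and their
uptake-time-corrected variants cSUV/cSUR — and asks the question that
motivates all three: which metric changes least when the same lesion is
imaged at an early (~35–50 min) and a late (~75–90 min) uptake time
within one session? This vignette documents the models, the defaults and
their rationale, the numerical choices, and what the synthetic data do
and do not establish.

## Tracer kinetics and the Patlak transform

Lesions follow the two-tissue compartment model: blood exchanges with a
free tissue pool (K1, mL/min/mL; k2, 1/min), which exchanges with a
bound pool (k3, k4, 1/min). The tissue concentration is the
sum-of-exponentials convolution of the blood input C_p(t) with the
compartmental impulse response, plus a fractional blood volume term
vb·C_p. With k4 = 0 the bound pool traps irreversibly and the Patlak
coordinates x = ∫C_p/C_p, y = C_t/C_p become asymptotically linear with
slope K_i = K1·k3/(k2+k3); `ki_true()` exposes this ground truth. With
k4 > 0 (DOTATATE-like reversibility) the plot bends downward, so a
late-window slope is strictly below an early-window slope — one of the
two signed mechanisms the package demonstrates.

`fit_patlak()` is deliberately plain: unweighted ordinary least squares
of y on x over the frames of one window, slope ×100 reported in
mL/min/100 mL. No t* search is performed — the analysis window (the
three latest pre-departure passes, chosen to reach steady state) plays
that role. The Patlak denominator C_p is always taken from the AIF
object supplied (fitted or true), mirroring a scanner workflow in which
the fitted AIF drives the reconstruction.

## Arterial input functions: truth, fit, extrapolation

The generator's ground-truth AIF is a Feng-type bolus model,
(A1·t − A2 − A3)e^(−λ1 t) + A2 e^(−λ2 t) + A3 e^(−λ3 t), the standard
realistic peak-plus-tail shape in PET simulation. First-pass amplitudes
follow the classic FDG bolus; the terminal clearance is set to
λ2 = 0.0055/min (tail half-life ≈ 2 h) so the blood pool falls about
20% between the 42.5- and 82.5-min window midpoints, matching clinical
image-derived whole-blood behavior at late uptake times. Each subject's
curve is scaled so the blood-pool SUV at 60 min lands in 1.4–2.2.

Blood is measurable only to 50 min (the subject leaves the scanner), so
the late window always runs on an extrapolated fit. Two fitted forms are
provided:

- `exponential_tail` (FDG-style): A1·e^(−λ1 t) + A2·e^(−λ2 t) by
  duration-weighted least squares on post-peak samples, excluding a
  3-min post-peak settle interval. The bi-exponential is the minimal
  form that can follow a realistic tail; it models the settled clearance
  phase, and including the first-pass spike (structurally a t·e^(−λt)
  term) in an unweighted fit with densely framed 10-s samples would
  sacrifice the tail to the spike. Duration weighting is the discrete
  analogue of a continuous-time least-squares fit.
- `linear_piecewise` (DOTATATE-style): an interpolating polyline;
  beyond the last sample it continues the final segment's slope, clamped
  at zero. Because a decaying exponential is convex, this extrapolation
  lies below the true curve — which is exactly how the package
  constructs its under-extrapolation demonstration: analyzing an
  irreversible lesion's late window with an AIF pointwise below truth
  inflates the late K_i.

Cumulative integrals ∫C_p use closed forms for all exponential-family
objects and exact trapezoids for polylines (with a linear rise from 0 at
t = 0 to the first sample).

## Phantoms, VOIs, and metric extraction

`render_dynamic_phantom()` builds a small 4D image (default 32³ voxels
at 4 mm) per subject: background tissue, up to five spherical lesions,
and a 20-mm aorta tube along z carrying the frame-averaged AIF. Because
a PET voxel reports the volume average of the activity inside it, lesion
surfaces are rendered with per-voxel inside-sphere volume fractions
(slab approximation) rather than binary membership; this is not PSF
modelling (no blur kernel) but prevents non-physical step changes at
edges. Frame values everywhere are averages of the continuous curves
over the frame (0.1-min midpoint sampling), matching how PET frames
integrate counts. Optional noise is zero-mean Gaussian with
SD = scale·sqrt(value/duration), the first-order count-statistics model.

Analysis masks follow one convention throughout: a voxel belongs to a
VOI iff its center is inside the shape, with coordinates in image-space
millimeters and voxel centers at (i − 0.5)·voxel size. Ground-truth
lesion masks (dilated one voxel, configurable) stand in for manual
segmentation. SUV = concentration / (dose/weight); the per-window SUV
map is the mean of the three pass frames, mirroring a multi-pass static
reconstruction. `extract_max()` is the maximum voxel; `extract_peak()`
is the PERCIST-style peak — the highest mean over a 1-mL sphere
(diameter ≈ 12.4 mm) centered within the mask, border-clipped; the
original study does not state its peak definition, so PERCIST is adopted
as the field standard. Blood SUV_mean comes from a 1-cm × 6-cm cylinder
inside the tube, and SUR_max/SUR_peak share that denominator. DOTATATE
K_i values are divided by (1 − hematocrit) because the tracer stays in
plasma.

## Uptake-time correction and the exponent b

cSUV = SUV·(Tc/T0)^(1−b) with Tc = 60 min and the window midpoint as the
effective uptake time T0; cSUR = SUR·Tc/T0. Defaults are b = 0.313 (FDG,
published) and b = 0.63 (DOTATATE, empirically derived). `derive_b()`
reproduces that empirical derivation: the two-point power-law equation
is solved exactly per lesion, b = 1 − ln(SUV_l/SUV_e)/ln(T_l/T_e)
(with one pair per lesion this coincides with the least-squares
optimum), then averaged within subject and across subjects so
lesion-rich subjects do not dominate; a lesion-pooled variant is one
argument away, since the original description ("averaged across all
subjects") does not fix the hierarchy. Results outside [0, 1.5] warn —
b > 1 implies washout.

## Repeatability statistics

Lesions are the unit of analysis and tracers are summarized separately.
For each metric: Δ = late − early; %Δ = 100·Δ/pair mean; |%Δ|;
95% limits of repeatability μ ± 2σ with σ the n−1 sample SD; quartiles
by linear interpolation (type 7 — one rule had to be picked and is
stated for reproducibility). The ICC is the two-way mixed, absolute
agreement, single-measurement form ICC(A,1), computed from the two-way
ANOVA mean squares; this is the only common form whose behavior matches
the phenomenon of interest — a metric can have R² > 0.9 yet ICC < 0.3
when a systematic early-to-late shift is present, which is precisely
what separates SUV/SUR from their corrected versions. The Wilcoxon
signed-rank test drops zero differences, mid-ranks ties, and enumerates
the exact null distribution (a subset-sum convolution over doubled
ranks) for up to 25 non-zero pairs, with a tie-corrected,
continuity-corrected normal approximation beyond.

## Generator defaults and what they represent

Chosen once, as a realistic single-center oncologic cohort, and
documented here rather than revisited:

- FDG lesion kinetics: K1 0.06–0.14, k2 0.25–0.45, k3 0.10–0.30 (1/min),
  vb 0.02–0.06, k4 = 0. This yields true K_i ≈ 1–4 mL/min/100 mL (the
  clinical lesion scale) and SUV growth between the windows consistent
  with the published FDG power law (b = 0.313) — the same property that
  makes cSUV work on real FDG lesions. DOTATATE: K1 0.10–0.30,
  k2 0.20–0.50, k3 0.05–0.20, k4 0.005–0.02, plus hematocrit 0.35–0.48.
  The source study does not report its lesions' microparameters; these
  are literature-style ranges, not measured values.
- Acquisition: early 35–50, late 75–90 min, three 5-min passes each,
  uniform ±5-min jitter on each window start per subject — the uptake
  time variability the correction targets. Doses 300–450 MBq, weights
  55–100 kg.
- Noise: voxel scale 0.2 (≈2–4% on lesion voxels), with blood samples at
  a tenth of that because the image-derived AIF averages the whole
  aortic VOI. This under-represents raw PET noise; the phantom stands in
  for the smoothed multi-pass reconstructions actually analyzed.
- Motion: default 0 mm. The emulated workflow reviews passes for bulk
  motion and segments lesions frame by frame, and a phantom without PSF
  smoothing over-expresses motion artifacts (1–2 mm of inter-frame
  motion inflates voxelwise K_i_max test–retest spread by tens of
  percent here), so the default represents the post-mitigation
  condition. Motion is a first-class configuration knob, and the test
  suite demonstrates the motion → K_i-error mechanism at 2 mm.

## Numerical choices

The 2TC solution uses an exact exponential-step recursion on a 0.01-min
grid with piecewise-linear input (verified against a stiff ODE solver at
1e-8 tolerance to < 0.1%); repeated compartment eigenvalues (a
measure-zero configuration) are split by a 1e-9 relative perturbation.
Seeded operations restore the caller's RNG state. Degenerate inputs fail
loudly by design: empty masks, VOIs off the grid, non-positive blood
concentrations at Patlak midpoints (naming the frame), inverted
windows, hematocrit ≥ 1, all-zero Wilcoxon differences (p = 1 with a
warning), and zero-variance series for ICC/R².

## Problem sizes

Package defaults keep everything desk-scale: 10-subject cohorts, 32³
phantoms at 4 mm, six analysis frames per subject; a full
simulate–analyze–report cycle runs in seconds, and the test suite's
largest computations are a 10,000-replicate noise calibration, a 2¹²
Wilcoxon enumeration, and one full noisy cohort.

## What passing tests do and do not show

The synthetic cohort establishes internal correctness — the estimators
recover known ground truth, the invariances hold at machine precision,
the bias mechanisms carry the right signs, and the end-to-end
repeatability pattern (unstable SUV/SUR, stable K_i/cSUV/cSUR,
agreement-type ICC separating them) emerges under realistic settings.
It does not establish clinical performance: real lesions are
heterogeneous and non-spherical, real AIFs vary in shape across
patients, reconstruction introduces resolution and noise structure the
Gaussian model lacks, and the literature exponents b are population
averages whose transfer to any particular cohort is an empirical
question. The package's repeatability numbers should therefore be read
as a qualitative analogue of the clinical result, not a reproduction of
it.
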