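---
title: "Models and methods for T1 and T2 relaxation mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for T1 and T2 relaxation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxometry)
```

## The problem

Quantitative MRI estimates the tissue relaxation time constants T1 and T2 by
acquiring a series of co-registered images at varying preparation times — an
inversion time (TI), a saturation time, an echo time (TE), or a
T2-preparation duration — and fitting a mono-exponential signal model to
every pixel's time-series. The resulting parameter maps support, among other
applications, myocardial extracellular-volume measurement, oedema detection,
tumour characterisation and non-invasive blood oximetry. Different scanners
compute these maps with undocumented inline algorithms; `relaxometry` is a
vendor-independent implementation in which every numerical step is open and
testable.

## Signal models

Seven sequence families are supported, each with a 3-parameter fit and,
where meaningful, a reduced 2-parameter variant:

| model id        | 3-parameter model                      | 2-parameter model            |
|-----------------|----------------------------------------|------------------------------|
| `ir_se_mag`     | \(S(t) = |A(1 - B e^{-t/T_1})|\)       | \(B = 2\) fixed              |
| `psir`          | \(S(t) = A(1 - B e^{-t/T_1})\) (signed)| \(B = 2\) fixed              |
| `sr_bssfp`      | \(S(t) = A(1 - B e^{-t/T_1})\)         | \(B = 1\) fixed              |
| `molli_mag`     | \(S(t) = |A(1 - B e^{-t/T_1^*})|\)     | n/a                          |
| `molli_psir`    | \(S(t) = A(1 - B e^{-t/T_1^*})\)       | n/a                          |
| `se_t2`         | \(S(t) = A e^{-t/T_2} + B,\; B \ge 0\) | \(S(t) = A e^{-t/T_2}\)      |
| `t2prep_bssfp`  | \(S(t) = A e^{-t/T_2} + B,\; B \ge 0\) | \(S(t) = A e^{-t/T_2}\)      |

Here `A` is the signal amplitude in arbitrary units, `B` a dimensionless
inversion/saturation efficiency factor (T1 rows) or an additive offset in
signal units (T2 rows), and `tau` the relaxation constant in ms. MOLLI-type
continuous readout perturbs the recovery, so the fitted constant is an
apparent \(T_1^*\); the Look-Locker correction \(T_1 = T_1^*(B-1)\) is
applied after fitting. The correction is physically meaningful only for
`B > 1`; pixels fitted with `B <= 1` are flagged and excluded rather than
silently emitted.

Three assumptions are worth making explicit. First, all models are
phenomenological mono-exponentials: readout perturbation is absorbed into
\(T_1^*\) and `B`, not modelled at the Bloch level, so the known MOLLI
underestimation for tissues with very short T2 is outside what this package
(or its simulator) can reproduce. Second, PSIR data are assumed to be
already polarity-restored; the package never reconstructs sign from phase.
Third, the saturation-recovery bSSFP row uses the signed formula exactly as
written (no magnitude operator), which also admits efficiencies above unity.

## Pixelwise fitting pipeline

**T1 initialization.** A two-pass lookup-table search over 0–4000 ms: the
pixel time-series is normalized by its maximum absolute value; candidate
curves assume unit amplitude and ideal efficiency (`B = 2` for inversion
recovery and MOLLI, `B = 1` for saturation recovery) and are normalized the
same way, so a noiseless pixel whose T1 lies on the grid scores exactly
zero. The coarse pass uses 50 ms spacing, the fine pass 5 ms spacing within
±100 ms of the coarse winner; the entry minimizing the sum of absolute
error wins, with ties broken toward the smaller T1 (deterministic).

**T2 initialization.** A weighted linear regression of
\(\log S = \log A - t/T_2\), repeated under stepwise truncation of the
longest echo down to three points; every candidate is scored by the sum of
absolute error of the back-transformed curve over *all* points and the
best-scoring T2 wins. The weights are \(w_i = S_i^2\), which compensates the
variance inflation of the log transform (the delta method gives
\(\mathrm{Var}[\log S_i] \approx \sigma^2/S_i^2\)); the exact weighting of
the original formulation is not documented, and this is the standard
choice. Non-positive samples are dropped before the logarithm; pixels with
fewer than three usable samples are marked unrefined.

**Exclusion.** Initial T2 estimates outside the open interval
0 < T2 < 400 ms are excluded and emit 0 in the map. The boundary is
enforced with a 10^-6 ms guard band: noiseless data generated at exactly
T2 = 400 ms initializes to 400 up to floating-point round-off, and the
open interval must exclude it deterministically. T1 estimates are clamped
to the lookup interval instead; unrefined pixels of either family emit 0,
for symmetry.

**Refinement.** A Nelder-Mead simplex (implemented in C++, standard
reflection/expansion/contraction/shrink coefficients 1, 2, 0.5, 0.5) over
the model's 2 or 3 parameters minimizes the sum of squared residuals by
default; sum of absolute error is available through
`fit_settings(objective = "sum_absolute")`. Least squares is the community
default for the refinement stage — the sum-of-absolute-error criterion
documented for the *initialization* stage is kept there. Convergence is
declared when the maximum absolute difference of the relaxation-time
coordinate between two consecutive simplexes drops below 0.10 ms. That
difference is taken over **all vertex pairs** of the two simplexes, which
bounds both the per-vertex motion and the within-simplex tau spread; the
weaker corresponding-vertices reading can trigger on the very first
iteration, when a single-vertex update happens to leave tau untouched.
Pixels that hit the iteration cap (default 1000) are marked unrefined and
emit 0.

**Starting simplex.** Vertices sit at the initial point plus a 5 %
per-coordinate perturbation (5 ms absolute for a zero tau). `A` starts at
the series maximum; `B` starts at the ideal efficiency for T1 models. For
the 3-parameter T2 fit, `B` starts at the anchor sample value when an
anchor is present, otherwise at the latest-echo floor (the minimum sample),
with `A` reduced accordingly: starting the offset at zero leaves the
simplex with a degenerate step in `B` (0.00025, the fminsearch convention
for zero coordinates), and the tau-based convergence test can then fire
before the offset unfolds — observed as a T2-prep fit converging to 156 ms
on noiseless truth of 100 ms.

**Constraint handling.** The T2 offset constraint `B >= 0` is imposed by
evaluating `|B|` inside the model (constraint by reparameterization), which
keeps the simplex unconstrained. The MOLLI condition `B > 1` is checked
after fitting and flags the pixel, rather than constraining the search.

**SR anchor.** In a T2-prepared series an extra saturation-recovery image
with short saturation time stabilizes the 3-parameter offset. It enters the
objective as one additional sample whose model prediction is the asymptote
`B` — operationally a sample at infinite preparation duration — weighted
equally with the echoes. This matches the anchor's purpose (it pins the
offset); the alternative, fixing `B` to the anchor value, would reduce the
fit to 2 parameters and was rejected because the anchor is as noisy as any
other sample.

**Residuals.** The per-pixel residual is the mean absolute difference
between fit and data, normalized by the pixel's maximum absolute value,
as a percentage — zero for a perfect fit, scale-invariant, and undefined
(flagged) for an all-zero series.

**Background.** Pixels whose maximum absolute signal falls below 1 % of
the image maximum (configurable) are skipped. On noiseless phantoms this
reproduces exact foreground counts; on noisy data most background survives
the gate and is fitted to garbage values, which mirrors how unmasked
scanner maps behave.

## ROI-based fitting

`fit_roi_mean()` averages the signal over the ROI per frame and sends the
mean series through the same single-pixel pipeline. One engine serves both
paths: any implementation satisfying the same 0.10 ms convergence criterion
is interchangeable, so maintaining a second optimizer for ROI means would
add surface without adding behaviour.

## The phantom simulator

`default_eurospin_specs()` builds a synthetic 12-vial gel phantom in the
style of commercial calibration sets: T1 spanning 214–1643 ms and T2
spanning 46–338 ms at 1.5 T (229–1752 ms and 45–316 ms at 3 T), endpoints
included and interior values log-spaced, since only the ranges of the
physical vials are published. Vials sit on a 3 × 4 grid with a 10 % margin
— arbitrary, but fixed so fixtures are stable. Amplitude defaults to
A = 100.

Noise is Rician for magnitude conventions (the modulus of two
Gaussian-corrupted quadrature channels — background then follows a Rayleigh
distribution with mean \(\sigma\sqrt{\pi/2}\), which the tests verify) and
additive Gaussian for signed (PSIR) data. Saturation-recovery bSSFP is
treated as signed because its Table of models carries no magnitude
operator; at the signal levels of a recovery curve the Rician/Gaussian
distinction is negligible away from the zero crossing.

MOLLI acquisitions are simulated phenomenologically: the merged
inversion-time schedule of a scheme such as `5(3b)3` (5 images, 3 recovery
beats, 3 images) is generated at a chosen heart rate, with inversion times
starting at 130 ms and stepping 80 ms per epoch — at 60 bpm this reproduces
the documented delay list 130, 210, 1130, …, 4130 ms, and `4(1b)3(1b)2`
yields 9 samples. The signal is synthesized from the apparent-T1 model with
\(T_1^* = T_1/(B-1)\), so the Look-Locker-corrected ground truth equals the
vial T1 by construction.

What the simulator deliberately omits: B0/B1 field inhomogeneity, slice
profiles, partial-volume mixing, motion, readout-induced deviation from
mono-exponential recovery, and structured (non-white) noise. Passing tests
on these phantoms therefore demonstrate the correctness of the numerics —
initialization, search, exclusion, correction, statistics — not robustness
to the system imperfections of a physical scan.

## Validation statistics

`bland_altman()` implements the modified Bland-Altman analysis: differences
`measured − reference` are summarized as bias (mean), variability (sample
SD, n−1 denominator) and 95 % limits of agreement at bias ± 1.96 SD, and
plotted against the reference rather than the pair mean, which is the
appropriate design when one method is a reference standard. Percentage
forms divide each difference by its own reference value and average
(rather than dividing the mean difference by the mean reference).

A design-level property this package's simulations reproduce: with
saturation efficiency away from its ideal value, the 2-parameter SR fit is
systematically biased while the 3-parameter fit absorbs the efficiency into
`B`. With true B = 1.05 at SNR 50 the 3-parameter per-vial bias stays below
1 % while the 2-parameter bias is positive and several-fold larger. An
efficiency *above* unity is what a driven bSSFP readout produces (the
steady state sits below the saturation-recovery asymptote, which the
3-parameter model expresses as B > 1); a value below unity would flip the
sign of the 2-parameter bias and contradict the positive bias this
configuration is meant to exhibit.

## Numerical choices and problem sizes

* Convergence tolerance 0.10 ms on tau; iteration cap 1000 (cap hits mark
  the pixel unrefined, they never error).
* Grid-search ties break toward the smaller T1.
* Degenerate inputs: all-zero pixels error in direct calls and are gated as
  background in maps; duplicate preparation times are rejected; an anchor
  frame's nominal time is ignored (`NA` allowed).
* Map containers are plain matrices; undefined residuals are `NA` in
  arrays and 0-with-`refined = FALSE` in maps; maps serialize to 64-bit
  float NIfTI so tau values round-trip bit-exactly.
* The test-suite and the acceptance script fit 48 × 48 phantoms (about 300
  foreground pixels per model) for the noiseless round trips, ~500 pixels
  per vial for the bias comparisons, and one full 192 × 144 × 15 map as the
  performance probe — sizes chosen to exercise every code path at
  comfortable desk-scale runtimes.

## Known limitations

No registration (rigid or non-rigid) is performed; series are assumed
co-registered. DICOM support covers standard tags on uncompressed
little-endian files only — vendor private headers are explicitly out of
scope. T2* mapping is not included. The phantom simulator's fidelity limits
are listed above; in particular, agreement statistics measured on synthetic
phantoms characterize the algorithms, not scanner performance.
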