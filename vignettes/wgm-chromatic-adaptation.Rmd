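---
title: "Weighted geometric mean chromatic adaptation: models, fitting, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted geometric mean chromatic adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgmcat)
```

## The model family

Every transform in this package is a von Kries-type operation in the CAT16
cone space: the cone response to a stimulus is divided channelwise by an
*effective adapting white*, and the models differ only in how that
denominator combines the adapting white $n$, a fixed reference white $r$,
and (for vK20) a previous adapting white $p$:

| model       | effective white            | parameters              |
|-------------|----------------------------|-------------------------|
| von Kries   | $n$                        | —                       |
| linear      | $D n + (1-D) r$            | $D \in [0,1]$           |
| vK20        | $D_n n + D_r r + D_p p$    | $D_n + D_r + D_p = 1$   |
| geometric mean | $\sqrt{n r}$            | —                       |
| WGM         | $n^{D} r^{1-D}$            | $D \in [0,1]$           |

The effective white is simultaneously the model's *predicted neutral*: a
stimulus whose cone response equals it adapts to $(1,1,1)$ and appears
achromatic. The two families differ qualitatively in where that neutral can
lie. A linear mixture confines it to the straight cone-space segment
between $n$ and $r$ — approximately a straight chord in the u′v′ diagram —
whereas the log-linear WGM mixture interpolates the *logarithms* of the
anchors. Because the Planckian locus is itself close to a log-linear family
(Planck's law exponentiates in $1/T$, and mired is the natural parameter),
WGM neutrals for blackbody-like adaptors track the locus: the package's
tests verify that for Planckian adaptors between 3000 K and 10000 K and
$D \in \{0.3, 0.5, 0.7\}$ every predicted neutral stays within
0.01 u′v′ of the locus, while the linear transform with an equal-energy
reference departs from it by several JND at low CCT.

At $D = 1$ both parametric families collapse to von Kries scaling
("discounting the illuminant", the cognitive limit), at $D = 0$ to
adaptation to the reference condition, and WGM at $D = 0.5$ reduces to the
plain geometric mean — the parameter-free rule describing steady-state
response compression in many peripheral sensory systems, which is the
physiological motivation for preferring the geometric over the arithmetic
mixture.

Corresponding colors follow the usual three-step composition
(`corresponding_color()`): XYZ → LMS via `M16`, adaptation under the first
illuminant, exact inverse adaptation under the second, LMS → XYZ. All
transforms are exactly invertible; the tests check round trips to 1e-9
over random stimuli.

## Reference whites and one deliberate inconsistency

The linear transform defaults to the equal-energy reference (the CAT16
convention); vK20, GM and WGM default to the sky-blue reference,
`reference_white("15000K")` = (95.41, 103.87, 169.81).

These published cone coordinates deserve a caveat that the package makes
explicit rather than hiding: they are the `M16` image of the *nominal*
chromaticity u′v′ = (0.185, 0.425) at Y = 100, which reproduces all three
values to their printed precision. A 15000 K blackbody synthesized from
Planck's law under the CIE 1931 2° observer
(`reference_white("cct:15000")`) lands about 0.0017 u′v′ away from that
nominal point, which moves the S coordinate from 169.8 to roughly 171.9.
The two spellings are therefore intentionally distinct: the string
`"15000K"` always returns the published constant (what vK20/WGM are defined
with), while `"cct:15000"` always computes through the radiometric
pipeline. Code that needs self-consistency between a generator and a fitter
parameterized by CCT should use the `cct:` form throughout, as the joint
$(D, \mathrm{CCT})$ recovery tests do.

## Colorimetric choices

- **Cone matrix.** The CAT16 $M_{16}$ matrix at full published precision;
  its rows sum to 1, so the equal-energy white maps to $L = M = S$ exactly
  (machine precision), a property the tests assert.
- **Observer and grid.** The CIE 1931 2° color-matching functions, stored
  at 5 nm over 360–830 nm and linearly interpolated to the working 1 nm
  grid. At this grid the synthesized chromaticities of standard anchors
  (equal energy, a 2856 K radiator vs illuminant A, the daylight polynomial
  at 6504 K vs D65) agree with their tabulated values to a few 1e-4 in
  u′v′, which is an order of magnitude below the 1-JND observer noise the
  rest of the package works at.
- **Planck's law** with $c_2 = 1.4388 \times 10^{-2}$ m·K, the value
  conventional in CCT work. Radiator SPDs are relative; all whites are
  normalized to $Y = 100$.
- **Daylight locus** via the CIE two-branch cubic chromaticity polynomial,
  valid 4000–25000 K, used for plotting and validation only. Reference-CCT
  *fitting* is parameterized on the Planckian locus, which has no upper
  validity bound and is where the sky-blue reference lives.
- Luminance is carried through every transform but never enters the error
  metric: the package follows the Δu′v′ (chromaticity-only) convention,
  with 1 JND ≈ 0.004 u′v′.

## The evaluation protocol

`pair_error()` maps both members of a corresponding pair to the model's
reference viewing state — adapt under the member's own illuminant, multiply
by the reference white (`to_corresponding()`), convert to u′v′ — and
returns the Euclidean distance between the two images. A model that
explains the pair exactly maps both members to the same point; the metric
is symmetric in the two members by construction. Achromatic-matching data
use the same metric between the observed neutral and `predict_neutral()`.
`evaluate_dataset()` aggregates per-record errors into per-condition and
overall means and their JND scalings.

Model comparison uses classical one-way fixed-effects ANOVA on per-pair
errors, pooling conditions (`compare_models_anova()`); Welch's correction
is available but off by default. The experimental unit is the pair, not
the observer — per-observer error structure is simply not representable in
the dataset schema. Two degenerate layouts have defined sentinels decided
on the raw groups rather than on QR residuals: all-constant groups with
differing means report $F = \infty, p = 0$; groups with exactly equal
means report $F = 0, p = 1$.

## Fitting

All fits minimize the mean Δu′v′ of the protocol above — nothing else is
ever optimized. `fit_D()` fits $D$ either independently per adapting
condition or as a single dataset-wide value. The 1-D search evaluates a
21-point grid on $[0, 1]$, then runs golden-section/parabolic minimization
(`stats::optimize`) on the bracketing interval, with parameter tolerance
1e-8; the endpoints 0 and 1 are always evaluated exactly, and ties within
1e-8 in the objective resolve to the lowest $D$, so fits are deterministic
and a dataset whose observations sit at the reference chromaticity returns
exactly $D = 0$. Parameter-recovery tests require $|\hat D - D^\ast| <
10^{-4}$ on noiseless synthetic data and agreement within $10^{-3}$ with
an exhaustive $10^{-4}$-step grid search of the same objective.

`fit_D_and_reference()` additionally frees the reference point,
parameterized as the Planckian white at a CCT searched in mired
($10^6/T$) for conditioning, with bounds defaulting to
$[4000, 10^6]$ K. The CCT search profiles $D$ out (the inner $D$ fit is
rerun at every candidate CCT), multi-starts from an 8-point mired-uniform
grid, and refines the best bracket. On noiseless data generated at
`cct:15000` with $D^\ast = 0.7$ the joint fit recovers the CCT to well
under 1 K and $D$ to under 1e-8; the acceptance checks require only
±500 K and ±0.01, leaving room for the objective's flatness near the
optimum on small datasets.

## The synthetic generator

`generate_neutral_matches()` emulates achromatic-matching experiments: per
adapting condition, the ground-truth model's neutral chromaticity is
perturbed by observer noise and lifted back to XYZ at $Y = 100$.
`generate_corresponding_pairs()` emulates memory-matching designs: each
stimulus under the first illuminant is pushed through the ground-truth
transform to the second illuminant, then perturbed. Design choices:

- **Noise model:** isotropic bivariate Gaussian in u′v′ — the space where
  observer scatter is reported and the JND defined — not in cone space.
  The default $\sigma = 0.004$ u′v′ is one JND. A consequence the tests
  exploit: the true model's mean error on its own data has a Rayleigh
  floor $\sigma\sqrt{\pi/2}$, checked within 10% at $n = 10^4$.
- **Default conditions:** the headline configuration — WGM ground truth,
  $D = 0.7$, 15000 K reference, eight Planckian adaptors mired-uniform
  from 3000 K to 15000 K, 20 trials per condition.
- **Stimulus set for pairs:** a fixed 5×5 u′v′ grid (half-width 0.04)
  around the phase-1 white at $Y \in \{20, 50, 100\}$.
- **Reproducibility:** one integer seed; identical seeds give bitwise
  identical datasets, asserted in the tests.

What the generator does *not* emulate — memory bias, cognitive
discounting, inter- and intra-observer variance structure, display
gamut limits — bounds what passing tests demonstrate: they show the
estimation and evaluation machinery is correct and well-conditioned under
the stated noise model, not that WGM is the best description of any
particular real dataset. On synthetic data the generating model at its
true parameters attains the minimal mean error among the three transforms
(each competitor granted its best single $D$), which is a consistency
check, not an empirical finding about observers.

## Problem sizes and runtime

The test suite and the acceptance script use deliberately compact designs:
8 conditions × 20 trials for recovery experiments (20 replicate seeds for
the noisy-median check), 1000 random stimuli for inversion bounds, a
$10^4$-trial single condition for the noise-floor check, and 2000-point
locus sampling (chord error below 1e-4 u′v′). These sizes put every
Monte-Carlo estimate an order of magnitude below its test tolerance.

## Known limitations

- $D$ is restricted to $[0, 1]$; the API rejects extrapolated values.
- Only the CAT16 cone space is supported (no CAT02/HPE variants), and the
  simplified linear transform carries no luminance-ratio factors — the
  degree of adaptation is always explicit or fitted, never derived from
  luminance (the CIECAM16 luminance rule is provided as an opt-in helper,
  `cat16_degree_of_adaptation()`).
- Fitting vK20's $D_p$ is unsupported: no dataset in the schema carries a
  previous-illuminant phase, so $D_p = 0$ with $D_r = 1 - D_n$, making the
  fitted vK20 the linear transform with the sky-blue reference.
- CCT estimation from arbitrary chromaticities (locus inversion) is out of
  scope; `locus_distance()` gives only the distance to the curve.
- The dataset format records one illuminant per phase and no observer
  identity, so observer-level mixed models cannot be expressed.
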