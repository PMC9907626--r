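---
title: "Methods: hyperspectral skin color evaluation with hsicolor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral skin color evaluation with hsicolor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsicolor)
```

## What the package models

`hsicolor` implements the analysis chain of a spectral-scanning
hyperspectral imager used for in vivo skin color evaluation:

1. **Calibration** — raw CCD count frames, one per tunable-filter band, are
   converted to fractional reflectance per voxel using a dark frame, a
   flat-field gain map and a white-standard cube:
   \[ R = \rho_w \frac{S - D}{W - D}, \]
   with \(S\) the (flat-corrected) sample counts, \(D\) the dark counts,
   \(W\) the (flat-corrected) white-standard counts and \(\rho_w = 0.99\)
   the certified reflectance of the white standard.
2. **Colorimetry** — per-pixel reflectance spectra become CIE XYZ by
   integrating against the CIE 1964 10° observer under the D65 illuminant,
   then CIE L\*a\*b\*; color differences use CIE76
   \(\Delta E = \sqrt{\Delta L^2 + \Delta a^2 + \Delta b^2}\).
3. **ROI statistics** — a 68-point facial landmark layout anchors a square
   region of interest (default 75 × 75 px, 12 mm at the instrument's
   160 µm pixel pitch) on the cheek; means, SDs and histograms of the Lab
   channels are extracted per ROI, and before/after product application
   differences \((\Delta L^*, \Delta a^*, \Delta b^*, \Delta E)\) form the
   unit of all downstream analysis.
4. **Uncertainty** — per-band spectral noise is propagated to Lab
   first-order through the Jacobian of the spectrum → Lab map; ROI
   averaging scales uncertainty by \(1/\sqrt{N_\text{pix}}\) and
   before/after differences add in quadrature.
5. **Study statistics** — per instrument–repetition–operator subset,
   products are compared by one-way ANOVA followed by Tukey HSD at
   \(\alpha = 0.01\) and rendered as compact ranking strings; operator and
   repetition agreement is quantified by least-squares fits, Pearson *r*,
   Spearman *ρ*, mean absolute differences and percent nonlinearity.

A synthetic-data generator stands in for the instrument so every stage is
testable without hardware.

## Colorimetry choices

**Integration range.** The imager's spectral support is 420–730 nm in 31
bands, which cannot cover the full 380–780 nm colorimetric range. The
default context therefore integrates over 420–730 nm with the
normalisation constant \(k = 100 / \sum S(\lambda)\,\bar y(\lambda)\)
computed over the *same* truncated range, so a perfect diffuser maps to
\(Y = 100\), \(L^* = 100\), \(a^* = b^* = 0\) exactly — truncation biases
cancel in the white point rather than leaking into every color. A
380–780 nm context with optional zero-extension is available for
full-range spectroradiometer spectra.

**Tabulated data.** The CIE 1964 10° color matching functions and the D65
spectral power distribution ship with the package as 10 nm CSV tables (the
standard CIE tabulations) and are linearly interpolated once onto the 5 nm
working grid. Band values are treated as point samples at band centers;
no bandwidth (FWHM) deconvolution is attempted, since the 32 nm bandpass
acts approximately as a linear smoothing that affects product *differences*
only at second order.

**ΔE variant.** CIE76 is the default everywhere; CIEDE2000 is available
behind `delta_e(..., method = "ciede2000")` but never used implicitly,
because ranking analyses should not silently change metric.

**sRGB rendering.** Lab → XYZ → linear sRGB (D65 primaries) → gamma
encoding, with out-of-gamut channels clipped and the clipped fraction
reported. No chromatic adaptation is needed since both ends use D65.

## ROI protocol

The landmark detector is pluggable (`detect_landmarks()` accepts any
function returning a 68-point set, or a stored fixture); the package never
bundles a face detector. Which landmarks anchor the cheek ROI is not
standardised anywhere, so the anchor is the centroid of a configurable
landmark triple (defaults: jaw point 3, nostril corner 32 and outer right
eye corner 37 for the right cheek), recorded in output provenance —
reproducibility across runs matters more than matching any particular
historical choice. Rectangles are half-open, 0-based, and are shifted
inward (never truncated) at image edges. Histograms default to 64 uniform
bins over the pooled range of a before/after pair so the pair shares a
scale.

## Uncertainty model

Noise is Gaussian and independent across bands and pixels — the
independence that the \(\sqrt N\) and quadrature rules downstream already
assume. Two scalings of the nominal 2% band uncertainty are supported:

- `"signal"` (default): \(\sigma_R = 0.02\,R\), multiplicative noise on
  reflectance. This is the scaling used by the synthetic generator.
- `"full_scale"`: \(\sigma_R = 0.02\,\rho_w\), a fixed absolute band noise,
  the natural reading of a detector signal-to-noise ratio of ≈ 47 quoted at
  the white reference. Under this scaling the *fractional* noise grows
  where skin reflectance is low — precisely the green region that
  \(a^*\) probes — which is why per-pixel skin-tone uncertainties come out
  markedly larger for \(a^*\) than for \(L^*\), reproducing the ordering
  \(\sigma_{a^*} > \sigma_{b^*} > \sigma_{L^*}\) reported for real skin
  data. Signal-proportional noise cannot reproduce that ordering, so
  typical per-pixel sigma computations use `full_scale`.

The Jacobian is computed by central finite differences with a step of
\(10^{-4}\) in reflectance, robust across the kink of the CIELAB \(f\)
function; a zero spectrum falls on the linear branch and is handled, not
rejected. Tests require agreement with a Monte-Carlo oracle (10⁴ draws)
within 10% relative under both scalings. Reported sigmas are rounded only
at presentation.

## Statistical grouping

`anova_oneway()` accepts raw samples or published group summaries; the
summary path uses the exact decomposition
\(SSB = \sum_i n_i(\bar x_i - \bar x)^2\),
\(SSW = \sum_i (n_i - 1) s_i^2\), so both paths agree to machine precision
when summaries derive from the raw data (and match `stats::aov`, which the
tests verify independently).

`tukey_grouping()` performs all-pairs Tukey HSD with the studentized range
distribution (Tukey–Kramer standard errors for unequal sizes). **Groups
are the maximal cliques of mutually non-significant products** — the
compact-letter-display convention of `multcomp::cld`, against which the
tests cross-check — rather than the transitive closure of non-significant
pairs. The distinction matters: with three products where only the extreme
pair differs significantly, transitive closure collapses everything into
one group and loses the information that the extremes *do* differ, while
the clique convention reports two overlapping groups, matching how mixed
orderings are reported in practice. A product belonging to two groups
appears in each token of the ranking string (e.g. `"BC,CA"`); when groups
are disjoint the string reduces to the familiar partition notation
(`"AC,B"`). Ranking strings order products ascending by mean (most
negative first) and parse back to the group structure with
`parse_ranking()`.

Percent nonlinearity is
\(\%NL = 100\,(\delta_+ + |\delta_-|)/\text{MaxSignal}\) with
\(\delta_\pm\) the extreme residuals about the least-squares line;
MaxSignal is not standardised, so the package uses the largest absolute
ordinate among the pairs (scale-invariant with the numerator) and records
the convention in its output. Spearman ties use average ranks; quartiles
use linear interpolation (`quantile` type 7); whiskers extend to the most
extreme points within \(1.5\,(Q_3 - Q_1)\) of the box.

## The synthetic generator

The generator defines the study conditions; its defaults are fixed once:

- **Skin spectra** are phenomenological: a blue-green baseline
  (0.16–0.28), a melanin-like sigmoidal rise toward the red (amplitude
  0.26–0.38) and hemoglobin-like Gaussian dips at 545 and 575 nm (depths
  0.04–0.08 / 0.03–0.07), drawn per model from a seed. These land in the
  skin-tone region of CIELAB (L\* ≈ 55–65, a\* ≈ 15–21, b\* ≈ 9–15) without
  any biophysical (Kubelka–Munk or photon-transport) modeling.
- **Product effects** are target Lab shifts realised as smooth spectral
  modulations (flat + red lobe + blue lobe) solved by Newton iteration to
  within 0.01 CIELAB units; unreachable targets raise a convergence error
  instead of clipping. Default targets emulate three foundations:
  A ≈ (+0.3, −0.2, +1.1), B ≈ (+3.9, −2.1, −1.2), C ≈ (+1.5, −1.5, −2.0).
- **Between-model effect scatter**: the realised effect adds a persistent
  model-by-product component (SD 1.0 CIELAB units, giving group SDs in the
  0.7–1.5 range typical of foundation panels) plus a repetition-specific
  component (SD 0.25). The persistent part is shared by both operators of
  a session, which is what makes reproducibility (between operators)
  tighter than repeatability (between repetitions).
- **Reproducibility physics**: operators differ by landmark placement
  jitter (SD 3 px). In full spatial mode the face carries a smooth gain and
  red-blue tilt pattern so that jitter genuinely moves the ROI across a
  color gradient; in the fast spectrum-level mode the same systematic is
  emulated as an equivalent per-acquisition Lab jitter (SD 0.12).
- **Noise** is 2% multiplicative Gaussian per band and pixel. Raw-count
  inverse rendering (for calibration testing) is unquantized by default so
  the calibrate → Lab round trip is exact; a `quantize` flag rounds to
  integer counts at the cost of a ≈ 5 × 10⁻⁴ reflectance quantization
  floor.

What the generator does **not** emulate: spatially correlated noise and
fixed-pattern systematics, illumination drift between days, cosmetic film
physics, pose/viewing-angle changes, and photorealistic faces (the
template is a schematic ellipse with a stored 68-point layout). Passing
tests therefore demonstrate the correctness of the analysis chain and the
statistical machinery under the stated noise model — not detector-level
realism.

## Problem sizes and numerical conventions

The test suite exercises the full 9 models × 3 products × 2 repetitions ×
2 operators × 2 time points design (216 acquisitions per study) at the
spectrum level, and reduced spatial cubes (31 × 96 × 96 and smaller, with
proportionally smaller ROIs) for the image pipeline; ranking-recovery and
type-I-error properties use 20 simulated studies and 500–600 null
ANOVA/Tukey draws respectively. Full-frame 31 × 2016 × 2016 cubes are
supported but exercised only through bookkeeping. Reflectance is clamped
to [0, 1.2] (not 1.0) so that specular or noise excursions above the 99%
standard survive for uncertainty analysis; clipped-voxel counts are kept
in provenance. Negative post-dark counts clamp to zero with a warning.
Band order is stored ascending in wavelength. All seeded generation
isolates and restores the caller's RNG state.

## Known limitations

- The ANOVA treats models as independent samples per product, matching the
  screening-test convention; a repeated-measures/mixed-effects variant is
  out of scope.
- Instrument-vs-instrument comparison (imager vs spectroradiometer) is out
  of scope; the design enumerates both but the simulator renders only the
  imager arm.
- The Lab transform is validated against `grDevices::convertColor`; no
  independent *spectral* reference implementation is available, so the
  spectrum → XYZ stage is validated against direct quadrature and its
  linearity/white-point invariants instead.
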