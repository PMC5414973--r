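---
title: "Quantifying whole-specimen fluorescence: models, defaults, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-specimen fluorescence: models, defaults, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorquant)
```

## The measurement problem

Externally expressed fluorescence in small arthropods — here, the crab
spider *Misumena vatia* design with five sex/life-stage groups — cannot be
separated from reflectance by ordinary spectrophotometry: the detector
cannot tell a reflected photon from an emitted one. The workaround this
package implements computationally is the photographic route: excite the
specimen with a narrow-band UV LED behind a dichroic beam splitter (plus an
optional long-pass blocking filter), capture 12-bit black-and-white images
in which *only* emission light reaches the camera, and score fluorescence
from pixel intensities inside manually traced areas of interest (AOIs).
Around that core sit three supporting computations: a photon-dose
calibration that makes the LED exposure ecologically meaningful, rank-based
group comparisons suited to small, zero-inflated samples, and
reflectance/emission spectrum processing for the qualitative color context.

`fluorquant` implements the full pipeline and, because the original imagery
is not redistributable, ships a synthetic-data generator with known ground
truth so that every stage can be validated end to end.

## Image quantification

A `gray_image` is a non-empty integer raster with values in $[0, 4095]$
(4096 gray levels; 12-bit data carried in 16-bit TIFF containers). Reading
a file with any sample above 4095 is a hard error rather than a silent
clamp: it is the cheapest way to catch a wrong-depth export.

**AOI rasterization.** An AOI is a closed polygon in 0-based pixel-center
(row, col) coordinates. A pixel belongs to the mask iff its center
satisfies the even-odd (crossing-number) rule; centers lying exactly on an
edge count as inside. This rule was chosen because it is deterministic,
orientation-independent, and easy to check against a brute-force
point-in-polygon loop, which the test suite does on every release.

**Scores.** Two scores are computed per body part:

* *mean pixel intensity* — the arithmetic mean of masked pixel values;
* *percent in brightest category* — the gray range is split into ten equal
  categories of 409.6 levels via $\mathrm{bin}(v) = \lfloor 10 v / 4096
  \rfloor + 1$, the ten bins are grouped into dim (1–3), medium (4–7) and
  bright (8–10) classes, and the score is the percentage of masked pixels
  in the brightest category.

Two conventions here are genuinely underdetermined by the field protocol
and are therefore explicit options rather than silent guesses:

* **Which bins are "brightest".** The default takes the whole bright class
  (bins 8–10); `binning_scheme(brightest = "top_bin")` restricts to bin 10.
  The dim/medium/bright membership itself is configurable.
* **How three AOIs combine into one body-part value.** The default
  `combine_rule = "mean_of_aois"` averages the three per-AOI values, which
  is robust to unequal AOI areas; `"pooled"` pools all masked pixels first.
  The reported histogram is always the pooled one, so its counts sum to
  `n_pixels` either way.

## Photon-equivalent exposure calibration

The LED dose is anchored to sunlight by photon count, not energy: with
absolute irradiance $E(\lambda)$ in µW·cm⁻²·nm⁻¹, the photon flux over a
band is

$$\Phi = \int_{\lambda_{lo}}^{\lambda_{hi}}
  \frac{E(\lambda)\,10^{-6}\,\lambda\,10^{-9}}{hc}\, d\lambda
  \quad [\text{photons·cm}^{-2}\text{·s}^{-1}],$$

integrated by the trapezoidal rule on the spectrometer's native grid (with
interpolated band endpoints; spectrometer exports are near-uniform grids,
so no resampling is performed by default). The equivalent exposure is then
`sun_reference_time × Φ_sun / Φ_led`. Physical constants are the SI exact
values $h = 6.62607015\times10^{-34}$ J·s, $c = 2.99792458\times10^8$
m·s⁻¹.

"At 340 nm" does not pin down a bandwidth, so the band is exposed as a
parameter: the default is a fixed $[330, 350]$ nm window around the
excitation line, and `led_support_band()` offers the alternative reading —
integrate wherever the LED emits above 1 % of its peak. The two agree for a
narrow LED up to the sliver of flux outside the window.

The calibration checks are closed-form by necessity: the original input
spectra exist only as published figures, so the validated properties are
the exact identity case (identical spectra → the reference time back), the
linear scaling law (a 1170:1 flux ratio turns 0.1 s into 117.0 s), and
invariance under joint rescaling of both spectra.

## Group comparisons

Sample sizes of 4–15 per group and percent scores with many exact zeros
(specimens with *no* pixels in the brightest class) rule out normal-theory
tests. The pipeline uses:

* **Kruskal–Wallis omnibus test** per body part, with midranks for ties and
  the tie-correction factor $1 - \sum(t^3 - t)/(N^3 - N)$, referred to
  $\chi^2_{k-1}$. The all-tied input (possible under heavy zero inflation)
  degenerates to $H = 0$, $p = 1$ with a warning flag instead of `NaN`.
  The omnibus computation is delegated to `stats::kruskal.test()`; the test
  suite verifies it against an independently coded rank-sum formula and,
  for total $N \le 8$, against the exact permutation distribution of $H$
  by exhaustive enumeration. The chi-square approximation at those sizes is
  coarse (absolute p-error up to roughly 0.1, worst for two tiny groups);
  that error is a property of the approximation, not of the implementation.
* **Dunn's post-hoc pairwise tests**, coded from the reference formula
  $z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T/(12(N-1)))
  (1/n_i + 1/n_j)}$ with two-sided normal p-values, run "where appropriate"
  — by default only where the omnibus test is significant at $\alpha$, with
  a `force_posthoc` override because published practice is not always
  consistent on this point.
* **Multiple-comparison adjustment.** The adjustment behind the original
  tables is unstated, but their many exact `1.000` entries imply a
  capped-at-1 family-wise method; the default is Bonferroni over all pairs
  within a body part, with Holm, Šidák and none selectable and the choice
  recorded in the output metadata. Adjusted pairwise p-values are therefore
  a method-dependent surface, and the package treats them as such.

`assemble_study_tables()` assembles the per-body-part omnibus table
(columns $X^2$, $X^2_{crit}$, df, p, star) and pairwise matrices. Degrees
of freedom fall out of the design: 4 for abdomen and cephalothorax (five
groups), 3 for right leg 1 (immature legs are never measured). p-values
below $10^{-4}$ are *displayed* as `<< 0.001`; full precision is kept in
the machine-readable output.

## Spectrum processing

Reflectance follows the spectrometer protocol hierarchy: ten readings
average into one measurement, four measurements average into one specimen
curve — unweighted at both levels, so an unbalanced design still weights
measurements equally rather than pooling readings. (A published figure
caption describes a flat ten-measurement average; the hierarchy here
follows the instrument protocol, and a flat average can be had by setting
one level's count to 1.) Mismatched wavelength grids are an alignment
error, never silently interpolated, because grid mismatches usually mean
different instrument configurations. Group curves are unweighted means
across specimens. Emission spectra are max-normalized (peak = 1), and
`emission_band()` reports the wavelength range above a fractional
threshold with linear interpolation between grid points — invariant under
normalization by construction.

Reflectance output is deliberately descriptive (curves and bands, no
hypothesis tests): the source protocol treats reflectance qualitatively.

## The synthetic-data generator

The generator emulates the study conditions, not arbitrary data:

* **Design.** Five groups with the beam-splitter-subset sizes 10/5/4/9/9 by
  default; abdomen, cephalothorax and right leg 1 (legs absent for
  immatures); three AOIs per part; both filter configurations.
* **Brightness.** Group emission means (12-bit levels) default to
  2000/400/2200/1100/1500 for adult female / adult male / penultimate
  female / penultimate male / immature, with dispersions 250–500. These
  encode the published qualitative ordering — females brightest, adult
  males dimmest by a wide margin — at an effect size large relative to the
  dispersions, as the original bar charts show; no quantitative means are
  published, so the levels are stand-ins, not estimates.
* **Distributions.** Pixel values and specimen-level means are truncated
  normals on $[0, 4095]$ (exact inverse-CDF sampling); percent-in-brightest
  draws are zero-inflated Beta scaled to $[0, 100]$, zero with probability
  0.05–0.60 by group (males most zero-prone). These families match the
  bounded, zero-inflated *structure* of the real scores without claiming
  their true distribution, which is unknowable from the published record.
* **Rendered images.** Each body part is a filled ellipse (round for body
  segments, elongated for the femur) over a dim background. A specimen
  first draws its own emission mean from the group distribution; pixel
  noise is then added per pixel. With the group's zero-inflation
  probability the specimen has no bright patch; otherwise a concentric
  sub-ellipse covering a Beta-drawn fraction of the body is painted at
  `bright_patch_level` (default 3300, inside the bright bins), which is
  what gives the *image-derived* percent score its zero-inflated,
  group-ordered structure. AOI polygons are placed analytically inside the
  ellipse, so the traced-on-white-light step is emulated without a
  segmentation stage.
* **Determinism.** One master seed; every specimen × part × filter draw
  uses a substream derived by a stable FNV-1a hash of its identifiers, so
  results are byte-identical across runs *and* independent of generation
  order.

What the generator does **not** emulate: camera physics (read noise,
vignetting, flat-field error), anatomical shape, UV reflectance, or any
correlation between body parts within a specimen beyond the shared group.
Passing tests on synthetic data therefore demonstrate that the measurement
and inference machinery is correct under the assumed statistical structure
— not that the biological conclusions would replicate on new specimens.

## Problem sizes and numerical choices

The validation suite runs the quantification oracle on 500 random 16×16
images, the permutation oracle on layouts of total $N \le 8$ (at most 560
assignments), power simulations on 200 replicates of 5 × 10 specimens, and
null calibration on 2000 replicates — sizes chosen so the full suite and
the acceptance script each complete in a couple of minutes on one core
while leaving the Monte-Carlo error well inside the asserted bounds
(e.g. the 99 % binomial band around 0.05 at 2000 replicates is ±0.013).
Renders default to 96×96 pixels, the smallest size at which every body
ellipse and its three AOIs fit with margin.

Other numerical choices: AOI boundary pixels are inside (ties broken
toward inclusion, deterministically); the all-tied rank test returns the
degenerate $H = 0, p = 1$ rather than an error so batch runs survive
pathological groups; percent scores from an empty mask are an error, never
0/0; the supplementary-table converter reports per-group counts exactly as
found in its input and never reconciles them against published captions,
which themselves disagree in places.

## Known limitations

* The original 117-s exposure figure cannot be recomputed independently —
  its inputs survive only as plots — so calibration correctness rests on
  the closed-form and invariance properties above.
* Workbook ingestion expects per-tab CSV/TSV exports rather than the
  legacy binary spreadsheet format.
* The pairwise p-values of the original tables depend on an unstated
  adjustment method; with Bonferroni the package reproduces their
  qualitative pattern (capped 1.000 entries, the same significant pairs in
  synthetic reconstructions), but exact numerical agreement on pairwise
  p-values is not a supported target.
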