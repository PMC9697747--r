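---
title: "Hyperspectral tooth colorimetry: models, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral tooth colorimetry: models, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothshade)
```

## The measurement model

A line-scan hyperspectral camera records, per pixel $(x, y)$ and band
$\lambda$, counts

$$I_{raw}(x,y,\lambda) = D(x,y,\lambda) + g(x,y,\lambda)\,R(x,y,\lambda) + \varepsilon$$

where $D$ is the dark offset, $g$ collects the illumination field, optics
and sensor response, and $R$ is the surface reflectance we want. Two
companion captures with identical settings — a covered-lens dark frame and
a matt gray ceramic tile of known reflectance $R_{tile}(\lambda)$ — let the
flat-field correction cancel both nuisance fields:

$$R(x,y,\lambda) = \frac{I_{raw}-I_{dark}}{I_{gray}-I_{dark}}\,R_{tile}(\lambda).$$

Because the same $g$ multiplies numerator and denominator, the estimate is
invariant to *any* positive per-pixel, per-band illumination gain — the
property the test suite asserts directly with five random gain fields.
Negative numerators (noise below dark) are floored at 0. Pixels whose
denominator magnitude falls below $\epsilon$ (default $10^{-6}\times$ full
scale) in any band cannot be corrected reliably; they get reflectance 0
there, are flagged `unstable_reference`, and — like saturated pixels — are
excluded from every downstream mean. Reflectance above 1 (specular
highlights brighter than the gray tile) is *retained* and counted via
`reflectance_overshoot()`, never clipped: masking specular areas is a
user decision, and clipping would silently hide them. Only the lower bound
0 is enforced, at colorimetric integration.

## Colorimetry

Tristimulus values use the CIE 1931 2° standard observer and the D65
illuminant, bundled as the standard 10 nm tabulation over 380–780 nm and
resampled onto the camera grid by piecewise-linear interpolation (the
camera's ~3 nm grid is much finer than the structure of the observer
functions, so linear resampling is adequate; a fine-vs-coarse-grid test
bounds the discrepancy below 0.2 in Y). Integration weights are
trapezoidal, so non-equidistant camera grids are handled correctly, and
$k = 100 / \sum S\,\bar y\,\Delta\lambda$ makes a perfect reflector yield
$Y = 100$ exactly by construction.

Cameras of this class cover 400–1000 nm; the observer functions vanish
outside the visible, so cubes are cropped to the intersection of the
camera bands with 400–780 nm before conversion (`crop_spectral_range()`).
Bands above 780 nm carry no colorimetric information and are ignored for
color.

The CIELAB transform uses the exact rational constants
$\epsilon = 216/24389$, $\kappa = 24389/27$; the white point is the
tristimulus of $R \equiv 1$ under the same table, so neutral spectra map
to $a^* = b^* = 0$ identically.

### Color differences

$\Delta E^*_{ab}$ is the Euclidean Lab distance. CIEDE2000 follows the
published worked procedure step by step: G-factor chroma rescaling with
the $25^7$ term, hue angles in degrees with the 0/360 conventions,
$\Delta H' = 2\sqrt{C'_1 C'_2}\sin(\Delta h'/2)$, weighting functions
$S_L, S_C, S_H$, and the rotation term $R_T$. The mean-hue branch rules
are the usual ones; a hue difference of exactly 180° falls under the
$\le 180°$ rule and takes the direct arithmetic mean. Correctness is
established against an independently coded, literal transcription of the
step list (written before the implementation) on 1000 seeded random Lab
pairs, to $10^{-6}$ — the stringent check, since published studies print
no CIEDE2000 intermediates.

One property worth recording: $\Delta E_{00}$ is monotonically
non-increasing in $k_L$ (which enters only the pure lightness term), and
scaling all three parametric factors by $s$ divides the value exactly by
$s$ — but it is *not* monotone in $k_C$ or $k_H$ individually. For
blue-region pairs the rotation term $R_T$ approaches $-1.7$ and the
negative cross term can shrink more slowly than the damped squares, so
raising $k_C$ alone can raise $\Delta E_{00}$. The tests assert the
provable properties only. Defaults are $k_L = k_C = k_H = 1$, the
reference condition.

Verdicts compare each value with the 50:50% dental thresholds
(PT: $\Delta E^*_{ab} = 1.2$, $\Delta E_{00} = 0.8$;
AT: $\Delta E^*_{ab} = 2.7$, $\Delta E_{00} = 1.8$). A value exactly on a
threshold classifies into the higher category: at PT half of observers
perceive the difference, so "perceptible" is the conservative call.
Report values are rounded half-up to 2 decimals, matching how such
results are conventionally printed.

## Regions and statistics

Row 1 of an image is the top, which in the chin-rest capture geometry is
the cervical (gingival) side. This orientation is fixed once and used
everywhere; flipping an image vertically provably swaps the cervical and
incisal thirds. The tooth axis is assumed aligned with the image columns
(the chin rest guarantees this); no rotation estimation is attempted.

The tooth mask gates on $L^* \ge 45$ and chroma
$\sqrt{a^{*2}+b^{*2}} \le 40$ — enamel is bright and weakly chromatic,
gingiva and lips darker and redder — then keeps the largest 4-connected
component, which selects a single tooth per call. Externally drawn masks
can replace this step entirely. Thirds are defined by equal division of
the mask's *bounding rows* (split at $r_0 + \mathrm{round}(h/3)$ and
$r_0 + \mathrm{round}(2h/3)$), not equal pixel counts: that matches the
anatomical depiction of thirds and is deterministic. The three outputs
always partition the mask.

Per-third colors are the arithmetic mean and SD of $L^*, a^*, b^*$ over
valid pixels, averaged *in Lab space* — not spectra-first-then-convert.
The two differ because the transform is nonlinear; mean-Lab is the
convention in which per-third tooth colors are reported, so comparisons
remain commensurable. Specular-highlight exclusion by an upper $L^*$
percentile is available but off by default.

The overall difference between two teeth is the unweighted mean of the
three per-third $\Delta E$ values, each computed between per-third mean
colors (a difference of means, not a mean of per-pixel differences).
"Overall" is rarely given an explicit definition in the shade literature;
this rule is adopted because, applied to the reference per-third means in
`table1_fixture()`, it reproduces every published whole-tooth value
(0.57, 0.58, 7.42, 7.39 for $\Delta E^*_{ab}$; 0.48, 0.45, 5.74, 5.71 for
$\Delta E_{00}$) exactly at 2 decimals, so it is evidently the operative
definition. The acceptance script recomputes all of these at run time.

## The synthetic scene generator

Raw captures of in-vivo teeth are not publicly deposited, so validation
rests on a forward model with exact ground truth:

- **Tooth spectra**: $R(\lambda) = \mathrm{clip}(base + amp/(1 +
  e^{-(\lambda-edge)/slope}), 0, 1)$ — a monotone edge spectrum, the
  simplest shape that reproduces enamel's rising red/NIR reflectance. The
  per-third presets make the cervical third redder and yellower (later,
  steeper edge; lower base) and the middle third lightest, and centrals
  brighter and less chromatic than laterals — the anatomical pattern.
  Parameters blend linearly between third centers so the gradient is
  smooth across third boundaries.
- **Layout**: four non-overlapping rectangles (centrals 60×90 px,
  laterals 45×80 px at 512×512, scaled proportionally), background a dark
  reddish gingiva placeholder. Rectangles keep the truth masks trivial;
  tooth-shaped outlines would change nothing the pipeline is sensitive to.
- **Illumination**: centered Gaussian vignette of amplitude 0.3 and a
  linear ±10% spectral tilt — exactly the nuisance the flat-field
  correction exists to remove.
- **Sensor**: 12-bit full scale (4095), dark level 100 counts, gain 3500
  counts per unit radiance (peak tooth signal ≈ 3100 counts: good
  exposure, no saturation), additive Gaussian noise of sd 20 counts
  (≈ 1% of a typical tooth signal), truncated to $[0,$ full scale$]$.
  Additive Gaussian noise without shot-noise scaling is deliberate: it is
  the simplest model that exercises robustness, and no sensor noise
  characterization exists to calibrate anything richer.
- **Truth**: the noise-free reflectance cube, the per-tooth masks and
  thirds, and noise-free Lab profiles computed through the *same*
  observer table as the pipeline under test — so zero-noise recovery is
  an exact end-to-end identity, verified to $10^{-9}$.

What the generator does **not** emulate: translucency and edge-loss at
the incisal margin, specular highlights, inter-subject variability (the
reference SDs are across 30 participants, not pixels; within-third pixel
variability in vivo is unknown and is a free parameter here), tooth
curvature, and gingiva spectra beyond a flat reddish placeholder. Passing
recovery tests therefore demonstrate the *pipeline's* correctness, not
that real enamel behaves like a sigmoid.

Tests run the generator at 128×128 px with 60 bands (and smaller), which
preserves every code path of the full 512×512×204 configuration while
keeping the suite fast; ≥ 75 pixels per third keep the noisy-recovery
error well inside the ΔE*ab ≤ 0.5 budget. Determinism is per-seed: the
RNG state is saved and restored around rendering, so a scene is
bit-reproducible without disturbing the caller's stream.

## Numerical choices and degenerate inputs

- ENVI I/O supports uint16 counts and 32/64-bit float reflectance; other
  type codes are rejected outright rather than half-supported. Round-trips
  are bit-exact for uint16/float64 across all interleaves and byte orders.
- Spectrum resampling is piecewise-linear and refuses to extrapolate by
  default; constant end-extension is available explicitly.
- Empty masks, thirds with zero valid pixels, masks under 3 rows tall,
  mismatched wavelength grids and overlapping tooth placements all raise
  immediate, specific errors instead of propagating NaN.
- `round_half_up()` carries a $10^{-9}$ guard so decimal halves that are
  not exactly representable in binary (0.565 stores just below its
  nominal value) still round up as printed arithmetic expects.

## Known limitations

Thirds are delimited geometrically; a clinician outlining thirds by
anatomy may place the boundaries differently. The reader targets standard
ENVI headers; vendor dialects with non-standard keys are carried through
`meta` untouched but not interpreted. Only the 2°/D65 condition ships
bundled; other observers or illuminants require supplying a replacement
table. No statistical inference across subjects is provided — the package
computes descriptive means, SDs and threshold verdicts.
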