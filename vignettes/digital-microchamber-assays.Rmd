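---
title: "Digital microchamber assays: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital microchamber assays: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digitalchip)
```

## The measurement model

A digital nucleic-acid assay partitions a sample across an array of
femtoliter microchambers so that each chamber holds 0, 1 or occasionally
more template molecules. After isothermal amplification, chambers that
held at least one template light up in a fluorescence channel; the
*fraction* of positive chambers carries the absolute concentration with
no calibration curve.

Loading is Poisson. With template concentration $c$ (mol/L), chamber
volume $V$ (L) and Avogadro's number $N_A$, the expected occupancy per
chamber is

$$\lambda = c \, V \, N_A ,$$

and the occupied fraction is $1 - e^{-\lambda}$. The assay's forward
estimator is the linear rule

$$\hat c_E = \frac{\lambda_\mathrm{exp}}{V N_A},$$

where $\lambda_\mathrm{exp}$ is the observed positive fraction. This is
what `estimate_concentration()` implements, and it is the default
everywhere because it is the estimator the assay protocol defines. It
ignores multiple occupancy: its relative bias is
$f / (-\ln(1-f)) - 1$, under 5 % for $f \lesssim 0.1$. The exact
inversion $\hat c = -\ln(1 - f) / (V N_A)$ is available as
`estimate_concentration_poisson()`, is always labelled
`poisson_corrected` in outputs, and errors at $f = 1$ (a saturated chip
cannot be quantified; dilute).

Chambers are cylinders: $V = \pi (d/2)^2 h$. The defaults $d = 4.2$ µm
and $h = 3.15$ µm are the midpoints of the fabricated ranges
(4.0–4.4 µm and 3.0–3.3 µm), giving $V \approx 43.6$ fL. At one
positive among 10,000 chambers the linear estimator reads ~4 fM; at
full occupancy ~40 pM — the instrument's nominal dynamic range. Volume
enters every concentration inversely, so per-chip measured $d$, $h$
should be supplied when available.

## Image analysis

**Detection.** Chambers are found in the *reference* channel, where a
reference dye fills every chamber: each appears as a bright disk of
about 10 px on a square lattice (9 µm pitch at 0.42 µm/px ≈ 21.4 px).
The detector is deliberately parameter-light, matching what a
well-built ImageJ macro would do on such data: a difference-of-Gaussians
band-pass at the chamber scale ($\sigma_1 = d_\mathrm{px}/4$,
$\sigma_2 = 2\sigma_1$), local maxima over a neighbourhood of half the
minimum separation, an adaptive response floor (median + 30 % of the
median-to-maximum span — scale-free, and empty images therefore return
zero detections rather than noise peaks), greedy merging of candidates
closer than the minimum separation (brighter wins), and removal of any
chamber whose 16 × 16 crop would cross the image border. The minimum
separation defaults to $0.6 \times$ pitch. Centres are reported at
local-maximum pixels (integer positions); subpixel refinement is
deliberately out of scope since all downstream measures use ≥ 81-pixel
supports. A lattice-refinement step (`refine_chamber_grid()`) can
resurrect rare missed nodes but is off by default.

**Features.** Two features per chamber, both computed from *raw*
intensities — the moment formulas use the pixel values directly, so no
background subtraction is applied by default:

- mean intensity over a circular ROI of 10 px diameter (pixels whose
  centres lie within $d/2$, boundary inclusive);
- the radius of gyration (ROG) of the 16 × 16 crop,
  $\mathrm{ROG} = \sqrt{(m_{20} + m_{02}) / m_{00}}$ with central
  second moments about the crop centre $(7.5, 7.5)$.

A uniform 16 × 16 crop has ROG $\sqrt{42.5} \approx 6.52$; a
chamber-sized bright disk sits near $R/\sqrt 2 \approx 3.5$–4.2. Note
the uniform value is *not* a global maximum over arbitrary images
(mass concentrated at crop corners can reach $\sqrt{112.5} \approx
10.6$); it is an upper bound on the physically occurring family
"background plus centred spot", which is what makes it usable as a
gate.

**Classification** is a two-stage logic tree:

1. ROG gate: `rog > rog_threshold` → negative. Diffuse signal that
   fills the crop — empty chambers, or large autofluorescent objects
   like bubbles and aggregates — fails here no matter how bright.
2. Intensity gate: remaining chambers are positive iff mean intensity
   strictly exceeds `mean + k_sd * SD` of the negative control
   (`k_sd = 15` by default). Ties are negative: strict comparisons are
   the conservative choice for a diagnostic count.

The intensity SD comes from a least-squares Gaussian fit to the
Freedman–Diaconis histogram of negative-control intensities
(`minpack.lm::nlsLM`), not from plain moments: the histogram fit locks
onto the dominant mode, so a few percent of bright contaminants in the
control do not inflate the threshold. On fit failure the fallback is
median and $1.4826 \times$ MAD with a warning; a zero-spread sample is
rejected. Inside the pipeline only, zero spread (which arises in
noise-free simulations) falls back to "threshold = maximum negative
intensity", so ideal renders still classify exactly.

The ROG threshold is nowhere published as a number; the default 5.5 px
sits midway between the uniform-crop limit (≈ 6.52, what negatives and
crop-filling artifacts give) and the chamber-disk band (≈ 3.5–4.2),
and is exposed as a parameter throughout.

Manual exclusion of by-eye false positives is supported only as an
explicit id list (`apply_exclusions()`, `--exclude ids.txt`): excluded
chambers leave both the numerator and denominator of the positive
fraction, raw totals remain reported, and nothing is ever excluded
automatically — that keeps analyses reproducible.

## Time-lapse metrics

With frames every 2 min, two clinically motivated times are reduced
from the positive-count curve:

- **detection time** — the earliest time the count *exceeds* 10
  (≈ 0.1 % of a 10,000-chamber field), under the precondition that the
  first frame has ≤ 2 positives (violations warn but still compute);
- **quantification time** — the first time after detection at which
  the consecutive-frame change falls below 20 % of the previous count.
  Pairs with a zero previous count are skipped (the rule's denominator;
  real series never hit this, simulations can).

Both rules use earliest-match semantics, so appending frames after the
quantification time changes neither. Thresholds for time-lapse series
come from the series' own first frame (nearly all chambers are then
pre-onset, i.e. a built-in negative control), not from a separate chip.

## The synthetic chip generator

The simulator exists so every stage above can be tested against known
truth. It emulates the statistical structure the analysis assumes:

- **Loading**: per-chamber template counts Poisson($\lambda$) from the
  input concentration and chamber volume; an occupied chamber amplifies
  with probability `amplification_efficiency` (default 1 — the paper-gap
  assumption that amplification from an occupied chamber always
  succeeds; the knob exists because real per-target efficiencies vary by
  up to an order of magnitude).
- **Kinetics**: positives turn on as a logistic
  $\mathrm{baseline} + (\mathrm{plateau}-\mathrm{baseline})\,
  \sigma((t - t_\mathrm{onset})/\tau)$ with onset
  $\mathcal N(10, 3^2)$ min truncated at 0 and $\tau = 2$ min. These
  defaults are simulator knobs chosen so that synthetic time courses
  qualitatively match observed behaviour (onsets spread over roughly
  8–22 min, detection well before saturation); they are not measured
  reaction constants.
- **Rendering**: every chamber is a soft-edged disk (error-function
  profile, 0.5 px edge SD ≈ 1 px of optical blur; no full PSF model);
  reference channel amplitude 500 a.u. over a 100 a.u. background,
  signal channel from the kinetics. Images are 16-bit; the grid is
  surrounded by a ≥ 8 px margin so every crop fits.
- **Noise**: Poisson shot noise (pixel values treated as photon
  counts), additive Gaussian read noise (default SD 5 a.u.), applied
  after rendering. The real camera's bit depth and per-chamber SNR are
  not published, so these defaults are plausible rather than
  calibrated — conclusions that depend on absolute SNR should scan
  `read_noise_sd`.
- **Artifacts**: Poisson-distributed large diffuse Gaussian blobs
  (30–80 px, i.e. always larger than a chamber) in the signal channel,
  emulating autofluorescent bubbles/aggregates. They are physical
  objects, so a time series samples them once and keeps them fixed
  across frames, and the truth table flags chambers under them.

What the simulator does *not* emulate: reaction chemistry and its
temperature dependence, spatially varying illumination or focus,
chamber-to-chamber volume variation, and camera fixed-pattern noise.
Tests passing on synthetic chips therefore validate the *analysis
logic* — detection geometry, moment arithmetic, threshold logic,
estimator algebra — not instrument-specific robustness.

Randomness is driven by one integer seed per operation with a
documented draw order (loading: counts, then amplification, then
onsets; rendering: artifacts under `seed`, pixel noise under
`seed + frame index`), which makes truth tables and images bit-identical
across runs with equal seeds.

## Numerical and convention choices

- Coordinates are 0-based with pixel-centre positions; matrices are
  indexed `[y + 1, x + 1]`.
- Crop start index is `round(center - (crop_size - 1)/2)` with base R's
  round-half-to-even, so a centre at (50, 50) crops columns/rows 42..57
  and the centre maps to crop coordinate (7.5, 7.5) up to rounding.
- ROI membership is inclusive (distance ≤ radius).
- An all-zero crop has undefined ROG; such chambers are negative.
- Detected centres are sorted row-major (y, then x); `roi_id` is the
  rank in that order.

## Problem sizes used in validation

The bundled tests run chips of 100–900 chambers for pipeline
properties (20 artifact seeds, translation shifts, determinism
re-runs), 10,000 chambers for occupancy and end-to-end concentration
recovery, and $10^5$ chambers for the Poisson-occupancy law; the
acceptance script averages ten 10,000-chamber chips. These sizes give
binomial standard errors of ~3 % on the recovered concentration per
chip, an order of magnitude below the effects being checked.

## Known limitations

- The linear estimator is biased upward of $f \approx 0.2$; the
  package reports the corrected value alongside but will not silently
  switch to it.
- Detection assumes an approximately regular bright-disk lattice; it is
  not a general spot detector and has no dewarping or field
  flattening.
- Intensity thresholds are per-image; no normalisation across fields
  of view is attempted.
- ROG gating removes chambers genuinely covered by an artifact even if
  they are true positives; on artifact-dense images this is a (correct,
  conservative) source of undercounting.
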