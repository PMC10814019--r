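---
title: "Quantitative microvessel imaging of choroidal tumors: models and methods"
author: "choromvq"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Quantitative microvessel imaging of choroidal tumors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Choroidal melanoma and choroidal nevus can look alike when small, yet the
malignant lesion grows new, structurally abnormal microvessels: wider,
more tortuous, more densely branched, more geometrically complex.
Contrast-free quantitative high-definition microvessel imaging (qHDMI)
makes this vasculature measurable with ultrafast power-Doppler
ultrasound: a 1-second ensemble of compounded plane-wave frames is
clutter-filtered, formed into a power-Doppler image, enhanced, binarized
and skeletonized, and the skeleton graph is summarized by twelve
morphological biomarkers that are then compared between malignant and
benign groups.

Patient data for this analysis are restricted, so `choromvq` implements
the entire chain *and* a synthetic-data layer that emulates its study
conditions: ground-truth vascular trees, ultrafast IQ ensembles over
them, and cohort tables whose marginal moments match the published group
summaries.  Every stage is therefore testable end to end without any
download.

# Signal model

Post-beamformed IQ data are modeled as tissue + blood + noise
(`simulateIQ()`):

* **Tissue clutter** is a spatially smooth complex field multiplied by a
  slow unit-modulus phase drift (default 2 Hz) — a rank-1 component of
  the Casorati matrix, typically 30 dB above blood.
* **Blood** is Rayleigh-amplitude speckle confined to the lumen
  occupancy; each pixel rotates at its Doppler rate
  $f_D = 2 v_{\mathrm{axial}} f_c / c$.  The amplitude is frozen over
  the ensemble (the minimal model sufficient for rank-based clutter
  separation); real blood decorrelates, so real power-Doppler speckle is
  smoother than the simulated one.
* **Noise** is circular complex white noise, default 20 dB below blood
  power.

All three are convolved with a Gaussian point-spread function (default
$\sigma = 1$ px at 50 µm/pixel, i.e. a FWHM of roughly 120 µm,
consistent with a 16.5 MHz linear array).  Exceeding the Nyquist rate
$|f_D| > \mathrm{PRF}/2$ triggers a warning, not an error.

# Reconstruction

`runHDMI()` composes four provenance-recorded steps:

1. **SVD clutter filtering** on the Casorati matrix (pixels × frames):
   singular components up to `rank_low` are discarded as tissue, those
   above `rank_high` (default 90% of full rank) as noise.  The default
   `rank_low = 2` is meant for real acquisitions; because the simulated
   clutter is *exactly* rank-1, the reduced-size demonstration
   configuration (`demoRunConfig()`) uses `rank_low = 1` — with
   `rank_low = 2` the second component strips most of the blood signal
   of simple, nearly-straight vessels whose Doppler signature is itself
   close to rank-1.
2. **Power Doppler**: per-pixel temporal mean of $|s|^2$.
3. **Log compression** (display-domain dB mapping with a 25 dB dynamic
   range; values further below the image maximum clip to zero).  This
   equalizes speckle-induced brightness variation along vessels — the
   tubularity filter below normalizes its structureness term by the
   *image-wide* maximum, which would otherwise suppress dim vessel
   stretches — while the clipping keeps the noise floor out of the
   enhanced image.  Disable with `log_compress = FALSE`.
4. **Vessel enhancement** (`enhanceVessels()`): a white top-hat with a
   disk (default radius 8 px at full scale, 6 px in the demo
   configuration) removes residual background, then a multiscale
   Hessian tubularity filter with $\beta = 0.5$,
   $c = \max(S)/2$ per image, $\sigma^2$-normalized derivatives and
   scales $\{1, 1.5, 2, 3, 4\}$ px spans lumen radii of roughly
   100–400 µm at 50 µm/pixel.  Bright-ridge polarity: responses with
   $\lambda_2 > 0$ are zeroed.

# Segmentation and morphometry

`binarizeVessels()` thresholds within the ROI only (Otsu by default,
fixed quantile as an option) and then applies a cleanup chain tuned for
sparse tubular foregrounds, in this order:

* a **threshold floor** at 10% of the ROI dynamic range (with very
  sparse vessels Otsu can otherwise split the background cluster);
* **hysteresis growing** of the Otsu seeds into connected pixels above
  1/3 of the threshold (a single hard cut truncates dim vessel
  stretches because the vesselness histogram of a vessel is itself
  right-skewed);
* **small-object removal** *before* closing, so closing cannot weld
  scattered noise blobs into spurious networks;
* a **disk closing** (radius 2 px) that bridges speckle dropouts and
  the junction gaps left by the tubularity filter (its blobness term
  attenuates junctions by $e^{-2}$);
* **small-hole filling** (≤ 16 px): interior speckle nulls would
  otherwise produce ring-shaped skeletons, i.e. phantom loops.  Large
  enclosed regions are genuine background and stay open.

`skeletonizeVessels()` thins the mask to one pixel (Guo–Hall thinning,
which unlike Zhang–Suen leaves unit-width diagonals), clusters junction
pixels with ≥ 3 skeleton neighbors within a 2 px Chebyshev radius into
single branch points, prunes junction-attached spurs shorter than 4 px,
and decomposes the remainder into maximal node-free segments with a
per-pixel diameter profile (twice the Euclidean distance transform of
the mask).  The clustering radius and pruning length are exposed in the
configuration because they define what counts as a vessel segment and a
branch point; an X-shaped crossing, for instance, is one clustered
junction with four arms.

The twelve biomarkers follow the field's definitions:

| biomarker | definition | aggregation |
|---|---|---|
| VD | vessel area fraction of the ROI | — |
| NV | number of skeleton segments | — |
| NB | number of clustered branch points (≥ 3 incident segments) | — |
| D | per-segment mean diameter (µm) | mean, max |
| τ | path length / endpoint chord | mean, max over segments |
| MD | $\lvert d_p^3 - \sum_i d_i^3\rvert / d_p^3$ at a junction | mean, max over junctions |
| BA | angle between the two daughter vessels (°) | mean, max over junctions |
| mvFD | box-counting slope of the skeleton | — |

Numerical conventions that required a decision:

* **Tortuosity path length** uses the Vossepoel–Smeulders corrected
  chain-code estimator (0.980 per orthogonal step, 1.406 per diagonal
  step, −0.091 per direction change) rather than raw $1/\sqrt2$ steps:
  the raw chain metric overestimates curved digital arcs by ≈ 5%
  independently of scale, which a half-circle oracle exposes
  immediately.  τ is floored at its theoretical minimum of 1, so
  straight segments measure exactly 1.  Segments that start and end at
  the same node, or whose chord is under 2 px, are excluded (a chord of
  zero is undefined; near-zero chords are degenerate loops).
  `method = "chain"` restores the raw metric.
* **Murray's deviation** fixes the exponent at 3 (configurable), takes
  the incident segment with the largest near-junction diameter as the
  parent, and averages diameters over the k = 5 skeleton pixels nearest
  the junction.
* **Bifurcation angle** uses unit vectors from the junction to the 5th
  skeleton pixel of each daughter; with more than two daughters the
  maximum pairwise angle is reported.
* **mvFD** is computed on the skeleton by default (`fd_source =
  "mask"` switches to the filled mask) over dyadic box sizes; the
  least-squares slope of $\log N$ vs $\log(1/\epsilon)$ is exact on
  grid-aligned lines (1) and filled blocks (2).
* **Structural missingness**: MD and BA are unmeasurable exactly when
  NB = 0; `computeBiomarkers()` carries this as `measurable_MD_BA`.

# Statistics

`runGroupAnalysis()` reproduces the study's analysis plan on any cohort
table: two-sided Wilcoxon rank-sum tests (exact when the pooled sample
is ≤ 20 and tie-free, else tie- and continuity-corrected normal
approximation), the Mann–Whitney AUC with malignant as the positive
class, a stratified percentile bootstrap 95% CI (default B = 2000; the
method is a package choice — the study names none — and DeLong-style
alternatives can be added behind the same interface), pairwise-complete
Pearson correlations, the thickness-restricted sensitivity re-analysis
(default cutoff 2.5 mm), and p-values left unadjusted throughout.

For the four branching biomarkers, association is tested jointly for
measurability and value with Firth logistic regression under the linear
predictor $\beta_0 + \beta_1 X_1 + \beta_2 X_1 X_2$, where $X_1$
indicates measurability and $X_2$ is the (z-scored) value; the fill for
unmeasured $X_2$ is irrelevant since it enters only through $X_1 X_2$,
and a test asserts that invariance.  The Newton solver maximizes the
Jeffreys-penalized likelihood with hat-corrected scores and step
halving; the 2-df likelihood-ratio statistic compares the full fit to a
*constrained* fit evaluated under the full model's penalty — comparing
each model under its own penalty is anti-conservative (we measured a
type-I error of ≈ 0.16 at n = 36 versus ≈ 0.05 for the constrained
construction, which the acceptance suite checks against the
[0.035, 0.065] band).

# The synthetic cohort and what it does (not) show

`defaultCohortSpec()` encodes the study conditions: 21 malignant vs 15
benign participants; per-biomarker marginals matched to the published
group means and SDs (Gaussian by default; log-normal for the
right-skewed NV and τ-max; a zero-inflated Poisson for NB parameterized
by its mean and P(NB = 0), with the benign no-branch probability 7/15);
log-normal thickness (3.81 ± 2.63 mm vs 1.70 ± 0.40 mm).  Gaussian
draws are deliberately *not* clipped to the biomarkers' theoretical
support — moment fidelity is what the downstream checks need.

Moment matching has a known limit worth stating: for τ-max, whose
published SD nearly equals its mean, a log-normal with those moments
implies far weaker *rank* separation (binormal AUC on the log scale
≈ 0.56) than the clinically observed AUC of 0.82.  Passing tests on
this generator therefore demonstrate the statistical machinery and the
moment-level behavior, not that moment-matched marginals reproduce
every observed effect size.

The imaging phantoms (`runEndToEnd()`) mirror the arms with
high-branching, tortuous, wide-rooted trees versus sparse, straight,
narrow ones, with branch counts drawn from the same zero-inflated
Poissons.  What the generator does **not** emulate: eye motion, depth-
dependent attenuation, aberration, blood-speckle decorrelation, and
real clutter of rank above one.

# Problem sizes and determinism

The full-scale configuration keeps the acquisition of the study: 1000
frames at 1000 Hz, 16.5 MHz, on a 256 × 256 px grid at 50 µm/pixel.
The package's own demonstration and test runs use a reduced
configuration (`demoRunConfig()`: 128 × 128 px, 64 frames, shorter
trees) — these sizes are the package's choice for a desk-scale,
fully-reproducible study and are what the shipped tests and the
`scripts/acceptance.R` report are computed at, except the resolution
scan, which runs at the full 1000 frames on a cropped single-vessel
grid.  Every stochastic stage takes an explicit seed; a fixed seed
reproduces trees, ensembles, cohorts and all output tables
byte-identically, and the end-to-end manifest records the seed and
configuration hash needed to reproduce any table.

```{r demo}
library(choromvq)
res <- runEndToEnd(demoRunConfig(), seed = 7, outDir = "qhdmi-demo")
res$analysis
```

# Known limitations

* The enhancement chain is a faithful generic realization of the
  published pipeline's *kind* (clutter filtering, denoising, vessel
  enhancement); the clinical implementation's exact operator chain is
  not public, and provenance records every step used here.
* Diameters from the distance transform are quantized to the pixel grid
  (± 1 pitch) and overestimate 1-px lines by construction.
* NV is sensitive to skeletonization spurs on wide vessels; counts are
  reproducible under the documented pruning defaults but should be read
  as pipeline-conditional, as in any skeleton-based morphometry.
* The frozen-speckle blood model makes power-Doppler speckle harsher
  than reality; the binarization cleanup (hysteresis, closing, hole
  filling) is calibrated for it.
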