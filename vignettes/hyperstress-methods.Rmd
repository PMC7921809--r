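---
title: "Resolving plant stress signatures from hyperspectral reflectance with equality-constrained MCR-ALS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving plant stress signatures from hyperspectral reflectance with equality-constrained MCR-ALS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Visible/near-infrared (VNIR, ~400-1000 nm) reflectance of leaves carries
chemically specific information: chlorophyll absorption in the blue and red,
the green reflectance peak, the red edge near 700-750 nm, and water- and
structure-related features in the NIR. When a rosette plant such as
*Arabidopsis thaliana* is exposed to a chemical stressor (salt, copper,
cesium), its reflectance spectrum changes in ways that are specific to the
stressor, not merely to "stress". `hyperstress` implements a pipeline that
turns a set of hyperspectral images of control and stressed plants into a
small library of spectral components — two chlorophyll-dominated plant
components, a few broadband background components, a constant baseline, and
per-condition stress components — together with per-plant component
intensities and heteroscedasticity-robust group comparisons.

Because no public imaging data accompany the study design this package
emulates, every stage is validated against a synthetic-scene generator with
known ground truth. The generator is first-class, tested code: all
acceptance-style checks (model-order recovery, constrained extension,
masking, classification) are parameter-recovery experiments on its output.

## The model

A calibrated scene is a cube $R \in \mathbb{R}^{L \times S \times B}$ of
unitless reflectance. Plant pixels from all images of one condition are
unfolded into a matrix $X$ (pixels x bands) and factorized

$$X \approx C\,S^{\mathsf T},$$

where the columns of $S$ (bands x K) are spectral components and the rows of
$C$ (pixels x K) their per-pixel concentrations. The fit alternates exact
non-negative least squares on $C$ given $S$ and on the free columns of $S$
given $C$ (MCR-ALS). Three structural choices follow the chemometrics
conventions for reflectance data:

* **Non-negativity** on concentrations and free spectra. The source workflow
  does not state its constraints; non-negativity is the field default and is
  what makes the components interpretable as reflectance signatures. Both
  constraints can be disabled in `fit_options()`.
* **A constant baseline component**, always present, equality-constrained to
  a flat spectrum, with a per-pixel coefficient *unconstrained in sign*, so
  additive offsets are absorbed without distorting the other components.
* **Equality constraints** on known columns of $S$. The control components
  are fitted once on pooled control pixels; when a stress condition is
  analysed, those columns are frozen and only the additional components are
  free. Any new component therefore absorbs exactly the signal the control
  model cannot represent. The high-potassium rescue arm freezes the control
  *and* the cesium stress components and asks whether anything is left.

### Reflectance calibration

Raw digital numbers are converted band-wise with a white reference (a
99%-reflectance Spectralon-style target) and a dark frame:
$R = f\,(\mathrm{raw} - \mathrm{dark})/(\mathrm{white} - \mathrm{dark})$.
The factor $f$ defaults to 1.0; pass 0.99 to `calibrate_reflectance()` to
correct for the nominal reflectance of the white target (the source protocol
does not state whether this correction was applied, so it is opt-in).

### Plant-pixel segmentation

A pixel is classified as plant from seven properties of its spectrum: the
mean reflectance in four wavelength windows — red 750-850 nm, orange
550-600 nm, blue 410-450 nm, blue-green (lower bound)-450 nm — two ratios
(orange/blue and red/blue-green), and a red-cutoff flag. The rule is

> red average > 0.5 AND (orange/blue > 1.5 OR red/blue-green > 3),

with strict inequalities and inclusive window membership. The published
description gives the blue-green window as "between 3 and 450 nm", which
cannot be taken literally; the lower bound is a configurable parameter
defaulting to 400 nm. Zero denominators yield `+Inf` so the comparisons stay
defined (a bright-NIR pixel with no blue signal reads as plant, which matches
the rule's intent). Leaf area is the plant-pixel count times
0.000112 cm²/pixel. Root area is computed from a grayscale photograph by
Otsu thresholding with a ≥ 5 px particle filter — the interactive ImageJ
steps of the original protocol are not fully specified, so these defaults
are explicit, reproducible stand-ins.

### Model-order selection

The number of components is chosen from the data:

1. **Scree elbow.** Eigenvalues of the mean-centred covariance of $X$;
   the elbow is the point of maximum perpendicular distance from the chord
   joining the first and last log-eigenvalues. This is a coarse starting
   point, not the final answer.
2. **Residual PCA.** After a fit, the top principal loading of the residual
   matrix is summarised by its lag-1 spectral autocorrelation. Smooth
   loadings (score > 0.5) mean unmodeled signal: increase the order.
3. **Null components.** A fitted free component is null when its share of
   explained signal ($\lVert C_k\rVert\,\lVert S_k\rVert$ relative to the
   non-baseline total) is below 1% or its spectrum is noise-like (lag-1
   autocorrelation < 0.5): decrease the order.
4. **Parsimony descent.** When a candidate order is clean and null-free, the
   search additionally verifies that the next smaller order is not. This
   guards against a failure mode we observed directly: an over-specified fit
   can redistribute genuine signal across all components, leaving every
   share above the null floor and every spectrum smooth, so rules 2-3 alone
   would accept it. The returned order is the smallest clean, null-free one,
   which is what "an appropriate number of components" means operationally.

If the search oscillates between two adjacent orders, the smaller is
returned with a warning. The thresholds (0.5 autocorrelation, 1% share) are
quantitative stand-ins for what a spectroscopist does by eye when inspecting
residual PCs; they are exposed as arguments.

### Numerical choices

* ALS half-steps are solved exactly by a fast combinatorial active-set NNLS
  over all right-hand sides at once (columns sharing a passive set are
  solved together), with the baseline coefficient exempt from the bound.
  Exact half-steps guarantee a non-increasing RSS, which the tests assert on
  every fit.
* Rank-deficient Gram matrices fall back to a ridge
  ($\lambda = 10^{-10}\,\mathrm{tr}$) and, in the degenerate all-zero case,
  to a truncated-eigenvalue pseudoinverse; a warning is raised only if the
  deficiency persists at convergence.
* A free component whose concentrations are clipped to all-zero (a "dead"
  component, the classic ALS local minimum) is reseeded from the dominant
  residual loading. This leaves $CS^{\mathsf T}$ and the RSS unchanged, so
  monotonicity is preserved; at most three revivals are attempted per
  column, after which the column is left for null detection to flag.
* Convergence: relative RSS change below `rel_tol` (default 1e-8) or
  `max_iterations` (default 500). Free spectra are reported with unit
  Euclidean norm and components are ordered fixed-first, then free by
  explained signal, baseline last, which makes repeated fits from one seed
  bit-identical.
* Random initialisation of free spectra (uniform per band, unit-normalised)
  follows the source workflow; the fit seed enters through
  `fit_options(seed = )` and the order-search uses `seed + k` for the fit
  with `k` free components.

### Statistics

Per-plant mean intensity — the mean of one component's concentration over
the plant pixels of one image — is the replicate-level statistic. Groups of
replicates are compared with the Games-Howell procedure: for groups $i, j$,

$$q = \frac{|\bar m_i - \bar m_j|}{\sqrt{(s_i^2/n_i + s_j^2/n_j)/2}},$$

referred to the studentized range distribution with $k$ groups and
Welch-Satterthwaite degrees of freedom. This is the appropriate pairwise
procedure when group variances differ — which the synthetic experiment
forces by design, and which rules out classical ANOVA + Tukey HSD. The
studentized range tail comes from R's `ptukey`; the test suite verifies the
$k = 2$ reduction to the $t$ distribution to 1e-4 and the family-wise error
calibration by simulation. The equal-variance two-tailed $t$-test used for
leaf-area comparisons and the 1.5 x IQR box-plot convention (type-7
quartiles) are provided alongside.

Note one asymptotic subtlety the tests encode: Games-Howell and Tukey-Kramer
agree in the equal-variance limit, but with *estimated* variances at
moderate n their p-values differ by more than the df effect alone suggests
(sampling noise in $s_i^2$ enters the two statistics differently). The
agreement test therefore standardises the groups to exactly equal sample
variances, isolating the Welch-vs-pooled df effect, which vanishes with n.

## The synthetic-data generator

`build_library()` constructs parametric reflectance shapes from logistic red
edges and Gaussian bumps/dips: a control-like chlorophyll component (green
peak 520-560 nm, red edge inflecting near 705 nm and completing by 760 nm), a
stress-like chlorophyll component (blue shoulder 400-430 nm, broader
500-640 nm reflectance, steeper red edge left-shifted to ~695 nm, post-edge
dip, reduced ~925 nm NIR), three broadband background components, one
salt-like and one copper-like stress component, and two cesium-like
components. A seeded ±5% amplitude jitter varies libraries across seeds.

Design choices that matter, and why:

* **Wavelength grid** 400-1000 nm, 301 bands (2 nm): the emulated imager's
  band count is not public; this is a typical VNIR line-scanner resolution.
  Configurable.
* **Backgrounds bleed into plant pixels** (default 20-25% of their outside
  amplitude, spatially varying): reflections from the surroundings
  contribute to plant pixels too — which is exactly why a plant-masked
  control model still needs the background components, and why five
  components (not two) model control data. The low-level scene constructor
  defaults to zero bleed for strict support testing; `experiment_config()`
  turns it on.
* **Background spectra carry their distinguishing structure between the
  masking windows** (bumps near 505, 660, 925 nm). Inside the windows they
  are close to flat, so their band ratios sit safely in the non-plant region
  of the decision rule at any brightness, while their full-spectrum shapes
  remain mutually distinct enough for all three to be recoverable above the
  noise floor. Every generated scene is verified against the decision rule
  at build time (noiseless render): plant pixels must classify as plant,
  background pixels must not.
* **Paired stress components are spatially distinct**: the second cesium
  component concentrates near the stem and primary veins, the first toward
  leaf margins. With proportional maps the pair would be numerically
  rank-one and no algorithm could recover two components.
* **Noise** is additive i.i.d. Gaussian in reflectance units (default sd
  0.005); the source states no noise model.
* **Schedules are linear in day**: control rosettes grow ~35% in area over
  the imaging window, stressed ones shrink slightly; stress amplitude ramps
  from 0 to its day-9 level. Only endpoint statistics are emulated.
* **Heteroscedasticity** enters through per-condition multipliers on the
  between-replicate standard deviation of the stress amplitude (copper
  largest), motivating Games-Howell over ANOVA.
* **The high-potassium arm** scales the cesium stress amplitudes to zero by
  default (`k_suppression = 0`): potassium supplementation abolishes the
  cesium-specific spectral response, so no additional components are required
  beyond the frozen control + cesium set and control-vs-high-K comparisons
  do not reach significance. A small positive `k_suppression` simulates a
  partial rescue; note that with the generator's low replicate-to-replicate
  noise even a few-percent residual amplitude becomes statistically
  significant, which real biological replicate scatter would mask.

What the generator does **not** emulate: radiative transfer in leaf tissue,
illumination geometry and specular highlights, sensor nonlinearity and smile,
multi-plant scenes, or spatially correlated noise. Passing the parameter
recovery suite therefore shows the algorithms are correct and calibrated on
data satisfying the model assumptions; it does not certify performance on
real acquisitions, where the mixing model itself is only an approximation.

## Problem sizes used in the tests

The packaged checks run the study at sizes chosen to exercise the claims
while staying comfortably reproducible on a laptop core: control model-order
recovery pools ~2.1 x 10^4 masked pixels (5 replicates x 2 days) per run with
fits capped at 200 ALS iterations; the constrained-extension runs use 4
replicates per condition (~1.2 x 10^4 control pixels, ~5 x 10^3 per stress
arm); the statistical calibrations use 10^4 Monte-Carlo replications. At
these sizes the model-order diagnostics are far from their decision
boundaries, and the RSS has long plateaued at the noise floor before the
iteration cap.

## Known limitations

* MCR without external constraints has rotational ambiguity; the pipeline
  pins it down with non-negativity, equality constraints, unit-norm spectra
  and explained-signal ordering, but individual free components on strongly
  overlapping mixtures are identified only up to that convention.
  Subspace-level claims (RSS, column-space angles) are the robust ones.
* The scree elbow is a heuristic; it only seeds the search. The
  residual/null/parsimony loop is what actually fixes the order.
* `root_area()` assumes white roots on a black background, as in the
  source's cropped photographs.
* The Games-Howell test is slightly conservative at very small n (< 6 per
  group); the synthetic study uses n >= 4-5 replicates, matching the
  emulated design.
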