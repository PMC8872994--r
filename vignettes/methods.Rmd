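---
title: "Methods: quantitative multiplex immunofluorescence and longitudinal cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative multiplex immunofluorescence and longitudinal cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mifquant implements a quantitative multiplex-immunofluorescence (mIF)
workflow — spectral unmixing, nuclear segmentation with cytoplasm ring
expansion, percentile-rescaled threshold scoring, immune-cell density
quantification — together with the longitudinal statistics used to relate
tissue immune-cell densities to clinical and serum variables in weight-loss
cohorts: Kruskal–Wallis tests with Dunn's adjusted post hoc, and
subject-bootstrapped repeated-measures correlation. Because mIF studies
rarely deposit raw images or patient tables, every stage is exercised on
synthetic data with known ground truth; this vignette explains the models,
the defaults and the choices that were genuinely open.

## Linear spectral unmixing

Each acquisition channel records a mixture of fluorophore emissions. The
observed spectrum of a pixel is modelled as a non-negative linear
combination of the library signatures — six marker fluorophores, DAPI, and a
tissue autofluorescence component treated as an ordinary library column so
that intrinsic fluorescence does not contaminate marker abundances:

$$\mathbf{y} = A\,\mathbf{a} + \varepsilon, \qquad \mathbf{a} \ge 0,$$

where $A$ (channels × components) holds unit-normalised spectra. Abundances
are estimated per pixel by non-negative least squares (Lawson–Hanson
active sets, compiled via RcppArmadillo). Non-negativity is the default
because component quantities are physical abundances; an unconstrained mode
exists for numerical comparisons. A fast path solves the unconstrained
normal equations for all pixels at once and falls back to the active-set
solver only where a coefficient goes negative, which on near-noiseless
images is a small minority of pixels.

Library spectra are extracted from single-stain reference slides as the
unit-normalised mean spectrum of the brightest 5% of pixels
(`top_fraction = 0.05`; the acquisition protocol is silent on pixel
selection, and the brightest pixels are the ones dominated by the stain),
optionally after channel-wise subtraction of an unstained slide's mean
spectrum, floored at zero.

Tiles of one scanned region are stitched by row-major abutting
concatenation. Commercial stitchers may blend overlaps, but overlap handling
does not change per-region cell counts, which is what downstream analysis
consumes. Regions of interest are sampled uniformly among non-overlapping
axis-aligned candidate rectangles, requiring at least 50% of a candidate's
area inside the tissue mask when one is supplied, and capped at 10 per
slide.

## Segmentation and compartments

Nuclei are detected from the DAPI abundance plane alone: Otsu threshold,
distance-transform watershed to split touching blobs, and removal of
components below `min_area_um2` (default 7 µm², suppressing sub-nuclear
debris; the threshold is a free parameter). A blank plane yields zero cells
rather than an error, since empty ROIs are legitimate.

The cytoplasm/membrane compartment is simulated by metric ring expansion:
every background pixel within `round(expansion_um / pixel_size)` pixels of a
nucleus joins that cell's ring. At the default 0.496 µm/pixel (20×
acquisition) and 2 µm expansion this is exactly 4 pixels; rounding is
half-up so the metric parameter maps deterministically to a pixel radius.
Pixels within reach of two nuclei are assigned to the nearer centroid, ties
to the lower label, so ring pixels partition uniquely. Compartments are
exclusive: the ring never includes nucleus pixels. Whether commercial
"cytoplasm" measurements include the nucleus is undocumented; exclusivity is
the defensible choice and is stated rather than guessed.

Per cell and per marker, the mean, minimum, maximum and standard deviation
of intensity are computed over each compartment, with areas converted to
µm² via the squared pixel size. A cell whose ring is entirely clipped keeps
its record with ring statistics set to missing.

## Scoring and quantification

Marker intensities are first rescaled to dataset-wide bounds: the empirical
1st and 99th percentiles (linear-interpolation definition) pooled over the
full dataset, so that the same intensity is represented — and thresholded —
identically in every image. By default the bounds are fitted on per-cell
primary-compartment means; a pixel-based mode pools raw component-plane
pixels for the literal reading of "pixel intensities". Fitting bounds
per-image would defeat the purpose of a common scale, which is why the
bounds live in the panel object.

A cell is positive for a marker iff its rescaled mean intensity in the
marker's primary compartment (ring for the six cytoplasmic/membranous
markers) meets a single dataset-global threshold for that marker. The mean
is used because a single summary statistic must be chosen and the mean is
the least noisy of the four stored; it is configurable. `suggest_threshold()`
proposes a data-driven cut (Otsu, or the crossing point of a two-component
Gaussian mixture) from a calibration set of ROIs, but the stored panel
threshold is authoritative — in practice thresholds are reviewed by a
pathologist.

Each ROI reports, per marker, the positive count, the density over the ROI
area (pixel count × pixel size², in cells/mm²) and the fraction of all
segmented cells. Density × area and fraction × total reproduce the count
exactly by construction. Both the per-ROI and pooled-sample aggregations of
"% positive cells" can be formed from the per-ROI table, since which
denominator a published table uses is often ambiguous.

## Synthetic image generator

The generator renders what the segmentation and scoring stages assume:
nuclei as non-overlapping disks (default radius 4 µm) with DAPI abundance on
the disk, each expressed marker on its primary compartment (ring of 2 µm or
the disk), a spatially uniform autofluorescence plane, mixing through the
spectral library, additive zero-mean Gaussian channel noise clipped at zero.
The truth table lists every rendered cell with its phenotype, so counts,
centroids, compartment statistics and positivity calls all have exact
oracles.

It deliberately omits optical point-spread, photobleaching, tile-edge
artifacts, irregular nuclear shapes, overlapping nuclei and spatially
correlated autofluorescence. Passing tests therefore demonstrate that the
algorithms are implemented correctly and are robust to channel noise — not
that they would segment real tissue flawlessly; on real slides the
commercial segmenter's behaviour on touching, irregular nuclei is the
dominant error source.

## Synthetic cohort generator

The cohort module emulates a 43-subject, three-visit (0, 2, 12 months)
weight-loss study with a 37/6 split between bariatric surgery and
low-calorie diet — deliberately imbalanced, since the statistics must
tolerate that imbalance. Weight follows the configured per-arm median loss
trajectory (surgery 15.1/63.3 kg at 2/12 months, diet 1.7/13.0 kg) scaled by
a lognormal subject-specific loss multiplier (log-sd 0.25, which puts the
MAD of 12-month surgical loss near 17.6 kg); baseline weight is lognormal
around 140 kg (class III obesity at a 52 kg/m² median BMI and typical
stature; only BMI, not weight, is usually published). BMI is weight divided
by a fixed per-subject height².

Serum and tissue markers are lognormal around configured per-timepoint
medians — medians, not means, because that is how such cohorts are reported
and because the marker distributions are right-skewed — with three variance
components on the log scale: a subject random intercept (sd 0.5 for serum,
1.0 for the much more dispersed tissue densities; dispersions are free
parameters, as published tables give medians without spread for densities),
multiplicative noise parameterised by a coefficient of variation
(`noise_cv`, default 0.3), and a component loaded on the subject's weight
*deviation* from their arm's mean trajectory.

The deviation loading is how the programmed within-subject correlation
`rho_within` between each (log) marker and weight is honoured. The key
observation is that per-timepoint medians plus the shared weight-loss
trajectory already induce a within-subject correlation (both are functions
of time); the generator therefore solves, from the empirical moments of the
realized weights, for the deviation loading (and, when needed, an inflated
noise floor) that makes the expected correlation equal the target. Loading
the *deviation* — which is mean-zero at every timepoint by construction —
leaves the calibrated medians untouched. A target whose sign opposes the
direction implied by the configured medians is unreachable by any such
construction; the generator warns and gets as close as the subject-level
weight variation allows. Default targets are 0.570 (CRP), 0.459 (IL-6),
−0.323 (CD8) and 0 for the remaining markers, with the correlations defined
on the log-marker scale.

## Cohort statistics

**Kruskal–Wallis.** Changes across timepoints are tested with the
tie-corrected Kruskal–Wallis rank statistic (delegated to
`stats::kruskal.test`), chosen over parametric alternatives because the
marker distributions fail normality and homoscedasticity screening. At very
small totals (N ≤ 10) the chi-square reference distribution is poor, so the
p-value is computed by exhaustive enumeration of group assignments there;
the statistic is unchanged.

**Dunn's post hoc** compares group pairs on pooled ranks,
$z = (\bar R_i - \bar R_j)\big/\sqrt{\left(\tfrac{N(N+1)}{12} -
\tfrac{\sum(t^3-t)}{12(N-1)}\right)\left(\tfrac1{n_i}+\tfrac1{n_j}\right)}$,
with two-sided normal p-values adjusted over all $k(k-1)/2$ pairs by Šidák
($1-(1-p)^m$, the default) or Benjamini–Hochberg. All pairs are computed;
the report highlights the baseline comparisons, which are the clinically
reported ones.

**Repeated-measures correlation (rmcorr)** estimates the common
within-subject association of two variables: an ANCOVA of y on x with
subject as a categorical factor and a shared slope. Algebraically this
reduces to the Pearson correlation of within-subject-centered values, with
$df = N_{obs} - N_{subjects} - 1$ and a two-sided t p-value — the closed
form is what the package computes, and the test suite checks it against an
explicit normal-equations solve of the dummy-coded design. rmcorr is used
instead of mixed-effects trajectories because it is robust to the 37/6
class imbalance and to heteroscedastic errors, and it makes no assumption
about between-subject intercepts. Distributional assumptions are relaxed
further by a cluster bootstrap: subjects are resampled with replacement
(keeping each resampled subject's complete visit set; duplicates count as
distinct subjects), r is recomputed per replicate from per-subject
sufficient statistics, and a 2.5/97.5 percentile interval is reported.
Subject-level resampling preserves the within-subject structure, which is
the quantity being estimated; resampling rows would not. Replicates with
insufficient degrees of freedom are redrawn up to 10 times, then dropped
with a count.

**Diagnostics.** The screening battery that motivates the non-parametric
choices is exposed as `distribution_diagnostics()`: QQ data, Shapiro–Wilk,
Bartlett, median-centered Levene (median centering is the robust variant
appropriate for skewed data), Fligner–Killeen, and a Box–Cox suitability
flag (true iff the profile-likelihood optimal λ makes the transformed
variable pass Shapiro–Wilk at 0.05).

## Numerical choices and degenerate inputs

- NNLS tolerance scales with the Frobenius norm of the library; iteration is
  capped at 3× the component count per pixel.
- Metric-to-pixel conversion rounds half-up, so 2 µm at 0.496 µm/pixel is 4
  pixels, never 3.
- Percentiles use R's default type-7 (linear interpolation) definition.
- A constant marker (p1 = p99), an all-zero reference slide, and a library
  with collinear columns are errors; a blank DAPI plane and an ROI with zero
  cells are valid empty results.
- Contested ring pixels break ties toward the lower label, making label maps
  deterministic.
- All generators take explicit integer seeds and restore the caller's RNG
  state; identical seeds give bit-identical images and tables. The pipeline
  driver fans one global seed out to per-stage child seeds through a fixed
  affine map modulo 2³¹−1, so stages can be re-run in isolation.

## Problem sizes in the test suite

The suite renders 220–320 px square ROIs with 10 acquisition channels and
30–80 cells, which keeps every geometric and spectral property testable at
full fidelity in well under a minute per scenario; correlation-recovery
checks use 200-subject cohorts over 100 seeded repeats, and bootstrap
coverage uses the 43-subject default with 1000 resamples over 50 repeats.
These sizes were chosen as the smallest at which the asymptotic claims
(recovery within ±0.05, ≥90% CI coverage) are meaningful.

## Known limitations

- The image model is linear and noise additive-Gaussian; detector
  saturation, Poisson photon statistics and spectral calibration drift are
  out of scope.
- Compartments are geometric (disk + ring), not membrane-specific; no 3D.
- No multi-marker co-expression phenotyping or spatial neighborhood
  statistics — single-marker densities only.
- Nonlinear mixed-effects trajectory modelling is intentionally not
  provided; with markers this skewed and classes this unbalanced it often
  fails to converge, which is precisely why rmcorr is the supported tool.
- The cohort generator cannot honour a within-subject correlation whose sign
  contradicts its own median trends, and menstrual-phase effects on immune
  infiltrates are not modelled.
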