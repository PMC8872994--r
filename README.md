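# mifquant

Quantitative multiplex immunofluorescence (mIF) for tissue immunology, with
the longitudinal statistics needed to relate tissue immune-cell densities to
clinical and serum variables in weight-loss cohorts.

mIF studies stain one tissue section for several protein markers at once
(here a six-marker immune panel — CD8, CD68, CD3, FOXP3, CD56, PD-1 — plus a
DAPI counterstain), acquire multispectral images, and quantify marker-positive
cells per unit area. mifquant implements that workflow end to end and pairs
it with the cohort-level analysis typically applied to serial biopsies taken
before and after a weight-loss intervention:

- **Spectral unmixing** — per-pixel non-negative least squares
  $\min_{\mathbf a \ge 0} \lVert \mathbf y - A\mathbf a\rVert^2$ against a
  spectral library $A$ of fluorophore signatures plus a tissue
  autofluorescence column (Lawson–Hanson active sets in compiled code);
  library construction from single-stain slides; tile stitching and random
  ROI sampling.
- **Segmentation** — DAPI Otsu threshold + distance-transform watershed,
  cytoplasm simulated by 2 µm metric ring expansion (4 px at the default
  0.496 µm/pixel), per-cell per-compartment intensity statistics.
- **Scoring** — dataset-wide 1st/99th-percentile rescaling, one global
  threshold per marker, positive-cell counts, densities (cells/mm²) and
  fractions per ROI.
- **Cohort statistics** — Kruskal–Wallis across timepoints (exact
  enumeration at small N), Dunn's post hoc with Šidák or Benjamini–Hochberg
  adjustment, distributional diagnostics, and repeated-measures correlation
  $r = \sum x_c y_c / \sqrt{\sum x_c^2 \sum y_c^2}$ (the ANCOVA common
  within-subject slope, $df = N_{obs} - N_{subj} - 1$) with a
  subject-level bootstrap CI.
- **Synthetic data** — a first-class module that renders multispectral
  tissue images with per-cell ground truth and simulates longitudinal
  cohorts (43 subjects, 37 surgery / 6 diet, visits at 0/2/12 months) with
  programmed medians and within-subject correlation structure, so the whole
  pipeline is testable without any data download.

See `vignettes/methods.Rmd` for the models, assumptions and design choices.

## Worked example

Simulate the default cohort and run the longitudinal report:

```r
library(mifquant)
tab <- simulate_cohort(cohort_sim_params(), seed = 1)
rep <- run_longitudinal_report(tab, variables = c("weight", "crp", "il6", "cd8"),
                               pairs = list("crp:weight", "cd8:weight"),
                               n_boot = 1000, seed = 1)
print(rep)
```

```
== Medians by timepoint ==
 variable        t0        t2       t12
   weight 1.413e+02 1.290e+02 78.529829
      crp 5.833e+00 3.285e+00  1.516283
      il6 5.614e+00 1.778e+00  1.270516
      cd8 3.182e-03 2.931e-03  0.004853

== Kruskal-Wallis across timepoints ==
 variable      H df         p significant
   weight 71.671  2 2.734e-16        TRUE
      crp 44.512  2 2.160e-10        TRUE
      il6 52.801  2 3.423e-12        TRUE
      cd8  3.399  2 1.828e-01       FALSE

== Dunn post hoc (sidak-adjusted), baseline pairs ==
 variable group1 group2         z     p_raw     p_adj baseline_pair significant
   weight      0     12  8.347838 6.952e-17 3.331e-16          TRUE        TRUE
      crp      0     12  6.504612 7.789e-11 2.337e-10          TRUE        TRUE
      il6      0     12  7.018058 2.250e-12 6.749e-12          TRUE        TRUE
      cd8      0     12 -1.598029 1.100e-01 2.951e-01          TRUE       FALSE
  (0 vs 2-month rows elided)

== Repeated-measures correlations ==
   x      y       r df         p  ci_low   ci_high significant
 crp weight  0.5707 85 7.867e-09  0.3517  0.747048        TRUE
 cd8 weight -0.2849 85 7.488e-03 -0.5484 -0.004763        TRUE
```

Reading the output: serum CRP and IL-6 fall with weight loss (significant
baseline↔12-month Dunn comparisons, and CRP correlates with weight within
subjects at r ≈ 0.57), while tissue CD8+ density shows no significant
cross-sectional change across timepoints but a significant *negative*
within-subject correlation with weight — it rises as weight falls. That
asymmetry (rmcorr detects what the rank test misses) is exactly why the
repeated-measures analysis is included.

The imaging half runs the same way from a rendered scene:

```r
lib   <- default_spectral_library(10, seed = 1)
cells <- place_cells(50, c(300, 300), seed = 2)
scene <- render_tissue_image(cells, lib, c(300, 300), noise_sd = 0.05)
comp  <- unmix_pixelwise(scene$image, lib)
nuc   <- segment_nuclei(comp$planes[, , "DAPI"], 0.496)
rings <- expand_cytoplasm(nuc)
stats <- compute_cell_stats(comp$planes, nuc, rings)
```

`run_pipeline(validate_config(list(out_dir = "run1")))` chains all stages,
writes every intermediate artifact (TIFF + JSON sidecars, CSV tables, YAML
panel) and a manifest with per-file checksums; re-running the same
configuration reproduces identical outputs. A thin command-line wrapper
lives at `inst/scripts/mifpipe.R`.

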