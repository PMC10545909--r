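# pamscope

Quantitative analysis of **saturation-pulse (PAM) chlorophyll-fluorescence
experiments imaged as confocal z-stack time series** — photosynthesis
measured not as one photodiode trace but in 3D, per tissue, cell and
chloroplast.

In the saturation-pulse method a weak measuring light probes chlorophyll *a*
fluorescence, a saturating flash closes all photosystem II centres to reveal
the maximal fluorescence (Fm dark-adapted, Fm′ in the light), and continuous
actinic light drives photosynthesis in between. The standard parameters are

```
Y      = (Fm − F′) / Fm          maximum PSII photochemical capacity
NPQ(t) = (Fm − Fm′(t)) / Fm′(t)  non-photochemical quenching time course
ΦPSII  = (Fm′ − Fs) / Fm′        effective PSII quantum yield
```

`pamscope` takes protocol-annotated 4D stacks `(t, z, y, x)` from a confocal
whose imaging laser serves as (saturating) measuring light and an external
LED provides actinic light and pulses, and turns them into:

* intensity-preserving **sum projections** and background-corrected
  **per-ROI fluorescence traces**;
* **Y, NPQ(t), ΦPSII** per chloroplast, cell or tissue;
* **3D object volumes** (voxel count × voxel size) and integrated
  fluorescence via median filtering, thresholding and 26-connected
  component labelling;
* **angular NPQ profiles** of single cells (radial scans every 5° of an
  equivalent-area circle) where individual plastids cannot be resolved;
* a **six-variable kinetic phenotype** per cell — NPQav, NPQmax, Induction,
  Decay, Fmax, AreaFrac — with correlation-matrix **PCA**;
* a **forward simulator** of complete acquisitions (moving plastid-sized
  blobs, NPQ-modulated emission, actinic-dependent background, Poisson +
  Gaussian noise) with ground truth for every stage.

## Worked example

Simulate the reference protocol — 3 dark, 6 actinic, 6 relaxation frames at
60 s spacing — analyse it blind, and compare with the simulator's truth:

```r
library(pamscope)

tl <- build_timeline(3, 6, 6, 60, actinic_intensity = 500)
sc <- render_scene(scene_params(seed = 1), tl)     # one cell, 8 plastids

pr   <- sum_project(sc$stack)                      # z-collapse, exact sums
corr <- subtract_background(
  mean_gray(pr, truth_cell_roi(sc$truth, 1)),      # cell ROI trace
  mean_gray(pr, truth_background_roi(sc$truth)))   # empty-ROI trace

npq <- compute_npq_series(corr, tl)
round(npq$npq$npq, 3)
#>  [1] 0.000 0.973 1.473 1.729 1.861 1.929 1.963 1.191 0.722 0.438 0.266 0.161
round(sc$truth$npq$npq_true[-(1:3)], 3)            # ground truth: identical
#>  [1] 0.000 0.973 1.473 1.729 1.861 1.929 1.963 1.191 0.722 0.438 0.266 0.161

extract_features(npq, tl, area_frac = sc$truth$area_frac[1])
#>   NPQav NPQmax Induction  Decay    Fmax AreaFrac
#> 1 1.328  1.929     0.736 -0.621 213.062    9.524
```

The NPQ course rises under actinic light (frames 4–9), peaks at 1.96 and
relaxes in the dark; the analysis inverts the simulator's kinetics to
within 7 × 10⁻⁶ despite plastid motion. The features read: mean/maximum NPQ
in the light 1.33 / 1.93, induction slope 0.74 min⁻¹ over the first two
minutes of light, decay −0.62 min⁻¹ after light-off, dark-adapted Fm 213
(a.u. of the projected image), and plastids covering 9.5% of the cell
section.

Phenotyping many cells feeds the six features into a correlation-matrix PCA:

```r
ft  <- simulate_feature_table(175, seed = 1)   # WT/mutant x 2 cell types
pca <- principal_components(standardize_features(ft))
round(pca$explained_variance_pct, 1)
#> [1] 60.0 29.9  3.7  3.2  3.1  0.1
```

PC1 carries the NPQ-linked variables (separating the genotypes), PC2 the
Fmax/AreaFrac pair (separating the cell types).

A thin command-line front end covering every stage
(`simulate | project | trace | npq | segment | angular | features | pca |
run`) ships in `inst/cli/pamscope.R`, and `run_pipeline()` orchestrates the
whole chain with a checksummed run manifest.

## Layout

```
R/                 protocol, stack I/O + projection, traces, photoparams,
                   segmentation, angular scan, PCA, simulator, pipeline
tests/testthat/    unit + property + end-to-end acceptance tests
scripts/acceptance.R
vignettes/pamscope-methods.Rmd   the methods notes
inst/cli/pamscope.R              command-line front end
```
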