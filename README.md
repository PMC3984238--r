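# dkimoco

Motion-robust post-processing for diffusion kurtosis imaging (DKI) in R.

DKI extends diffusion tensor imaging with a rank-4 kurtosis tensor and
needs multiple b-values and many gradient directions, so scans are long and
head motion — especially in sedated infants and patients with tremor — is
common. A single sudden movement destroys the signal of individual axial
slices (complete or local signal loss) or displaces them (mismatch,
inter-volume misalignment), and those corrupted measurements bias every
parameter map fitted from them. `dkimoco` implements a slice-wise
quality-control and estimation workflow for such data:

- **LPCC artifact rejection.** Each diffusion-weighted slice is compared
  with a b0 reference through the *local Pearson correlation coefficient*:
  the slice is divided into 8×8-pixel sub-windows, background-only windows
  get weight 0, the remaining windows get equal weight `1/(L − N_b)`, and
  the LPCC is the weighted sum of per-window Pearson coefficients. Within
  each (slice, b-value) group of 25 directions the scores are normalized by
  their maximum and measurements falling below `mean − 3·SD` are rejected.
  The global correlation coefficient (NCC) is computed alongside as the
  conventional baseline.
- **Constrained tensor estimation.** Surviving measurements enter a
  log-linear constrained least-squares (CLLS) fit of the model
  `ln S = ln S0 − b·D_app(g) + (b²/6)·MD²·W_app(g)` with 22 unknowns per
  voxel (ln S0, 6 diffusion-tensor elements, 15 kurtosis elements), subject
  to `D_app(g) ≥ 0`, `K_app(g) ≥ 0` and `K_app(g) ≤ C/(b_max·D_app(g))` at
  the acquisition directions (C = 3). Mean kurtosis (MK), mean diffusivity
  (MD) and fractional anisotropy (FA) maps are derived. A shell that keeps
  fewer than 15 directions on a slice is dropped entirely; a slice with
  fewer than 2 nonzero shells is unfittable.
- **Protocol feasibility by MSE.** The influence of rejected data is judged
  by the mean squared error of parameter maps refitted from reduced
  protocols (15–25 trailing-consecutive direction subsets; the 26
  combinations of 2–5 nonzero b-values) against the full-protocol
  reference, compared with the lower bound of the background noise variance
  `σ²_L = mean(σ²) − SD(σ²)`.
- **A synthetic DKI phantom.** A brain-like multi-tissue object
  (gray-matter background, bending white-matter band, ventricle-like CSF
  stripe, multi-scale intensity texture, Rician noise) with known
  ground-truth tensors and injectable motion artifacts, so the whole
  workflow is testable without scanner data.

## Worked example

```r
library(dkimoco)

# a 128 x 128 x 10 phantom with the reference acquisition:
# b = 0 (x5), 500...2500 s/mm^2, 25 directions per shell, SNR 20
ph <- render_phantom(phantom_config(seed = 7))

# corrupt two slices and score everything against the b0 reference
ph <- inject_artifacts(ph, list(
  artifact_event("complete_loss", volume_index = 40, slice_index = 7,
                 magnitude = 0),
  artifact_event("local_loss", volume_index = 10, slice_index = 9,
                 magnitude = 0, geometry = 0.3)
), seed = 1)

qc <- run_qc(ph, window = 8, nsigma = 3)
qc
#> <qc_report> 1250 slice-measurements scored (window 8, 3 sigma)
#>   rejected: 2 (0.16%); b0 volumes excluded: 0

library(dplyr)
tidy(qc) |> filter(rejected) |> select(slice, bval, direction_index, lpcc_norm, threshold)
#> # A tibble: 2 x 5
#>   slice  bval direction_index lpcc_norm threshold
#> 1     7  1000              10    0.0385     0.351
#> 2     9   500               5    0.653      0.722
# exactly the two injected slice-measurements, below the mean - 3 SD
# thresholds of their 25-direction groups

# reject, smooth, fit
fit <- ph |> smooth_dataset(fwhm = 2.5) |> fit_dataset(qc = qc)
glance(fit)
#> # A tibble: 1 x 6
#>   n_fitted n_fallback median_mk median_md median_fa mode
#>      77960          0     0.840      1.07    0.0957 proposed

# white-matter ROI means
roi <- white_matter_roi(fit$maps$fa, lower = 0.3)
round(c(mk = mean(fit$maps$mk[roi], na.rm = TRUE),
        md = mean(fit$maps$md[roi], na.rm = TRUE),
        fa = mean(fit$maps$fa[roi], na.rm = TRUE)), 3)
#>    mk    md    fa
#> 1.303 0.789 0.685
```

The white-matter band's ground truth is MD 0.83 µm²/ms, FA 0.73 and
direction-averaged MK ≈ 1.25; the fitted ROI means land within about 5% of
these at SNR 20 (the MD/FA shrinkage and the positive MK offset come from
the Rician noise floor at high b and from smoothing across the CSF stripe;
the vignette discusses both).

`autoplot(qc)` draws the per-(slice, shell) normalized LPCC profiles with
their rejection thresholds; `plot_map_slice(fit$maps$fa, 5)` renders a map
slice. `run_workflow()` chains mask → registration/distortion hooks → QC →
smoothing → fit with full logging, and `inst/cli/dkimoco.R` exposes
`simulate`, `qc`, `fit` and `pipeline` subcommands for shell use on
NIfTI + bval/bvec inputs.

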