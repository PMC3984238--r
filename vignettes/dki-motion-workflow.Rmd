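---
title: "Slice-wise motion QC and constrained kurtosis estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise motion QC and constrained kurtosis estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dkimoco)
```

This vignette explains the models and procedures `dkimoco` implements, the
choices that were genuinely open when the package was designed, and what the
synthetic phantom does and does not establish about real data. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The signal model and its estimator

Diffusion kurtosis imaging models the log-signal along a unit gradient
direction $g$ at diffusion weighting $b$ as

$$\ln S(b, g) = \ln S_0 - b\,D_{app}(g) + \tfrac{b^2}{6}\,MD^2\,W_{app}(g),$$

where $D_{app}(g) = \sum_{ij} g_i g_j D_{ij}$ is the apparent diffusivity
of the symmetric diffusion tensor $D$ (µm²/ms), $W_{app}(g) = \sum_{ijkl}
g_i g_j g_k g_l W_{ijkl}$ contracts the fully symmetric rank-4 kurtosis
tensor, and $MD = \mathrm{tr}(D)/3$. b-values are supplied in s/mm² and
converted internally to ms/µm² so units cancel. The per-voxel unknowns are
$\theta = (\ln S_0, D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz},
V_1 \ldots V_{15})$ with $V = MD^2\,W$: 22 parameters, i.e. 21 tensor
unknowns beyond the intercept. Estimation is linear least squares on
log-signals with equal row weights, subject to, at every acquisition
direction:

* $D_{app}(g) \ge 0$,
* $K_{app}(g) = V_{app}(g)/D_{app}(g)^2 \ge 0$, and
* $K_{app}(g) \le C/(b_{max} D_{app}(g))$ with $C = 3$,

each linear in $\theta$, solved as a quadratic program
(`quadprog::solve.QP`). The unconstrained solution is computed for all
voxels of a slice in one factorization; the QP runs only at voxels that
violate a constraint. Signals at or below zero (possible after the
magnitude noise floor is subtracted conceptually — in practice, dropout
regions) are clamped to half the background Rayleigh mean before the log.
This floor, not the QP, is what limits accuracy at very high $b$ in low-SNR
tissue.

MK is the average of $K_{app}(g)$ over the acquisition's sampled
directions — the convention of multi-direction DKI studies, and the one
that keeps a brute-force oracle trivial; directions with
$D_{app} < 10^{-4}$ µm²/ms are skipped, and the result is clipped to
$[0, 10]$ (the minimum-diffusivity guard and kurtosis clipping range used
by common DKI implementations: where the log-signal is nearly flat —
map background, CSF at high $b$ — $D_{app} \to 0$ and the kurtosis ratio
is unbounded). Tissue kurtosis (0.2–1.8 in this package's phantoms) is
far from the clip. FA and MD come from the eigenvalues of $D$. Voxels
outside the brain mask are never fitted.

**Minimum protocol.** After rejection, a nonzero shell retaining fewer than
15 directions on a slice is dropped entirely for that slice (15 directions
and 2 shells are the determinacy floor of the 21-unknown model), and a
slice with fewer than two surviving nonzero shells is marked unfittable
(NaN in the maps) rather than fitted badly.

## The LPCC detector

A DWI slice is compared against a b0 reference. The slice is partitioned
into square sub-windows (default 8×8 pixels; edge windows may be smaller
so the partition is complete). Windows are classified from the brain mask
as background-only ($S_b$), tissue-only ($S_t$) or mixed ($S_{bt}$);
background-only windows get weight 0 and every tissue-containing window the
equal weight $1/(L - N_b)$. The LPCC is the weighted sum of per-window
Pearson coefficients. Two deliberate readings are documented here:

* $S_{bt}$ windows use *all* their pixels, background included — the
  tissue/background edge itself carries alignment information;
* a zero-variance window scores 0, not NA — a signal-destroyed (flat)
  window should count as uncorrelated, which is exactly the artifact
  semantics.

Scores are normalized by the maximum within each (slice, shell) group of
25 directions, and a measurement is rejected when its normalized LPCC falls
strictly below `mean − 3·SD` of its group (ties keep). The window size and
the factor 3 are exposed (`window`, `nsigma`) since the field treats both
as calibration constants. Rejection granularity is the 2D slice: one
(slice, shell, direction) measurement at a time, never the whole volume.

**b0 screening.** The five b0 volumes are screened per slice by each b0's
mean LPCC against the others. Here the threshold is computed leave-one-out
(each b0 against `mean − 3·SD` of the *other* b0s' scores): among $n$
values the largest possible z-score is $(n-1)/\sqrt{n}$ — about 1.79 for
$n = 5$ — so a threshold that includes the candidate itself could never
exclude anything. Survivors are voxel-averaged into the reference.

**Known limitations.** The detector keys on intensity correlation; a
slice with *plausible* contrast but globally hyper- or hypo-intense
tissue will not be caught. And because the threshold is estimated from
the group that contains the artifacts, two artifacts of very different
severity inside one 25-direction group can mask each other: a complete
dropout inflates the group SD enough to hide a milder local loss. The
shipped validation experiments therefore scatter events over distinct
(slice, shell) groups and measure single-event sensitivity; co-occurring
same-group artifacts degrade gracefully (the severe one is still caught).
Both behaviours are inherent to a mean − 3·SD rule, not implementation
choices.

The NCC baseline is a single global Pearson coefficient over the brain
bounding box of the slice. The package's paired comparison
(`relative_difference_experiment()`) scores an artifact image and its
best-scoring artifact-free partner at the same b-value and compares
$(\mathrm{coef}_{free} - \mathrm{coef}_{art})/\mathrm{coef}_{free}$ between
the two coefficients with a one-sided Wilcoxon signed-rank test. Its
default injects the full artifact taxonomy in equal thirds (complete loss,
local loss, mismatch) — the mixture actually seen in motion-corrupted
acquisitions. For *large* local dark patches alone the global coefficient
loses covariance nearly proportionally too, so the LPCC-versus-NCC margin
is direction-consistent but not always significant in that single-kind
setting; the mismatch and mixed settings separate the two decisively.

## The phantom

`render_phantom()` builds, per axial slice, an elliptical "brain" of
isotropic gray matter (MD 1.1 µm²/ms, MK 0.7), an anisotropic white-matter
band (eigenvalues 1.7/0.4/0.4 µm²/ms, FA 0.726; axial kurtosis 0.6, radial
1.8), and a ventricle-like CSF stripe (MD 2.9 µm²/ms, MK 0.2) flanked by
the band — so an FA-threshold ROI is periventricular white matter, and
anatomy-displacing artifacts have a realistic high-diffusivity
partial-volume pathway. Three structural features deserve explanation
because correlation QC depends on them:

* **Multi-scale intensity texture.** The baseline signal is modulated by a
  smooth multiplicative field with a fine component (sd 0.25 of the
  signal, 2-pixel scale) and a coarse shading component (sd 0.25,
  12-pixel scale), shared by all volumes. A piecewise-constant phantom has
  no within-window structure at all, and the coarse component is what lets
  a *global* coefficient ride out a local artifact, as large-scale anatomy
  does in real images.
* **A bending tract.** The band's fiber orientation sweeps 90° along its
  length. A single coherent orientation makes the per-direction
  white-matter signal vary far more across a shell than mixed-orientation
  real slices do, which would inflate the within-shell score spread the
  mean − 3·SD threshold works against.
* **Rician noise, calibrated to the measured SNR.** Noise is applied in
  the magnitude channel. `snr_b0` is defined as b0 tissue mean over
  background standard deviation — the quantity one would measure on real
  magnitude images — so the Gaussian channel sd is
  $\bar S/( \mathrm{snr} \sqrt{2 - \pi/2})$ (the background of a magnitude
  image is Rayleigh). Default `snr_b0 = 20`; the subjects' actual SNR is
  not published, and 20 is a realistic pediatric-EPI value.

Artifacts are injected *post-noise* for the signal-loss kinds (the tissue
signal is attenuated and re-passed through the magnitude channel, so the
noise floor survives — the visual appearance of real dropout slices);
`mismatch` translates one slice by integer pixels with zero fill;
`volume_misalignment` applies a rigid in-plane rotation plus translation
to every slice of a volume with bilinear resampling. The generator works
in the same $(\,\ln S_0, D, MD^2 W)$ parameterization the fitter
estimates, through the same design matrix, so a noise-free phantom is
recovered to numerical precision — by construction, which is the point:
the round trip validates the algebra, not the realism.

**What passing tests on this phantom do not show.** No EPI distortion,
eddy currents, physiological noise, k-space effects, partial-volume
gradients, or real anatomical texture statistics. Detector sensitivities
measured here transfer to real data only to the extent that real slices
have comparable within-window structure relative to noise.

## The evaluation machinery

The feasibility question — does rejecting data hurt more than noise does? —
is answered by refitting reduced protocols on clean phantoms and comparing
each parameter's MSE against the full-protocol reference (over brain
voxels, pooled across slices) with the noise criterion
$\sigma^2_L = \mathrm{mean}(\sigma^2) - \mathrm{SD}(\sigma^2)$. Choices
made here:

* Direction subsets keep the *first* $n$ directions of each shell and drop
  the trailing consecutive block — motion concentrates late in a scan.
* The 26 b-value combinations are a fixed enumeration of all 2–5-subsets
  of {500, 1000, 1500, 2000, 2500} s/mm², in the conventional labelling
  (`"5"`, `"4_#1"` … `"2_#10"`).
* $\sigma^2$ is measured per parameter on the *background of the derived
  parameter maps* (a subsample of up to 1000 background voxels is fitted
  for this purpose), so MSE and criterion share units. Mean and SD of
  $\sigma^2$ are taken across replicate seeds — the desk-scale surrogate
  for an inter-subject average. Background kurtosis fits are close to
  degenerate (apparent diffusivity near zero), which is precisely why the
  MK clipping range matters here: without it the background MK variance is
  heavy-tailed and $\sigma^2_L$ is not even sign-stable across seeds. With
  it, the MK criterion is finite but loose; the MD and FA criteria are the
  informative ones.
* Replicate phantoms in `protocol_experiment()` default to 64×64×4 at
  SNR 20 with 5 seeds — sizes chosen so the full study runs in minutes on
  one core; the statistics of interest (MSE orderings, criterion
  comparisons) are scale-stable well below the acquisition matrix.

The workflow contrast (`workflow_contrast_experiment()`) processes 18
artifact replicates with both the proposed (QC rejection) and conventional
(no rejection) workflows, and 18 clean replicates in which the artifact
replicates' rejections are replayed as manual exclusions. Replicates are
jittered "subjects" (tissue parameters and band geometry vary ~10%,
emulating a heterogeneous pediatric cohort). Each replicate's artifact
load mixes 10 complete losses, 5 local losses, 8 mismatches and 4
volume misalignments scattered over distinct (slice, shell) groups — the
taxonomy of a genuinely motion-corrupted dataset, scattered so events do
not mask each other at the group threshold. ROI means use each workflow's
own FA ≥ 0.3 map (the way a threshold ROI is drawn in practice); map
accuracy is additionally summarized as the voxel-wise mean absolute error
against ground truth over brain voxels, which is robust to sign-canceling
biases that ROI *means* can hide.

Two findings from this experiment are worth stating plainly because they
are properties of the method, not bugs:

* Conventional-workflow MD corruption is large voxel-wise but nearly
  sign-symmetric at ROI-mean level (dropouts pull apparent MD down, while
  anatomy-shifting artifacts pull it up through CSF mixing), so the paired
  ROI-mean test for MD is much weaker than for FA and MK even when the map
  error is dramatically worse.
* Replaying exclusions on clean data produces a tiny (≈0.1–0.2%) but
  sign-consistent MK reduction — fewer measurements mean noisier fits and
  slightly more truncation at the $K \le C/(b_{max}D)$ cap, which sits
  close to white-matter axial kurtosis at $b_{max} = 2500$. A paired
  signed-rank test on noise-matched phantom pairs resolves an effect this
  small; real paired measurements carry enough additional jitter
  (registration, manual ROIs, scanner drift) to mask it.

## Numerical and degenerate-input policy

Zero-variance tiles score 0; an all-background slice errors at weighting
("no tissue to score"); a score group whose maximum is not positive errors
(whole group corrupt). Ties at the rejection threshold keep. Rank-deficient
per-voxel systems and QP failures degrade to flagged NaN / unconstrained
fallback, never silent garbage. Smoothing is in-plane 2D (slices are 5 mm
against 1.4 mm in-plane — through-plane smoothing would mix far more
tissue than it removes noise), FWHM 2.5 mm by default, zero-padded
convolution. `fwhm = 0` is the identity. Gradient schemes use a spherical
Fibonacci half-sphere layout rotated by a seeded random rotation; any
scheme read from bval/bvec files works identically.

## Problem sizes used by the shipped studies

Detector validation: ten 128×128×10 phantoms at SNR 20 (the reference
acquisition geometry). Protocol MSE study: five 64×64×4 replicates.
Workflow contrast: 18 + 18 replicates at 64×64×6. These are the package's
own choices of study size, balancing Monte-Carlo stability against a
single-core run of a few minutes; all are configurable.
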