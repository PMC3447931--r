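---
title: "alffkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{alffkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`alffkit` implements a voxel-based resting-state fMRI analysis built
around the amplitude of low-frequency fluctuation (ALFF): per-subject
ALFF maps standardized by the global mean, a two-group voxel-wise
comparison with cluster-level family-wise error (FWE) control by
permutation, grey-matter (GM) covariate adjustment, and correlation of
volume-of-interest (VOI) mean ALFF with clinical measures of amyotrophic
lateral sclerosis (ALS) severity. A synthetic cohort generator with
planted, exactly known effects provides the ground truth every stage is
validated against.

## The ALFF model

For a voxel time series $x_0, \dots, x_{N-1}$ sampled at the repetition
time $\mathrm{TR}$, the one-sided amplitude spectrum is computed by FFT
without padding or tapering and normalized as

$$a(k) = \frac{2}{N}\,|X(k)|, \qquad 0 < k < N/2,$$

with $1/N$ at the DC and Nyquist bins, so a pure sinusoid of amplitude
$A$ on an exact bin is recovered as $a = A$. ALFF is the mean of $a(k)$
over the bins whose frequency $k/(N\cdot\mathrm{TR})$ lies in the
analysis band, 0.01–0.08 Hz by default, edges inclusive. "Square-rooted
power averaged over the band" is read as the magnitude spectrum averaged
over in-band bins — i.e. the average of square roots, not the square
root of the average, matching the convention of the REST-style tooling
this pipeline mirrors. Standardized ALFF (mALFF) divides each voxel by
the mean ALFF over an explicit brain mask, so the in-mask mean is
exactly 1. Because the normalization constant cancels in this ratio,
mALFF is invariant to the $2/N$ convention; the test suite asserts this
to $10^{-9}$.

With $N = 190$ retained volumes at $\mathrm{TR} = 2$ s, the in-band bins
are $k = 4..30$: 27 bins, which the suite checks by enumeration.

## Preprocessing contract

The pipeline assumes spatially aligned data (the generator produces it
on a common grid) and applies, in order:

* **Initial-volume discard** (default 10 of 200) for signal
  equilibration.
* **Motion QC**: a run fails if, on any axis, the translation range
  reaches 2 mm or the rotation range reaches 1 degree. The published
  rule is "less than 2 mm … less than 1°", so the boundary itself fails;
  ranges (max minus min) are used as the displacement measure.
* **Spatial smoothing**: separable Gaussian,
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in voxel units,
  half-sample reflective boundaries (constants are preserved exactly,
  which makes the behaviour testable). Default 8 mm FWHM. Whether
  smoothing precedes or follows ALFF is not fixed by the source
  pipeline's description; here smoothing precedes ALFF (the SPM
  preprocessing order), stated as a convention.
* **Ideal band-pass**: FFT, zero every bin outside
  $[f_{lo}, f_{hi}]$ (a bin is in-band iff
  $f_{lo} \le k/(N\,\mathrm{TR}) \le f_{hi}$), inverse FFT. Rectangular,
  no taper ("taper percent 0"); linear and idempotent. Linear detrending
  is available but off by default — the band-pass already removes a
  linear drift's low-frequency power, and the upstream description never
  states detrending.

Since ALFF averages only in-band bins, band-passing before ALFF does not
change the statistic; the filter is kept in the chain for fidelity and
for users exporting filtered series.

## Group inference

Voxel-wise pooled-variance two-sample t statistics (patients minus
controls), $df = n_A + n_B - 2$. Zero-variance voxels get $t = 0$ and
are counted rather than propagating NaN. Suprathreshold clusters are
connected components of $\{t > t_c\}$ and $\{t < -t_c\}$ separately,
default 18-connectivity (SPM's convention; 6 and 26 available), with the
cluster-forming threshold taken as a t value — default 3.32, the
one-tailed $p < 0.001$ quantile at 38 df; `critical_t()` re-derives it
from $(\alpha, df)$. The printed $t > 3.32$ matches the *one-tailed*
0.001 quantile at 38 df, so one-tailed-per-direction cluster forming is
assumed.

**Cluster-level FWE is controlled by permutation**, not random-field
theory: group labels are permuted (or all label arrangements enumerated
when there are at most `n_permutations` of them), the maximum cluster
size over the permitted tails is recorded per permutation, and each
observed cluster receives
$p = (1 + \#\{\text{perm max} \ge \text{size}\})/(1 + B)$ — the add-one
estimator, so $p > 0$. In the exhaustive branch the exact proportion
over all arrangements (which include the observed one) is used instead,
as add-one would double-count the identity arrangement. This is a
deliberate divergence from the SPM8 random-field machinery the original
analysis used: permutation is exact under exchangeability, requires no
smoothness estimation, and is feasible at desk scale. The null
calibration test (200 null cohorts) checks the realized family-wise
false-positive rate lies in $[0.02, 0.10]$ at $\alpha = 0.05$.

**Covariate adjustment.** The GM-corrected analysis fits, at each voxel,
`malff ~ intercept + group + gm(voxel)` with the subject's GM
probability at that voxel as the covariate (the Biological Parametric
Mapping idea), returning the group-coefficient t with $df = n - 3$.
Voxels where the covariate is constant across subjects drop it and fall
back to the two-group fit; remaining rank-deficient voxels yield
$t = 0$ and are counted. The scalar-covariate variant (e.g. total
intracranial volume for GM-volume comparisons) fits the same model with
one covariate value per subject; a globally constant covariate is
dropped with a warning ($df = n - 2$). Both are verified against
per-voxel `lm()` oracles to $10^{-8}$.

Peak coordinates are reported in world mm via the map affine (0-based
voxel indices in a debug column) and converted to Talairach space with
the standard Brett piecewise-affine `mni2tal` constants (one matrix for
$z \ge 0$, one for $z < 0$); the source text does not print the
coefficients, so the published constants are adopted as named constants.

## Clinical statistics

Progression rate follows the tabulated footnote definition,
$(40 - \mathrm{ALSFRS})/\text{duration (months)}$. (The running text
describes ALSFRS divided by duration; the footnote formula — also the
field-standard one — is implemented.) VOI analysis extracts the mean
mALFF over each significant cluster per patient and computes Pearson
correlations with duration, progression rate and ALSFRS;
$p = 2P(T_{n-2} \ge |r|\sqrt{n-2}/\sqrt{1-r^2})$. Significance is
flagged at two-tailed $p < 0.05$ *uncorrected*, matching the study
convention; a Bonferroni option exists but is off by default. Signed
$r$ is reported without interpretation (the source prose and its printed
signs disagree for the two significant correlations).

## The synthetic cohort: what it emulates, and what it does not

Defaults state the emulated world: two groups of 20, TR 2 s, 200 volumes
(10 discarded), and clinical marginals matching the published cohort
table (age 45.30 ± 9.95 vs 47.05 ± 9.89 years, 13:7 vs 14:6 male:female,
duration 15.20 ± 10.37 months, ALSFRS 31.85 ± 5.39, onset sites 4:10:6).
The default grid is 16³ voxels of 3 mm — a deliberately reduced field of
view that keeps Monte-Carlo calibration affordable; the voxel size
matches the resampled analysis grid of the emulated pipeline.

Per voxel, the in-band signal is the sum of $K = 8$ sinusoids on
randomly chosen exact FFT bins of the *retained* run length with
independent uniform phases; each has amplitude `baseline_amp`, times the
ROI multiplier for patients inside planted spherical ROIs. Exact-bin
placement gives closed-form spectra: with zero noise, ALFF equals
$K \cdot a_v / (\#\text{in-band bins})$, so the patient/control ALFF
ratio inside an ROI equals the multiplier exactly, and recovery of the
true amplitude map is exact up to one global constant. Nuisance
"respiratory" (0.3 Hz) and "cardiac" (1.1 Hz, aliased by the 0.25 Hz
Nyquist) sinusoids are snapped to the nearest exact out-of-band bin of
the retained length: without snapping, rectangular-window leakage from
off-bin frequencies would bleed into in-band bins and break those closed
forms. White noise (SD 1 by default, about half the in-band signal SD)
is smoothed spatially (6 mm FWHM) to give noise maps realistic spatial
correlation.

Clinical coupling draws the chosen covariate as
$r\,z(\text{ROI amplitude}) + \sqrt{1-r^2}\,\varepsilon$ on standardized
scales across patients, then maps it linearly to clinical units
(truncated at physical bounds; truncation is rare at the default
scales). This requires across-subject amplitude variance, so a lognormal
per-subject jitter (SD 0.2) on the designated ROI is enabled
automatically with coupling (it is 0 otherwise, keeping the exact
closed-form examples exact). GM maps are smoothed uniform random fields
rescaled to $[0,1]$, independent of the planted effects unless
`gm_roi_coupling` is set (which depresses patient GM inside the ROIs to
exercise the covariate correction). Motion traces are compliant random
walks; `motion_violators` injects mid-run jumps that fail QC.

Not emulated: hemodynamics, scanner artefacts, susceptibility
distortion, registration error, and anatomically realistic brain shape
(the mask is an ellipsoid). A green recovery test therefore establishes
that the *statistical machinery* recovers planted spectral effects at
realistic SNR — not that the pipeline is robust to acquisition
confounds it never sees.

One behaviour of real ALFF analyses that the generator *does* reproduce
is worth flagging: because mALFF divides by the global mean, a strong
localized amplitude increase depresses standardized values everywhere
else, so a planted positive ROI also produces a genuine, diffuse
negative "dilution" effect. Tests therefore select detected clusters by
tail rather than assuming the largest cluster is the planted one.

## Numerical choices and degenerate inputs

* FFT length equals the number of time points (no padding), matching the
  "FFT length = shortest" setting for equal-length runs.
* Band edges are inclusive on exact bins.
* Smoothing kernels are truncated at $4\sigma$ and renormalized.
* `standardize_alff` refuses non-positive global means; `compute_alff`
  reports the bin count when a band contains no bins.
* Permutation p-values: add-one estimator (sampled branch), exact
  proportion (exhaustive branch); ties in cluster size are counted
  conservatively (`>=`).
* All NIfTI output is little-endian float32 (uint8 for masks) with the
  affine in the sform; loading rejects NaN voxels outright.
* NIfTI I/O is implemented in-package (the deployment environment has no
  R NIfTI reader); it is cross-validated against nibabel in the test
  suite.

## Known limitations

Random-field-theory p-values, fractional ALFF, ReHo, paired and
multi-group designs, slice timing, realignment and spatial normalization
are out of scope. The permutation FWE needs exchangeability under the
null — true for the generator, an assumption for real two-sample data.
Monte-Carlo acceptance tests run at reduced scale (16³ grids, 64
volumes, 500 permutations, 100–200 replicates) to fit a desktop time
budget; the bands they assert ($[0.02, 0.10]$ for the null family-wise
error rate) account for that Monte-Carlo error.
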