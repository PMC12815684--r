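---
title: "Separating iron and myelin contributions to subcortical susceptibility: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chisep methods}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative susceptibility mapping (QSM) measures tissue magnetic
susceptibility $\chi$ (in parts per billion, ppb). In subcortical gray
matter, $\chi$ rises with paramagnetic iron and falls with diamagnetic
myelin, so a case-control difference in $\chi$ — for instance, lower
subcortical $\chi$ in schizophrenia — is ambiguous on its own: it could
reflect less iron or more myelin. `chisep` implements an analysis pipeline
that disambiguates the two by combining three measurements:

1. **ROI statistics** on subcortical $\chi$ and diffusion-derived mean
   diffusivity (MD, which falls with myelin and tissue density);
2. **white-matter magnetic susceptibility anisotropy** $\delta\chi$, a
   myelin marker insensitive to iron, estimated from the orientation
   dependence of white-matter $\chi$;
3. **voxelwise inference plus imaging transcriptomics**, associating the
   spatial pattern of the case-control $\chi$ difference with regional gene
   expression and cell-type-specific gene sets.

Every stage also has a synthetic-data generator that emulates the
statistical structure the stage assumes, so the whole pipeline is testable
without any imaging or expression download.

## ROI statistics

Group differences use the pooled-SD standardized mean difference
$d = (\bar x_P - \bar x_C)/s_p$ and independent-sample t-tests (Student
pooled-variance by default; Welch behind a flag — the two agree exactly for
equal sizes and SDs). Families of ROI comparisons are corrected by
Benjamini–Hochberg FDR (`bh_fdr()`, a thin wrapper over the step-up
adjustment); the FDR family is the set of subcortical ROIs per metric, and
clinical Pearson correlations are corrected within their own family.

Confounder-adjusted models use Huber M-estimation (`huber_regress()`),
fitted by iteratively reweighted least squares with tuning constant
$k = 1.345$ (95% Gaussian efficiency), MAD scale re-estimated each
iteration, convergence when the largest coefficient change falls below
1e-8 (at most 100 iterations), and Huber-type asymptotic standard errors.
On data whose scaled residuals all lie inside $k$ the estimate is exactly
least squares. The final adjusted model (`final_model()`) regresses
whole-subcortex $\chi$ on case-control status, smoking (current/past),
THC urine screen, sex, age, subcortical MD, and white-matter $\delta\chi$
— nine terms including the intercept. Missing MD and $\delta\chi$ are
imputed with the subject's *group* mean ("group means" read as per-group;
a whole-sample option exists).

## Susceptibility anisotropy

In white matter, $\chi$ depends on the fiber-to-field angle $\theta$
(between the dominant fiber orientation and the scanner's main field):

$$\chi = \delta\chi \cos^2\theta + \chi_{\mathrm{iso}}.$$

`prepare_wm_voxels()` applies the retention rules: the white-matter mask is
eroded by a 2 mm digital-ball radius (a voxel survives if every in-ball
neighbour is in-mask; the discretization is a distance criterion on voxel
centers), tract masks by one 6-connected erosion; voxels need fractional
anisotropy $\ge 0.6$ (lower FA marks crossing fibers) and $\chi$ inside the
censoring bounds, by default the fixed $[-110, 30]$ ppb pair (a switch
recomputes 1st/99th percentiles instead). Retained voxels are sorted by
$\theta$ into 10 equally populated bins (sizes differing by at most one,
the first bins taking the remainder), and ordinary least squares of the
per-bin mean $\chi$ on the per-bin **mean of** $\cos^2\theta$ gives
$\delta\chi$ (slope) and $\chi_{\mathrm{iso}}$ (intercept), with a
two-sided slope t-test on 8 df.

The regressor choice matters at second order: under the model the bin-mean
$\chi$ is *exactly* linear in the bin mean of $\cos^2\theta$, so that
regressor gives an unbiased (and, noiselessly, exact) estimator, whereas
$\cos^2(\bar\theta)$ attenuates the slope by roughly 0.7% under a random
3-D orientation distribution. We therefore default to the bin mean of
$\cos^2\theta$; `regressor = "cos2_mean_theta"` restores the alternative.

Tract selection pools all control voxels per tract and keeps tracts with
$\delta\chi > 0$ and $p < 0.05$; a participant's white-matter $\delta\chi$
is the unweighted mean of their per-tract fits over the selected tracts
(subject-level fits reuse the identical binning/fit code). Subject fits
default to a minimum of 100 retained voxels.

## Voxelwise inference

`voxel_glm()` fits, per voxel, $\chi$ on case-control status adjusting for
smoking, THC, sex and age — Huber regression with OLS fallback at voxels
where IRLS fails — after censoring values outside $[-74, 171]$ ppb (the
pooled 1st/99th percentile reading; the bounds are a single pair, not
per-voxel). The group-coefficient t-score map feeds threshold-free cluster
enhancement:

$$\mathrm{TFCE}(v) = \sum_{h} e_h(v)^{E}\, h^{H}\, \mathrm{d}h,$$

with $e_h(v)$ the size of the suprathreshold connected component containing
$v$. Defaults are the standard $E = 0.5$, $H = 2$, 26-connectivity, and
$\mathrm{d}h$ = 1/100 of the observed maximum statistic, held fixed across
permutations. Negative and positive tails are enhanced separately and
recombined with sign. The implementation processes thresholds from high to
low with a union-find merge tree (exactly equal to the brute-force
threshold loop, which the tests verify), making 10^4 permutations
practical on one CPU.

`permutation_inference()` builds the null by the Freedman–Lane scheme —
residuals under the nuisance-only model are permuted and the full model
refitted — with simple label permutation behind a flag. Voxel p-values use
the plus-one rule on the enhanced magnitude (never exactly zero), are
BH-FDR corrected across in-mask voxels, and significant clusters are
connected components of adjusted $p < 0.05$ reported with sign, size, peak
voxel and peak t. One deliberate choice: the observed and permuted
statistic maps use the *same* estimator, and that estimator defaults to
OLS score maps. Permutation validity rests on the observed statistic being
exchangeable with the null ensemble, and refitting a per-voxel M-estimator
thousands of times is orders of magnitude slower; this mirrors standard
permutation tools. `robust = TRUE` switches both sides to Huber fits.
Constant nuisance columns (e.g. a smoking category no subject occupies)
are dropped before fitting.

## Imaging transcriptomics

Expression samples are matched to the t-score voxel whose center is
nearest their MNI coordinate; samples landing outside the analysis mask
are dropped with a count. Each gene is normalized by a robust sigmoid,
$y = \left[1 + \exp\!\big(-(x - \mathrm{med}(x)) / (\mathrm{IQR}(x)/1.35)\big)\right]^{-1}$,
rescaled to $[0,1]$; zero-IQR genes are dropped and flagged.

`plsr_nipals()` is partial least squares regression for a univariate
response (NIPALS with deflation; for one response the inner loop is
non-iterative). The component count is chosen by five sets of five-fold
cross-validation (`select_components_cv()`): out-of-fold Pearson r per
candidate $K \in \{2,\dots,10\}$, averaged over the five repeats, argmax
with ties to the smaller $K$. Significance uses the mean cross-validated r
over components 2–10 as the statistic, compared against (a) random
permutations of the t-scores and (b) variogram-matched spatially
autocorrelated surrogates, each with the plus-one rule. The surrogate
generator is self-contained: permute the map, smooth with Gaussian
distance kernels over the $k = \min(30, n-1)$ nearest neighbours, mix with
a white-noise term whose two weights are least-squares fitted to the
25-bin empirical variogram of the original, then re-rank to the original
marginal distribution. Tests require the surrogates to beat naive
permutations at variogram fidelity in at least 95% of runs.

Gene importance is the VIP score,
$\mathrm{VIP}_j = \sqrt{G \sum_a SS_a w_{ja}^2 / \sum_a SS_a}$ (mean
squared VIP is 1 by construction), divided by its bootstrap standard error
(paired resampling of samples with their t-scores by default; t-score-only
resampling behind a flag — the source description is ambiguous between the
two). VIP is non-negative, so the z-score is signed by the gene's Pearson
correlation with the t-scores (first-component weight sign available);
neither convention is asserted as the original one. Genes are ranked by z
descending (rank 1 = most associated with higher $\chi$ in patients) and
ascending; export drops genes absent from a supplied brain-expressed list
but VIP/z are computed on the full panel first.

The cell-type test measures how far a cell-specific gene list's median
rank deviates from the list center $(G+1)/2$; negative deviation ties the
cell type to higher $\chi$ in patients, positive to lower. Two-sided
significance comes from 10,000 random same-size gene sets.

## The synthetic generators

`simulate_cohort()` draws per-subject ROI metrics from per-group normal
distributions whose defaults are the reference study's group summaries
(80/79 subjects with $\chi$; the first 43/73 of each group also carry MD
and $\delta\chi$, the diffusion subsample), with a heavier-tailed t(3)
switch for robustness studies. Covariates the source tables do not print
were fixed once at realistic values: smoking (non/past/current) 60/20/20%
in controls and 40/20/40% in patients, THC-positive screens 5% vs 15%, and
participant $\delta\chi$ mean 20.4 vs 17.4 ppb at SD 8 ppb (reproducing
the reported $d \approx -0.37$; the control mean is the average of the
four selected-tract slopes). Confound coefficients (age, sex, smoking,
THC on $\chi$) default to zero and exist to plant confounding.

`simulate_tract()` draws $\theta$ from the angle distribution of a
uniformly random 3-D direction by default ($\cos\theta \sim U(0,1)$),
applies the anisotropy equation exactly, and adds Gaussian noise;
`simulate_expression()` builds gene maps as squared-exponential
Gaussian-process fields over the sample coordinates (correlation length 0
gives spatially white maps) in which a configurable set of causal genes
share latent component fields that drive the t-score map.

Model-order recovery deserves a note: PLS1 reaches the response through a
Krylov space, so a three-component panel only *requires* three components
when the three latent directions are spectrally distinct. The recovery
tests therefore use per-component loading scales (4, 2, 1) with spatially
white gene maps; with equal scales, or strong spatial autocorrelation
shared between causal and background genes, the cross-validation optimum
legitimately sits at 2 or above 3 — a property of the estimand, not a
defect of the selector.

What the generators do *not* emulate: anatomically realistic atlas
geometry, MRI physics (dipole kernels, phase processing), registration
error, donor- and probe-level expression artifacts, and spatially varying
noise. Green tests demonstrate the statistical machinery is correct under
its own assumptions, not that those assumptions hold in any given dataset.

## Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to exercise each property
clearly: null calibration of the voxelwise engine uses 100 replicates of
500 permutations on a 20-voxel cube with 40 subjects; PLSR null
calibration uses 100 simulations of 200 permutations at 40 samples x 60
genes; slope-test calibration uses 2000 simulated tracts of 200 voxels;
the contamination study places the 10% gross outliers at the
highest-leverage design points, where slope damage is expressed. Seeds are
fixed throughout; all generators are pure functions of (config, seed).
Degenerate inputs (empty masks after erosion, empty tract voxel sets,
constant scores, zero-IQR genes, all-censored voxels) warn or flag rather
than abort wherever the pipeline can continue, and error where an estimate
would be meaningless (rank-deficient designs, degenerate angle
distributions, zero bootstrap SEs).

## Known limitations

* Real-data effect sizes, cluster coordinates, and the PLSR r = 0.48 of
  the motivating study are not reproducible without that study's MRI data;
  the acceptance surface is printed-summary worked examples plus
  calibration/recovery properties.
* Registration, reslicing between native spaces, QSM reconstruction and
  tract segmentation are out of scope; volumes must arrive aligned (the
  package checks shape and affine agreement to 1e-4 mm and only resamples
  label atlases, by nearest neighbour, explicitly).
* The robust per-voxel fit falls back to OLS at voxels where IRLS fails;
  with 10% of a small subject sample censored at a voxel the fit can be
  unstable, which is flagged rather than hidden.
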