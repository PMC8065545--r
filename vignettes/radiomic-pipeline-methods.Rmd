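---
title: "Methods: a reproducible radiomic pipeline for prostate mpMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reproducible radiomic pipeline for prostate mpMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, the design choices
made where the methodology is genuinely open, and what the synthetic-cohort
validation does and does not demonstrate.

## 1. The problem

Radiomics extracts large panels of quantitative descriptors from medical
images in the hope that some of them behave as biomarkers. For prostate
cancer the clinically pressing question is preoperative aggressiveness
assessment: Gleason grade group (GGG), extracapsular extension (ECE) and
nodal involvement (pN) are only known reliably after surgery, while
multiparametric MRI (T2-weighted imaging plus diffusion-weighted imaging
summarised as the apparent diffusion coefficient, ADC) is available before.
The pipeline implemented here takes per-patient T2w volumes, a two-b-value
DWI pair, binary lesion delineations from two readers, and a clinical label
table, and produces (i) a stability- and redundancy-screened feature panel,
(ii) unsupervised radiomic phenotypes tested for association with the
pathological endpoints, and (iii) supervised signature evaluations under
class-imbalance-aware resampling.

## 2. Preprocessing

**ADC computation.** The monoexponential diffusion model
$S(b) = S_0 e^{-b\,\mathrm{ADC}}$ is inverted from two acquisitions:
$\mathrm{ADC} = \ln(S_{b_1}/S_{b_2})/(b_2-b_1)$ with $b_1 = 50$,
$b_2 = 800$ s/mm². Low b-values above zero suppress perfusion
contamination; two points determine the single exponential exactly, so the
inversion is algebraic. Voxels with nonpositive signal (noise floor) cannot
be inverted; they are set to 0 and counted, rather than aborting the map.

**T2w standardization.** T2w intensities are scanner-arbitrary; the pipeline
applies the affine map sending the volume minimum/maximum to 0/600. The
min/max are taken over the whole volume, not the VOI, because
standardization precedes any segmentation-dependent step. No percentile
clipping is applied — the rule is the plain min/max map, stated as such.
Bias-field correction is treated as upstream acquisition preprocessing: the
pipeline expects corrected volumes and the synthetic generator produces
bias-free images.

**Volume filter.** Only lesions whose ADC-modality delineation strictly
exceeds 0.7 cc enter the analysis (the ADC map has the coarser resolution;
a VOI under ~4 voxels per direction makes texture matrices meaningless).
The boundary is strict: exactly 0.7 cc is excluded, and such cases are
flagged in the exclusion report.

## 3. Feature extraction

Each (image, mask) pair passes through a fixed chain, fully deterministic:

1. **Isotropic resampling.** Target spacing = the smallest in-plane spacing
   on all axes (with the default (0.6, 0.6, 3.0) mm grid this upsamples the
   slice axis fivefold). Intensities are tri-linearly interpolated, masks
   nearest-neighbour; the interpolator choice is a convention documented
   here, as is the target-spacing rule.
2. **Collewet re-segmentation.** In-mask voxels outside mean ± 3 SD (sample
   SD, single pass, no iteration) are dropped. A single pass cannot empty
   the VOI.
3. **Fixed-bin-number discretization.** 64 gray levels,
   $\ell(x) = \min(64, \lfloor 64 (x - x_{\min})/(x_{\max}-x_{\min})\rfloor + 1)$;
   the maximum maps exactly to level 64 through the clamp, a constant VOI to
   level 1. Because the bin edges are recomputed from the VOI range, all
   downstream texture features are invariant under positive affine intensity
   rescalings (and only affine ones — equal-width bins do not commute with
   nonlinear monotone transforms).

**The 93 features.** 14 morphological + 18 first-order + 61 textural
(24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM) — the unique standard family
partition consistent with those totals. The exact name lists follow the
common radiomics convention and are frozen in `feature_names()`.
Morphology is computed on the resampled mask before intensity
re-segmentation; intensity and texture on the re-segmented VOI.

*Morphology.* Surface area and mesh volume come from a triangulated
iso-surface of the mask indicator (Kuhn 6-tetrahedra decomposition per grid
cube, marching-tetrahedra case logic, divergence-theorem volume). The
indicator is smoothed with a small Gaussian (σ = 0.7 voxels) before
iso-surfacing at level 0.5: meshing a raw binary field yields a staircase
surface whose area does not converge to that of the underlying smooth shape,
and the smoothing removes most of that bias (the digitized-ball test keeps
sphericity within [0.95, 1.0]). Masks too small to survive smoothing fall
back to the raw field. Elongation and flatness are
$\sqrt{\lambda_2/\lambda_1}$ and $\sqrt{\lambda_3/\lambda_1}$ from the
eigenvalues of the physical voxel-coordinate covariance; a degenerate
(point-like) mask is defined isotropic (both = 1).

*Texture.* GLCM and GLRLM are built per each of the 13 unique 3D directions
at Chebyshev distance 1, counting in-mask voxel pairs/runs only, and the
feature values are averaged over directions (the convention of the common
extraction tools); GLSZM zones are 26-connected equal-level components
(direction-free); NGTDM uses the in-mask 26-neighbourhood mean. Degenerate
fallbacks are defined so the 93-vector is always finite: GLCM correlation of
a single-level VOI is 1, NGTDM busyness/strength 0 when their denominators
vanish, coarseness capped at 10⁶, first-order skewness/kurtosis of a
constant VOI 0. Every matrix builder is verified in the test suite against
an independent brute-force enumeration (explicit pair loops, a naive run
scanner, recursive flood fill, per-voxel neighbourhood loops) on randomized
small VOIs.

## 4. Feature selection

**Stability.** For each feature, the Friedman rank test compares the two
readers' values across patients; tie-corrected statistic, chi-square
reference with k−1 degrees of freedom. With k = 2 readers this reduces to a
sign test, so the p-value is discrete; the chi-square approximation is
compared against exact permutation enumeration in the tests, where the
decisions at α = 0.05 agree outside the discreteness window just above the
threshold. A feature is *stable* iff p > 0.05 strictly; fully tied data
(0/0 tie correction) is read as "no evidence of a reader effect", p = 1.
The *stability rank* orders by descending p — the only ordering monotone in
the stability decision — with ties broken by the canonical feature order.

**Redundancy.** Pearson correlations across patients; features joined when
|r| > 0.8 (absolute value, to catch anti-correlated duplicates); clusters =
connected components of that graph — deterministic and parameter-free,
though transitivity means two representatives of different clusters are not
themselves guaranteed below the threshold, and the tests assert the property
that *is* guaranteed: every pruned feature exceeds the threshold against
some member of its own cluster. Each cluster keeps its highest-CoV member
(CoV = sample SD / |mean|; scale-free, so it compares features across
units), ties to the earlier candidate; constant features correlate with
nothing by convention (r set to 0) and carry CoV 0.

**Signatures.** Per modality, the top-10 features of the stability rank are
reduced *among themselves* to non-redundant representatives; the per-modality
results union into the joint signature, and the lesion mean ADC is evaluated
both alone and appended to the joint set. (An alternative reading —
intersecting the top-10 with the cohort-wide representative set — collapses
to the empty set whenever the cohort-wide representative of a cluster sits
outside the top-10, so the within-top-10 reduction is the one implemented;
the cohort-wide reduction is still computed and feeds the clustering stage.)

## 5. Unsupervised association

Features with extreme values (|sample skewness| > 2, a configurable
threshold — no canonical rule exists) are log2-transformed after replacing
zeros with the column's smallest positive value; columns are standardized to
zero mean and unit sample SD (constant columns dropped); patients are
agglomerated with Euclidean distance and complete linkage and the tree is
cut at k = 2 (the analysis is defined for two radiomic phenotypes; no
automatic k selection). Group 1 is the group containing the first patient,
making the labelling deterministic. The two groups are tested against GGG
(dichotomized at ≥ 4+3), ECE, and pN (pN0 vs pN≥1, with pNx patients
excluded from this table only) by a two-sided Fisher exact test implemented
by direct hypergeometric enumeration (all tables with the observed margins
whose probability does not exceed the observed one, with 1e-7 relative
slack; zero-margin tables give p = 1). The implementation is verified
against the independent base-R implementation over exhaustive small tables.

On the synthetic cohort, complete linkage tends to cut off a handful of
outlier patients rather than split the two planted classes: heavy-tailed
size-type features dominate the Euclidean metric even after the log2/z-score
preprocessing, and the class signal is diluted across a minority of the
representative features. The association p-values are then near-null even
though the supervised signatures separate the same classes almost perfectly.
This divergence is a property of the unsupervised step worth knowing about;
`hierarchical_two_groups()` exposes the linkage method for users who prefer
a variance-minimizing cut (ward.D2).

## 6. Signature evaluation

The endpoints are imbalanced, so each evaluation draws 10 balanced subsets:
all minority-class patients plus an equal-size uniform draw (without
replacement, fresh per subset) from the majority class. How performance is
estimated *within* a balanced subset is not pinned down by the methodology
this pipeline follows; resubstitution would be optimistically biased, so the
package adopts stratified 5-fold cross-validation per subset, z-scoring
features on the training folds only and pooling fold predictions into one
confusion matrix per subset. This is the main place where a defensible
alternative reading exists, and it is therefore exposed (`cv_folds`) and
flagged here. The classifier is a radial-kernel SVM with
library-conventional hyperparameters (cost 1, kernel width 1/d on the
standardized scale), deliberately untuned. Sensitivity counts the
high-GGG / ECE-present / pN≥1 class as positive. Summaries are mean, SD,
min and max over the 10 subsets; ROC curves pool the signed decision values
across subsets and integrate by the trapezoidal rule (the tests pin the AUC
to the Mann–Whitney identity). TZ-only lesions are never analysed as a
separate stratum (too few by construction); the PZ subset is re-analysed in
full.

## 7. The synthetic cohort

The generator replaces unavailable patient data and defines the study
conditions; its defaults are fixed once:

| parameter | default | rationale |
|---|---|---|
| grid, spacing | 48×48×14 at (0.6, 0.6, 3.0) mm | lesion-centred subvolume; 3 mm slices exercise anisotropic resampling |
| cohort size | 102, of which 40 below 0.7 cc | matches the volumetric-exclusion structure the filter must reproduce |
| included-lesion radius | 5.8–9.0 mm equivalent-sphere | 0.8–3 cc VOIs, safely above the filter |
| sub-threshold radius | 3.0–5.0 mm | ≤ 0.52 cc, safely below it |
| mean ADC (low/high GGG) | 1.4 / 0.9 ×10⁻³ mm²/s | the established direction: denser tumours diffuse less |
| texture correlation length | 1.5 / 3.0 mm FWHM | coarser texture in aggressive lesions, detectable by GLCM at 0.6 mm lags |
| T2w class means | 420 / 300 (background 200) | hypointense aggressive lesions on standardized T2w |
| reader jitter | 1.2 mm, Dice ≥ 0.6 | sub-slice-thickness boundary disagreement |
| label frequencies | high-GGG 0.71, ECE 0.61, pN≥1 0.25 of assessable, pNx 0.16, PZ 0.69 | the imbalance profile the undersampling must handle |

Lesions are ellipsoids (volume-preserving random anisotropy, random
in-plane rotation) whose interior is a Gaussian random field — white noise
smoothed to the class's correlation length (FWHM), scaled and shifted to
the class mean — on a uniform background; the DWI pair is generated so the
monoexponential relation holds voxel-wise *exactly* before noise, which is
what makes the ADC-inversion identity testable to floating-point tolerance.
ECE and pN are drawn conditionally on the class so that their marginals
match the table above while remaining genuinely associated with the
image-generating class; their link is stochastic, so endpoint predictability
decays from GGG to ECE/pN by construction.

**Two readers.** Both readers' masks are independent volume-matched
perturbations of the true boundary: the erosion of the truth by the jitter
depth is always kept, the dilation never exceeded, and within that shell a
smooth random field selects exactly as many voxels as the truth owns there
(so a reader never biases the VOI volume), with draws retried until Dice
≥ 0.6. An earlier design — reader 2 as a perturbation of reader 1's exact
boundary — was abandoned: it systematically contaminates reader 2's VOI
with background tissue, and at n = 62 the sign test then flags nearly every
intensity feature unstable, which contradicts the premise of a
stability-screening step (most features should survive honest inter-reader
noise). The volume-matched, both-readers-err design restores that premise
without tuning any threshold.

**What the phantoms do not emulate:** prostate anatomy and zonal contrast,
endorectal-coil bias fields, motion/susceptibility artifacts, Rician noise
statistics (noise is additive Gaussian), non-monoexponential diffusion
(IVIM, kurtosis), DCE imaging, and genuinely independent human readers.
Passing tests on this cohort therefore demonstrate the *pipeline's*
correctness and its ability to recover planted structure — not clinical
performance on real mpMRI.

## 8. Numerical choices and problem sizes

Determinism is a contract: one master seed fans out to per-stage seeds by
fixed offsets, and every stochastic operation (cohort, reader masks,
undersampling draws, fold assignment) goes through it; identical
configuration gives bit-identical tabular outputs. Degenerate inputs have
defined, logged behaviour rather than errors wherever a finite answer
exists (constant VOIs, zero-margin tables, all-tied readings, zero-mean
CoV). Oracle comparisons in the tests run at 1e-10 relative tolerance on
texture matrices and exact equality on run/zone enumerations.

The validation suite exercises the full pipeline on one 102-lesion cohort
(62 analysed patients, two modalities, two readers — 248 extractions) plus
randomized small-grid oracle checks; these sizes keep a complete run in the
minutes range on a single CPU while leaving every stage's logic fully
covered. The analysis scripts run the same cohort at the same size.

## 9. Known limitations

* The feature name lists within the fixed 14/18/61 partition are a
  documented convention; other toolkits make slightly different choices
  (e.g. which of the deprecated compactness variants to include).
* The within-subset evaluation protocol (cross-validation vs held-out vs
  resubstitution) materially affects absolute accuracy values; only the
  cross-validated protocol is implemented.
* With two readers the stability test is a sign test; its p-values are
  discrete and the chi-square approximation is coarse at small n (the tests
  quantify exactly where).
* Complete-linkage two-group cuts on heavy-tailed radiomic features can
  isolate outliers instead of phenotypes (see §5).
* Shape features rely on a smoothed-indicator mesh; surface areas of
  structures at the scale of one voxel are resolution-limited by
  construction.
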