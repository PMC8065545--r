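# radpipe — reproducible radiomics for multiparametric prostate MRI

`radpipe` implements a complete radiomic analysis pipeline for
multiparametric prostate MRI (mpMRI) lesions, aimed at researchers who want
to study how quantitative imaging features relate to pathological markers of
prostate-cancer aggressiveness — Gleason grade group (GGG), extracapsular
extension (ECE) and nodal stage (pN) — and at methodologists who need a
tested, deterministic reference implementation of the standard radiomics
chain. Because patient imaging of this kind is generally not shareable, the
package ships a synthetic 3D lesion-phantom cohort generator with the same
statistical structure (anisotropic voxel grids, two-reader delineations,
class-dependent intensity and texture, imbalanced clinical labels), so the
entire workflow can be exercised, validated and benchmarked end to end.

## What the pipeline computes

1. **Preprocessing.** ADC maps from a two-b-value DWI pair via the
   monoexponential diffusion model, ADC = ln(S_b1/S_b2)/(b2 − b1) (mm²/s,
   b1 = 50, b2 = 800 s/mm²); T2w intensity standardization by linear scaling
   into 0–600; a volume-of-interest (VOI) inclusion filter keeping lesions
   whose ADC delineation exceeds 0.7 cc.
2. **Feature extraction.** 93 features per (image, mask): 14 morphological
   (mesh-based surface/volume, sphericity (36πV²)^⅓/A, PCA
   elongation/flatness, diameters), 18 first-order intensity statistics, and
   61 textural features from GLCM (24), GLRLM (16), GLSZM (16) and NGTDM (5)
   matrices — computed after isotropic resampling, Collewet (μ ± 3σ)
   re-segmentation and 64-bin fixed-bin-number discretization, with the 13
   unique 3D directions averaged for GLCM/GLRLM.
3. **Feature selection.** An inter-reader stability rank per feature from
   the Friedman test across two readers' segmentations (stable ⇔ p > 0.05),
   then redundancy pruning: clusters of features with |Pearson r| > 0.8
   collapse to the member with the highest coefficient of variation.
4. **Unsupervised association.** Two-group hierarchical clustering of
   patients (Euclidean distance, complete linkage) on the non-redundant
   stable features; Fisher's exact test of the groups against GGG, ECE, pN.
5. **Signature evaluation.** Five signatures (per-modality and joint top-10
   stable non-redundant sets, lesion mean ADC alone, joint + mean ADC)
   evaluated with radial-kernel SVMs under 10-subset balanced undersampling
   and stratified cross-validation; accuracy/sensitivity/specificity as
   mean ± SD (min–max) over subsets, plus pooled ROC/AUC.

## Worked example

```r
library(radpipe)

# one synthetic high-grade lesion phantom
params <- phantom_params()
case <- generate_phantom(params, class_label = "high", seed = 7)
imgs <- prepare_case_images(case)          # ADC map + standardized T2w

voi_volume_cc(case$masks$adc$reader1, params$spacing_mm)
#> [1] 3.05532

fv <- extract_all(imgs$adc, case$masks$adc$reader1)
round(fv[c("fos_Mean", "shape_Sphericity", "glcm_Correlation",
           "glszm_SmallAreaHighGrayLevelEmphasis", "ngtdm_Busyness")], 4)
#>                             fos_Mean                     shape_Sphericity
#>                               0.0011                               0.6713
#>                     glcm_Correlation glszm_SmallAreaHighGrayLevelEmphasis
#>                               0.8004                             700.6124
#>                       ngtdm_Busyness
#>                               0.6033
```

The lesion passes the 0.7 cc filter (3.06 cc); its mean ADC of
1.1 × 10⁻³ mm²/s reflects the high-grade class setting, and the remaining
values are the lesion's texture/shape descriptors (an irregular ellipsoid,
hence sphericity well below 1). The statistical building blocks are exposed
directly:

```r
friedman_test(cbind(1:8, 1:8 + 1))[c("statistic", "p_value")]
#> $statistic
#> [1] 8
#> $p_value
#> [1] 0.004677735

fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))
#> [1] 0.4857143
```

## The analysis workflow

The full study is organised as numbered scripts under `analysis/`, each a
thin driver over the package functions, writing its tables under `results/`:

| script | stage |
|---|---|
| `01_simulate_cohort.R` | 102 lesion phantoms + label table (NIfTI + CSV) |
| `02_preprocess_filter.R` | input validation, 0.7 cc VOI filter |
| `03_extract_features.R` | 93 features × 2 modalities × 2 readers |
| `04_feature_selection.R` | Friedman stability rank, redundancy reports |
| `05_cluster_association.R` | radiomic phenotypes, Fisher p-values, heatmaps |
| `06_signature_evaluation.R` | SVM signature performance, ROC curves |

Run them in order (`Rscript analysis/01_simulate_cohort.R`, ...); the seed
comes from the `RADPIPE_SEED` environment variable (default 42). On the
default synthetic cohort the run reports 62/102 included lesions, ~90/93
features stable per modality, and mean balanced-subset accuracies for GGG of
0.96 (S_TOP-ADC), 0.81 (S_TOP-T2w) and 0.97 (S_TOP+ADCmean) — the planted
class signal lives in the ADC channel, and the supervised signatures recover
it. ECE and pN accuracies are lower by construction, since those labels are
only stochastically linked to the image-generating class (see the methods
vignette).

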