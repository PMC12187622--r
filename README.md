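# mrseries

Metadata-based MRI series-type identification and curation for prostate
multiparametric MRI (mpMRI).

Clinical machine-learning models for prostate cancer consume a triplet of
series per study — an axial T2-weighted image (T2W), a high b-value
diffusion-weighted image (DWI) and an apparent diffusion coefficient map
(ADC) — but PACS exports deliver unlabelled bags of DICOM series whose
descriptions and tags vary across centres and vendors. `mrseries` labels
each series as one of five types (`T2W`, `DWI`, `ADC`, `DCE`, `OTHERS`)
from DICOM *header metadata only*, then applies deterministic curation
rules to select the machine-learning-ready triplet.

The pipeline:

1. **Extraction** — a configurable tag set is read per slice, aggregated to
   one value per series (space-joined unique values) and sanitised with a
   four-step protocol: date substrings matching
   `[0-9]+[/-:][0-9]+[/-:][0-9]+` removed; missing values set to `-`;
   `| - ; , ( ) _ :` replaced by spaces; space runs squeezed.
2. **Features** — per-field word n-grams (n = 1–5, document frequency
   ≥ 0.01) with occurrence counts, plus five summary statistics (character
   count, sum, mean, min, max) for space-separated numeric fields; or raw
   factor pass-through for the native-categorical backend.
3. **Classification** — gradient-boosted five-class models trained with
   5-fold nested stratified cross-validation and random hyperparameter
   search, reported as per-class precision/recall/F1 with macro F1
   (unweighted mean over classes) as the headline metric:
   `F1_c = 2·P_c·R_c / (P_c + R_c)`, `macroF1 = (1/5) Σ_c F1_c`.
4. **Validation** — leave-one-centre-out CV (each fold holds out one centre
   entirely) against pooled CV, and learning curves over training fractions
   1–100 % with a two-step saturation detector (segmented fit of score on
   log-fraction + t-test of the post-breakpoint slope at α = 0.05).
5. **Curation** — five rules pick the triplet from predictions: axial plane
   via the argmax of the slice normal (cross product of the orientation
   cosine triplets, index 0/1/2 → sagittal/coronal/axial); T2W slice
   spacing strictly < 4.0 mm; exponential ADC excluded via an `EADC` token
   in ImageType; synthetic DWI excluded via a `synthetic` substring in the
   description; highest b-value DWI selected via tag (0018,9087) with GE
   (0043,1039, 1e9 offset) and Siemens (0019,100c) private-tag fallbacks.

A synthetic fixture generator produces labelled multi-centre DICOM studies
(real Part 10 files or metadata records) with vendor tag dialects,
configurable missingness and distractor series, so the entire pipeline is
testable without patient data, including controlled centre-shift
experiments.

## Worked example

```r
library(mrseries)

# 1. simulate a 3-centre dataset (100 studies, 800 series) and train
spec <- synthetic_study_spec(100, centres = default_centres(3), seed = 7)
records <- generate_dataset(spec)
fit <- nested_cv_train(records, backend = "engineered",
                       grid = hyper_grid(max_depth = c(4L, 6L), learning_rate = 0.3,
                                         nrounds = c(40L, 100L), n_iterations = 3L),
                       seed = 7)
fit$report
#> series-type evaluation on 800 series
#>   class precision recall f1 support
#>     T2W         1      1  1     200
#>     DWI         1      1  1     200
#>     ADC         1      1  1     100
#>     DCE         1      1  1     100
#>  OTHERS         1      1  1     200
#> macro F1 1.0000 | weighted F1 1.0000

# 2. predict new studies and curate the T2W/DWI/ADC triplet
new_records <- generate_dataset(synthetic_study_spec(
  5, centres = default_centres(3), seed = 99))
preds <- predict_series(fit$bundle, new_records)

study_uids <- vapply(new_records, `[[`, "", "study_uid")
study <- new_records[study_uids == unique(study_uids)[2]]
cur <- curate_study(preds, study)
cur$decisions[, c("predicted_label", "keep", "rules_fired")]
#>   predicted_label  keep                      rules_fired
#> 1             T2W  TRUE axial_plane;slice_spacing_lt_4mm
#> 2             T2W FALSE                  non_axial_plane
#> 3             DWI FALSE           synthetic_dwi_excluded
#> 4             DWI  TRUE                  highest_b_value
#> 5             ADC  TRUE                        plain_adc
#> 6             DCE FALSE                not_triplet_class
#> 7          OTHERS FALSE                not_triplet_class
#> 8          OTHERS FALSE                not_triplet_class
```

The curated triplet is the kept T2W/DWI/ADC: the coronal T2W distractor and
the synthetic b1400 DWI are excluded, and the b1000 acquisition wins the
DWI slot. The outer macro F1 of 1.0 reflects the clean synthetic
vocabulary — fixtures are separable by construction (out-of-sample
prediction on a fresh seed lands near but not at 100 %; in the run above,
one "ep2d diff adc" series was misread as T2W). On real multi-centre data
the interesting quantity is the *drop* under leave-one-centre-out
validation:

```r
shifted <- inject_centre_shift(spec, "centre_02", 1)   # out-of-distribution centre
res <- logocv(generate_dataset(shifted), backend = "engineered",
              grid = default_grid(n_iterations = 5), seed = 7)
res$macro_delta      # centre_02 clearly below the pooled-CV baseline
```

A command-line interface wrapping the same functions is installed at
`inst/cli/mrseries` (`simulate`, `extract`, `train`, `predict`, `curate`,
`evaluate`, `logocv`, `learning-curve`); every run writes a manifest with
the seed and options next to its output.

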