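# shared helpers: small fixture specs and a fast search grid for tests

`%||%` <- function(a, b) if (is.null(a)) b else a

quick_grid <- function(n_iterations = 2L) {
  hyper_grid(max_depth = c(4L, 6L), learning_rate = 0.3,
             nrounds = c(40L, 100L), n_iterations = n_iterations)
}

small_spec <- function(n_studies = 30, k = 3, seed = 101, ...) {
  synthetic_study_spec(n_studies, centres = default_centres(k), seed = seed, ...)
}

# spec rich in curation distractors: sagittal/coronal and thick-axial T2W,
# eADC next to plain ADC, synthetic DWI among multiple b-values
distractor_spec <- function(n_studies, seed) {
  # slice spacing is always present here so every exclusion rule sees its tag
  centres <- lapply(1:3, function(i)
    centre_profile(sprintf("centre_%02d", i),
                   missingness = c(SAR = 0.25, PercentPhaseFieldOfView = 0.2,
                                   ScanOptions = 0.3)))
  synthetic_study_spec(
    n_studies, centres = centres,
    label_mix = c(T2W = 3, DWI = 3, ADC = 2, DCE = 1, OTHERS = 1),
    seed = seed, p_extra_adc_eadc = 1, p_sdwi = 1, p_thick_t2w = 0.5)
}

truth_of <- function(records, what) {
  if (what == "label") vapply(records, function(r) r$truth$label, character(1))
  else lapply(records, function(r) r$truth[[what]])
}

# oracle predictions: feed the generator's hidden labels to the curation stage
oracle_predictions <- function(records) {
  data.frame(series_uid = vapply(records, `[[`, character(1), "series_uid"),
             predicted_label = vapply(records, function(r) r$truth$label, character(1)),
             stringsAsFactors = FALSE)
}

split_by_study <- function(records) {
  split(records, vapply(records, `[[`, character(1), "study_uid"))
}
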