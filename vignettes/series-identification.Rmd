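---
title: "Metadata-based series-type identification and curation for prostate mpMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metadata-based series-type identification and curation for prostate mpMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical machine-learning models for prostate cancer are trained on
multiparametric MRI (mpMRI) triplets — an axial T2-weighted series (T2W), a
high b-value diffusion-weighted series (DWI) and an apparent diffusion
coefficient map (ADC). Hospital PACS exports do not label series this way:
a study arrives as a bag of DICOM series whose descriptions, protocols and
private tags vary wildly across centres, vendors and software versions.
`mrseries` classifies each series into one of five types — `T2W`, `DWI`,
`ADC`, `DCE` (dynamic contrast-enhanced) and `OTHERS` — using header
metadata only (no pixel decoding), and then applies five deterministic
curation rules to pick the ML-ready triplet from the predictions.

Working from metadata keeps the method cheap enough to run anywhere; the
trade-off, explored below, is that the text features it leans on are
centre-specific, so performance depends on having training data from the
centres one deploys to.

## Sanitisation and aggregation

Each configured DICOM field is reduced to one string per series:

1. date-like substrings matching `[0-9]+[/-:][0-9]+[/-:][0-9]+` are deleted
   (scanner consoles often stamp dates into series descriptions, which would
   otherwise become high-cardinality noise tokens);
2. missing values become the literal `"-"`;
3. the characters `| - ; , ( ) _ :` become spaces (vendor conventions
   disagree on delimiters; this normalises `t2_tse-tra` and `t2 tse tra` to
   the same tokens);
4. space runs are squeezed and trimmed.

Because a series has one file per slice, per-slice values are sanitised,
de-duplicated and joined with spaces in C-locale lexicographic order, so the
result is independent of file read order. The date rule is applied to every
text field, not only the series description: other fields essentially never
contain date-like content, and one rule applied uniformly is easier to
reason about than a per-field exception list. Sanitisation is idempotent,
which the test suite fuzzes on random strings.

One consequence of rule 3 is that minus signs are lost: orientation cosines
like `0\\1\\0\\0\\0\\-1` lose their sign in the sanitised table. The
classifier never needed the sign, but the plane-detection heuristic does, so
extraction additionally carries raw (unsanitised) values for the
geometry-relevant fields (`raw.*` columns in the metadata table).

## Feature representations

Two representations feed two gradient-boosted backends:

* **engineered** — categorical fields are tokenised into word n-grams
  (sizes 1–5 over space-split words; the sanitisation protocol makes word
  tokens well defined) kept when their document frequency over series is at
  least `min_df = 0.01`; cells carry occurrence counts. Numeric-string
  fields (values parsing entirely as space-separated numbers, e.g. an
  echo-time set `"90 92"`) are summarised by five statistics: string length
  in characters, and the sum, mean, minimum and maximum of the parsed
  numbers.
* **native-categorical** — categorical fields are passed to the learner as
  raw factor levels with no explicit tokenisation; category handling happens
  inside the gradient-boosting library. Numeric-string fields are summarised
  as above.

Vocabularies are per-field (the token `2` means different things in a
b-value list and a description), built on training data only; unseen tokens
at prediction time are ignored so the design matrix never grows. Counts
(rather than tf-idf or binary indicators) are the simplest representation
consistent with occurrence-based tokenisation; trees are insensitive to
monotone rescalings, so little rides on this choice.

Four feature-set variants mirror common ablations: `all`, `no_sd` (without
series description), `no_fov_sar` (without percent-phase field of view and
specific absorption rate — fields that encode centre identity more than
sequence identity), and `no_sd_fov_sar`.

## Training and validation

Both backends train a five-class gradient-boosted classifier with 5-fold
nested stratified cross-validation: the inner loop draws random
hyperparameter candidates (uniformly with replacement from a configurable
grid; 50 draws by default) and scores each by stratified CV macro F1 on the
outer-training split only; ties prefer fewer trees, then shallower trees.
The outer loop provides the unbiased performance estimate, and the final
model is refit on all data with the best candidate. Macro (unweighted) F1
is the headline metric; weighted F1 is also reported.

Two further analyses probe generalisation:

* **Leave-one-centre-out CV** (`logocv()`): each fold holds out one centre
  entirely, with the hyperparameter search re-run inside each fold so the
  held-out centre never influences selection. Per-class F1 deltas against
  pooled stratified 5-fold CV on the same records quantify how much of the
  performance is centre-specific.
* **Learning curves** (`learning_curve()`): stratified subsets at fractions
  1, 2, 5, 10, 25, 50, 70 and 100 % of the training data, all scored on one
  fixed held-out test set.

### Saturation detection

Whether a learning curve has saturated is decided in two steps on the
macro-F1-versus-log-fraction curve (log scale because the fraction grid is
geometric): first, a two-piece continuous linear fit with the breakpoint
profiled over the interior grid points is compared with a single line by an
F-test with two extra parameters at α = 0.05 — a significant improvement
means the rate of improvement changed, and the best breakpoint is reported.
Second, the post-breakpoint slope is t-tested against zero; the curve is
declared stationary when that slope is not significantly different from 0.
If no rate change is detected the same t-test is applied to the single
fitted slope. Degenerate inputs are resolved before any test: an exactly
flat curve is stationary; an exactly linear curve has no breakpoint and is
stationary only if its slope is numerically zero. On the 8-point default
grid with additive noise of sd 0.01 the detector recovers planted
breakpoints within one grid step in well over 90 % of simulations (the
acceptance script recomputes this rate).

## Curation heuristics

Five deterministic rules refine predictions into the ML-ready triplet:

1. **Axial T2W**: the slice normal is the cross product of the row and
   column direction cosines (`ImageOrientationPatient`); the index of its
   largest absolute component (0, 1, 2) maps to sagittal, coronal, axial.
   A 2×3 cosine pair has no literal "z column", so the cross-product normal
   is used; it reproduces the 0/1/2 mapping exactly for canonical
   orientations and behaves sensibly under in-plane rotation. Exact 45°
   obliques are broken towards axial, with a warning.
2. **T2W slice spacing** must be strictly below 4.0 mm (prostate T2W is
   acquired at roughly 3 mm). Missing spacing keeps the series (fail-open):
   the rule is an exclusion filter, and silently dropping a valid T2W is
   worse than a false keep.
3. **Exponential ADC** is excluded when `ImageType` contains `EADC` as a
   whole token (whole-token matching avoids hits inside unrelated words).
4. **Synthetic DWI** is excluded when the lower-cased description contains
   the substring `synthetic`.
5. **Highest b-value DWI** is kept among the remainder, reading the
   standard tag (0018,9087) first and falling back to the GE (0043,1039)
   or Siemens (0019,100c) private tags by manufacturer; GE values at or
   above 1e9 carry a documented 1e9 offset which is subtracted (the
   at-or-above form, rather than strictly-above, keeps b = 0 well defined;
   the offset handling can be disabled). Missing b-values rank lowest;
   remaining ties go to the highest series number.

Residual multiplicity (two compliant axial T2W, say) resolves to the
highest series number — later acquisitions are typically repeats that
superseded earlier ones — and is flagged in the decision log.

## The synthetic fixture generator

No patient data ships with the package; every test runs on synthetic
studies. A `synthetic_study_spec()` fixes the number of studies, the centre
profiles, an exact per-study series mix and a seed; generation is a pure
function of (spec, seed), including the bytes of the DICOM files it can
write. The defaults emulate a typical mpMRI exam — two T2W (one axial, one
sagittal/coronal or thick-slice distractor), two DWI b-values, one ADC, one
DCE, two accessory series — with realistic acquisition parameter ranges per
type, vendor-specific b-value tag dialects (GE private tag with 1e9 offset,
Siemens private tag, standard tag otherwise), optional exponential-ADC and
synthetic-DWI variants, per-field missingness, and dates embedded in a
fraction of descriptions to exercise the date rule. Orientation cosines are
canonical planes under an in-plane rotation, so triplets stay unit-norm and
the slice normal stays exact.

Centres share one description template bank by default, i.e. they are
identically distributed; heterogeneity is introduced explicitly with
`inject_centre_shift()`, which deterministically replaces a chosen fraction
of one centre's vocabulary tokens with tokens no other centre uses and
raises the missingness of the informative acquisition tags proportionally.
At strength 1 this produces the out-of-distribution centre whose
leave-one-centre-out score drops well below the pooled-CV score, while
identically distributed centres show per-class F1 deltas near zero — the
qualitative signature that motivates collecting centre-specific training
data.

What the generator does *not* emulate: real vocabulary drift within a
centre over time, protocol changes, mislabelled ground truth, or any pixel
content. Synthetic descriptions are cleanly separable by construction, so a
perfect nested-CV score on fixtures demonstrates that the pipeline is
correct, not that real-world F1 will be perfect; the published experience
with this family of methods on real multi-centre data is high but not
perfect performance, with the LOGOCV drop being the robust phenomenon.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale versions of each
analysis, chosen to exercise every code path at comfortable runtimes:
classifier recovery on 300 studies across 3 centres (~2,400 series) with a
reduced random search (2–3 candidates over depth {4,6}, learning rate
{0.1,0.3}, 40–100 trees); a balanced 300-study set with permuted labels as
the chance-level control (macro F1 ≈ 0.2 for five balanced classes);
leave-one-centre-out on 150 studies; curation on 500 distractor-rich
studies; and DICOM round trips on a handful of studies per vendor dialect.
The default grid (`default_grid()`: depth 4–10, learning rate 0.03–0.3,
100–600 trees, row/column subsampling, L2 regularisation, 50 draws) is the
recommended starting point at realistic data sizes.

Other fixed choices: class order is `T2W, DWI, ADC, DCE, OTHERS` everywhere
so confusion matrices are comparable across runs; per-class F1 is 0 when
precision and recall are both 0; all lexicographic orderings use C-locale
radix sorting for locale independence; and every stochastic step (fold
assignment, candidate draws, learner seeding, subset draws) derives from a
single user-supplied seed.

## Limitations

* The classifier treats `"-"` as just another missing value; a record with
  every field missing is still classified but flagged `low_confidence`.
* Strongly oblique acquisitions have no well-defined plane; the argmax
  convention assigns the nearest canonical plane and warns on exact ties.
* The "number of characters" summary statistic reads string length
  literally (including spaces); counting parsed values instead would also
  be defensible, and the statistic is cheap to change if a downstream model
  prefers it.
* The minimum document frequency is interpreted per series (each token must
  appear in ≥ 1 % of series), not per file.
* The DICOM codec reads and writes explicit-VR little-endian Part 10 files
  only — sufficient for the fixture generator and typical exports, but not
  a general-purpose DICOM implementation.
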