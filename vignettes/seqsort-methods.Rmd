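---
title: "Methods: rule-based virtual labels and blank-series recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based virtual labels and blank-series recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsort)
```

# The model

`seqsort` classifies brain-MRI series into eight pulse-sequence families
(T1, T2, FLAIR, Diffusion, MRA, suscgre, Scout, Perfusion) without human
labels. Its supervisory signal is the DICOM header itself: vendors encode
the sequence family in `SeriesDescription`/`ProtocolName` free text often
enough that a keyword table can label most of an archive. Those rule
labels ("virtual labels") then supervise a random forest over acquisition
parameters, and the forest fills in the series the rules could not label
("blanks").

The central assumption is that text and physics are redundant descriptions
of the same acquisition: a series whose header says `t2_tirm_tra_dark-fluid`
also has the long TR and 2200–2800 ms inversion time of a FLAIR. Where the
text is absent or uninformative, the physics remains, which is exactly why
the blank series — unusable for training by construction — are a
legitimate held-out test set and the deployment target at once.

## The rule-based labeler

Matching runs on normalized text (lower-cased; space, underscore, hyphen,
slash, and dot unified to single spaces) and is substring-based, because
vendor strings concatenate tokens (`ep2d_diff`). Two guards limit false
hits:

* **Exclusions.** Tokens used across sequence families are never decision
  keywords; the shipped table excludes `mip`, since maximum-intensity
  projections occur in MRA and susceptibility series alike.
* **Token-only keywords.** Short collision-prone keywords (`loc`, `dw`,
  `cow`) match only as whole delimiter-bounded tokens — `velocity` must
  not trigger `loc`.

The search is two-step: `SeriesDescription` first; `ProtocolName` only if
the description is missing, empty, or keyword-free. Multi-keyword hits are
resolved by ordered precedence rules (a rule applies when its label
pattern is a subset of the candidate set): T1+FLAIR is T1, T2+FLAIR is
FLAIR, T1+MRA is MRA (contrast-enhanced MRA texts carry "t1"),
suscgre+MRA is suscgre, and T2+suscgre is suscgre (a "t2\*" text also
contains the bare "t2"). An unresolved conflict yields BLANK with a
warning rather than a guess: a blank is recoverable by the classifier, a
wrong virtual label silently corrupts training.

The complete table is a reconstruction from common stroke-protocol naming,
not a transcription of any site's list, and is meant to be edited: the
rule-file format is plain text (`save_ruleset()` / `load_ruleset()`, exact
round trip), and `"Others"`-mapping keywords can be added even though the
default table maps nothing to Others (that class is a human judgement).

## Features

From each series the extractor takes a fixed attribute set — TR, TE, TI,
flip angle (deg), imaging frequency (MHz), phase-encoding steps, matrix
rows/columns, slice thickness (mm), the derived slice count, and the coded
attributes ScanningSequence, SequenceVariant, MRAcquisitionType,
ImageType, ScanOptions, BodyPartExamined. Numeric features are min–max
normalized to the training range (a "common scale" that preserves relative
differences; forests are scale-robust, so this choice is about
reproducibility, not accuracy), with three deliberate conventions:

* degenerate range (max = min) maps to 0;
* inference values outside the training range clip to \[-0.5, 1.5\], so an
  outlier cannot dominate a split threshold learned elsewhere;
* missing numerics become the sentinel −1 **plus** a 0/1 indicator column.
  The sentinel sits outside the clip range, and the indicator keeps
  missingness informative rather than imputed away — InversionTime being
  absent is evidence against FLAIR, not noise.

Coded attributes are one-hot encoded against vocabularies fitted on
training data; unseen tokens at inference map to all zeros. The two text
attributes are **excluded** from the feature set by design, so the
classifier cannot trivially re-learn the keyword table; the no-leakage
property is asserted by a test on the schema's column order.

## Training and model selection

The classifier is a random forest (`ranger`, single-threaded, seeded) with
every hyperparameter at its library default except the number of trees,
the parameter that matters for overfitting. Tree counts are evaluated over
a grid spanning 1–1000 — by default
\{1, 5, 10, 25, 50, 100, 200, 400, 700, 1000\}, with a `full_sweep` flag
for the exhaustive 1..1000 sweep, which changes the answer only in run
time — by stratified 5-fold cross-validated accuracy. Stratification is a
deliberate choice over plain random folds: Scout and Perfusion are rare
(2% and 0.3% of a hospital-style mix) and unstratified folds can starve
them. Ties select the smaller forest. BLANK labels are rejected as
training input, and Others rows are dropped before fitting.

Retraining for an appended archive concatenates all datasets' non-blank,
non-Others rows, refits the feature schema on the combined rows (bounds
and vocabularies should reflect all vendors now present; reusing the old
schema would clip the new site's ranges), and trains as usual, with all
dataset identifiers recorded in provenance. Labels come from rule
decisions only — appending an archive requires no human input.

# The synthetic-data generator

Real hospital/trial archives cannot ship with a package, so the generator
is first-class, tested code that emulates the properties the method
actually consumes:

* **Class mix.** Default per-class proportions follow a large
  hospital-style stroke archive (T1 25%, MRA 23%, Diffusion 20%, suscgre
  11%, T2 9%, FLAIR 9%, Scout 2%, Perfusion 0.3%); a `trial` preset
  shifts weight toward MRA/Diffusion and smaller totals. Counts are
  allocated by largest remainder, so empirical frequencies match the mix
  to within one series.
* **Vendor text styles.** Philips/Siemens/GE-flavoured description
  templates (mixed 62/34/4% by default, 22/43/35% in the trial preset),
  including compound texts (`T1 FLAIR AX`, `ce_mra_t1_fl3d`, `t2_gre_tra`)
  that exercise every precedence rule, and a 10% chance that the keyword
  lives only in `ProtocolName`, exercising the fallback search.
* **Acquisition parameters.** Uniform class-conditional ranges at
  realistic 1.5T/3T values (e.g. FLAIR TR 8–11 s with TI 2.2–2.8 s; TOF-MRA
  TR 20–35 ms at flip 18–25°; scouts with 6–10 mm slices and small
  matrices). The classes are separable by design — the generator validates
  the pipeline's mechanics, not clinical difficulty.
* **Missingness.** Per-attribute tag-absence probabilities (e.g.
  ScanOptions 25%, BodyPartExamined 15%), plus structural absence of TI
  outside FLAIR.
* **Blanks.** Exactly `round(blank_fraction * n_series)` trainable-class
  series receive keyword-free text (default fraction 0.129, trial preset
  0.11). Blankness is defined operationally against the shipped default
  rule set, not against an abstract emptiness. `Others` series always get
  keyword-free text (the rule table has no Others keywords by design), so
  a nonzero Others share adds blanks beyond the quota; the default mix
  sets Others to zero.
* **Files.** One DICOM Part-10 file per slice (2–12 slices per series,
  about one in seven series implicit-VR to exercise both parsers), written
  by the package's own codec and cross-checked against pydicom in a test.
  Pixel data is a fixed 4×4 placeholder raster: the method never reads
  pixels, and Rows/Columns header values are acquisition-matrix features,
  not raster dimensions. `write_files = FALSE` skips file writing and
  yields the identical manifest draw for classifier-scale experiments.

What the generator does **not** emulate — and what passing tests therefore
do not show — includes: genuinely ambiguous or misleading header text
(available only as an opt-in `ambiguity_rate` of `MIP`-style texts),
inter-class parameter overlap at clinical severity, enhanced multi-frame
DICOM, site-specific vocabulary drift, and longitudinal patient structure.
Perfect rule fidelity on synthetic non-blanks is a property of the
templates matching the table; on real data the rule system, not the
mechanics, is the accuracy bottleneck.

# Numerical and interface choices

* **Determinism.** Every stochastic step (generator draw, fold
  assignment, each forest fit) is seeded; the generator restores the
  caller's RNG state. Replaying a seeded pipeline reproduces decisions,
  predictions, and reports byte for byte, which is tested.
* **First-file convention.** Series attributes are read from the first
  file (sorted by InstanceNumber, ties by filename); within-series header
  disagreement is flagged in a message and the first file wins. Headers in
  the extraction set are constant within a series in practice.
* **Plane descriptor.** The acquisition plane comes from the slice normal
  (cross product of the six direction cosines); the dominant |component|
  must reach 0.8, else the plane is reported oblique. The threshold is a
  package choice; 0.8 corresponds to ≈37° of tilt.
* **Undefined metrics.** Precision/recall/F1 with empty denominators are
  `NA`, excluded from macro averages with an explicit count — never
  silently zero. Both macro (headline) and micro averages are reported;
  for single-label multi-class data micro-precision = micro-recall =
  overall accuracy, which the tests assert on random matrices.
* **Evaluation conventions.** The rule system is scored on its non-blank
  subset with the blank count reported separately; classifiers are scored
  on the blank set.
* **Sorting is non-destructive.** The `sort` mode copies series files
  into per-label directories by default; `--move` is explicit.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every class including the rare ones: 1000-series archives for
rule fidelity, a 2000-series archive (blank fraction 0.15) for blank-set
recovery and the virtual-vs-human label comparison, and 300 + 1700 series
for the retraining experiment. On synthetic data with the default grid
these complete in well under a minute each on one core.

# Known limitations

* The default rule table is a best-effort reconstruction; real archives
  will need site keywords added (the rule file is designed for this).
* On fully separable synthetic data the virtual labels equal ground truth
  on non-blank series, so the virtual- and human-label models coincide;
  their agreement statistic becomes informative only under injected
  ambiguity or real data.
* The DICOM codec reads explicit/implicit VR little endian Part-10 files
  and skips what it does not understand; big-endian, deflated, and
  undefined-length (sequence-heavy) files are skipped with a warning, not
  parsed.
* Probability calibration, alternative classifiers, and statistical
  comparison of systems (bootstrap CIs) are out of scope.
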