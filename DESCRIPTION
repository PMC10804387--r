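Package: seqsort
Title: Self-Supervised Sequence-Type Classification of Brain MRI from
    DICOM Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sorts brain MRI series into pulse-sequence types (T1, T2,
    FLAIR, diffusion, MR angiography, susceptibility/gradient echo,
    perfusion, scout) without human labeling.  A rule-based labeler over
    DICOM header text (SeriesDescription, ProtocolName) produces virtual
    labels; a random-forest classifier trained on those labels and on
    acquisition-parameter features fills in the series the rules cannot
    label, and the system retrains as new archives are appended.  Includes
    a minimal DICOM Part-10 header reader/writer, a synthetic multi-vendor
    archive generator for testing, evaluation reports, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
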