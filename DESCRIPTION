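Package: prrtdose
Title: Planar-Image Dosimetry and Dose-Response Analysis for Lu-177 Peptide
    Receptor Radionuclide Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end internal-dosimetry pipeline for Lu-177 DOTATATE
    therapy based on conjugate-view planar scintigraphy. Quantifies organ and
    lesion activity from anterior/posterior count images, fits
    sum-of-exponentials time-activity models and computes time-integrated
    activity coefficients, converts them to absorbed doses with MIRD-schema
    S-values (including a mass-weighted remainder-of-body correction and a
    blood-based red-marrow model), derives tumor doses with the unit-density
    sphere model interpolated by lesion mass, projects full-course doses,
    and reports tumor size-change statistics, dose-response association and
    toxicity-threshold flags. A synthetic phantom cohort generator with
    known ground-truth kinetics makes every stage testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
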