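Package: mwdhseg
Title: Seeded Wavelet-Domain Segmentation of Pelvic CBCT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automatic segmentation of soft-tissue structures
    (bladder, prostate, rectum) in cone-beam CT slices using an
    undecimated three-channel double-Haar filter bank. A user-supplied
    seed point drives adaptive thresholding: an iterative two-class
    clustering threshold on the low-frequency sub-band and a Lee-filter
    based hard threshold on the high-frequency sub-bands; wavelet
    reconstruction of the thresholded coefficients yields a binary mask.
    Includes overlap evaluation metrics (Dice, sensitivity,
    inclusiveness, signed volume difference), a synthetic pelvic phantom
    generator with implanted-transponder streak artifacts for validation,
    image input/output (PNG, NIfTI, DICOM series), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
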