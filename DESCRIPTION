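Package: flairtex
Title: Texture Analysis of Pre- and Post-Contrast FLAIR MRI in Small Vessel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Masked-region gray-level co-occurrence matrix (GLCM) texture
    analysis of paired pre- and post-contrast FLAIR brain MRI volumes, aimed
    at studying cerebral small vessel disease and blood-brain barrier leakage.
    Provides uniform intensity quantization, per-slice GLCM construction with
    orientation averaging, six Haralick texture descriptors (contrast, GLCM
    variance, entropy, correlation, homogeneity, energy), first-order region
    intensity statistics including the pre/post difference in the
    variance-to-mean ratio (DVMR), cohort-level statistical comparisons
    (Kruskal-Wallis, Mood's median test, ANCOVA of post- on pre-contrast
    texture, and a random-intercept linear mixed model with a
    pre/post-by-Fazekas interaction), and a synthetic phantom cohort generator
    with injected, recoverable effects for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    lme4,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
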