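Package: fusact
Title: Functional Ultrasound Power Doppler and Activation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Analysis pipeline for functional ultrasound (fUS) neuroimaging:
    coherent compounding and temporal averaging of per-angle beamformed
    complex frames, SVD clutter filtering of Casorati matrix blocks into
    ultrafast power Doppler image series, motion correction and voxel
    normalization, general linear model activation mapping against a gamma
    hemodynamic response function with Benjamini-Hochberg FDR control,
    region-of-interest stimulus-response statistics, and contrast-to-noise /
    resolution quality metrics. Includes a seeded synthetic ultrafast-Doppler
    phantom generator emulating an auditory block-design experiment (low-rank
    tissue clutter, vessels with slow-time Doppler phase progression,
    stimulus-locked cerebral blood volume increases, nonrigid motion) so the
    whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
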