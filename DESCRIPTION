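Package: imptrobust
Title: Worst-Case Robustness Evaluation for Intensity-Modulated Proton Therapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating the robustness of intensity-modulated proton
    therapy (IMPT) dose distributions against setup and range uncertainties
    using the worst-case approach. Computes per-voxel robustness maps (the
    error-bar dose distribution, the root-mean-square error dose, and the
    voxel-wise minimum/maximum dose) from a nominal dose plus twelve
    uncertainty-scenario doses, cumulative dose-volume histograms and their
    scenario band, DVH-point metrics (D95%, D0.01cc, Dmean, Vx%) with
    physical-scenario and voxel-wise worst-case values, error-bar and RMSED
    volume histograms with their area under the curve, and cross-method
    Pearson correlation and conservativeness summaries over a plan cohort.
    Includes a synthetic phantom-cohort generator that emulates robustly
    optimized plans and their scenario recalculations, plus readers/writers
    for NRRD and NIfTI volumes and a DICOM RT Dose importer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
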