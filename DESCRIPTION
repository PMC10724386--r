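Package: hvmudi
Title: High-Spatiotemporal-Resolution Vector Micro-Doppler Imaging of
    Microvascular Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Contrast-free processing of ultrafast plane-wave ultrasound
    ensembles into enhanced microvascular images, per-voxel vector velocity
    fields, and hemodynamic statistics. Implements block-wise singular value
    decomposition clutter filtering with adaptive singular-value thresholds
    and an adaptive high-pass cutoff frequency, morphological bowler-hat and
    Hessian vesselness enhancement with mask and centerline extraction,
    multibeam (multi-angle) vector Doppler velocity estimation by least
    squares, and quantification of vascular density, vessel diameter
    (full width at half maximum), tortuosity (sum of angles metric),
    pulsatility index, flow-reversal ratio and arteriole/venule
    classification. Includes a flow-phantom simulator that generates
    per-angle in-phase/quadrature ensembles for straight-microtube scenes
    with tissue clutter and electronic noise, plus synthetic mask/vector
    field scenarios with analytically known metric values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    signal,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
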