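Package: castseg
Title: Local-Threshold Segmentation and Wall Shear Stress Analysis of
    Cast-Constricted Murine Carotid Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for reconstructing the lumen geometry of a murine
    common carotid artery constricted by a tapering shear-modifying cast
    from contrast-enhanced micro-CT, and for estimating wall shear stress
    along the reconstructed vessel. Implements per-contour local midway
    thresholding (lumen/background region statistics, midway local
    thresholds, a global-threshold comparator, binarization and subvoxel
    ray-cast contour refinement), centerline fitting with
    rotation-minimizing frames and cross-section extraction, diameter and
    wall-thickness profiling against the known cast taper, lofted
    watertight lumen surfaces with volume-preserving smoothing and flow
    extensions, Doppler waveform cycle averaging and Fourier low-pass
    filtering, and a quasi-1D Poiseuille wall-shear-stress surrogate with
    TAWSS and OSI summaries. A synthetic micro-CT phantom generator with
    known ground truth, calibrated to published Hounsfield-unit regimes,
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
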