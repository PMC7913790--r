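Package: iffmap
Title: Interstitial Fluid Flow Mapping from Dynamic Contrast-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates interstitial fluid flow velocity fields and isotropic
    diffusion coefficient maps from dynamic contrast-enhanced MRI time series
    by inverting the diffusion-advection equation pixel-wise with a
    noise-corrected least-squares solver. Includes a forward finite-difference
    simulator and phantom generators for validation by parameter recovery,
    region-of-interest tools (polygon rasterization, parenchymal rings),
    slice/patient/cohort flow summaries with the accompanying statistics, and
    flow-pattern visualizations (velocity heat maps, quiver and streamline
    overlays, direction-magnitude rose histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    RNifti,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
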