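Package: csaaa
Title: Compressed-Sensing Black-Blood MRI Simulation and Aneurysm Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates accelerated three-dimensional black-blood magnetic
    resonance imaging of abdominal aortic aneurysms on seeded digital
    phantoms and quantifies what an accelerated protocol preserves.
    Provides variable-density Poisson-disc k-space undersampling with an
    elliptical footprint and a fully sampled calibration centre,
    a combined compressed-sensing and parallel-imaging reconstruction
    (wavelet l1 regularisation minimised by an accelerated proximal-gradient
    method with coil sensitivities estimated from the calibration region),
    vessel-wall morphometry (maximal aneurysm diameter, lumen and
    intraluminal-thrombus areas, thrombus signal ratios and typing, boundary
    sharpness), and the method-agreement statistics used for surveillance
    studies (Bland-Altman bias and limits of agreement, intraclass
    correlation, coefficient of variation, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
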