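Package: dkialps
Title: Glymphatic ALPS Indices from Diffusion and Kurtosis Tensor MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Computes the DTI-ALPS and DKI-ALPS indices of glymphatic
    (perivascular) water transport from multi-shell diffusion MRI. Fits the
    diffusion tensor and the fourth-order kurtosis tensor per voxel by
    log-linear ordinary or weighted least squares, extracts axis-aligned
    diffusivity and kurtosis maps, places spherical regions of interest in
    projection- and association-fibre white matter, and forms the ALPS
    ratios for the left, right and whole brain. Includes a synthetic
    multi-shell phantom with known ground truth (explicit tensors and
    crossing-fibre Gaussian mixtures), a cohort simulator, and the group
    statistics used in ALPS studies (Lilliefors normality test with
    Monte-Carlo p-values, two-sample t-tests from raw data or printed
    summaries, exact and normal-approximation Mann-Whitney U, 2x2
    chi-square, correlations, and a two-group report).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse,
    yaml
Config/testthat/edition: 3
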