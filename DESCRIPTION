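Package: relaxometry
Title: Vendor-Independent T1 and T2 Relaxation Mapping for Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs pixelwise and ROI-mean T1 and T2 relaxation maps from
    multi-timepoint magnitude or phase-sensitive (PSIR) image series. Supports
    inversion-recovery, saturation-recovery, MOLLI (with Look-Locker correction),
    and multi-echo / T2-prepared sequences with 2- and 3-parameter signal models;
    two-pass lookup-table T1 initialization; weighted log-linear T2 initialization
    with echo truncation; Nelder-Mead simplex refinement with a relaxation-time
    convergence criterion; exclusion rules; normalized residual maps; a synthetic
    multi-vial gel phantom simulator with Rician noise; and modified Bland-Altman
    agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    rlang,
    ggplot2,
    generics,
    png,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
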