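Package: nucorg3d
Title: Quantitative 3D-FISH Analysis of Nuclear Organization in Early Embryo Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segmentation and quantification pipeline for multichannel 3D
    confocal stacks of preimplantation-embryo nuclei labelled by DNA
    counterstain and centromeric/pericentromeric FISH probes. Extracts
    nuclei by background-statistics thresholding, detects FISH signals with
    multiscale top-hat filtering, segments nucleolar precursor bodies (NPBs)
    and nucleoli as dark round regions, computes label-object morphometry
    (volume, surface, sphericity, flatness, elongation), scores
    signal-to-NPB interactions, and tests nuclear polarity of centromere
    distributions against a uniform-placement null. A ground-truthed
    synthetic phantom generator emulating embryo nuclei (ellipsoidal
    nucleus, dark NPBs, heterochromatin motifs, punctate centromeres and
    telomeres, optional Rabl-like polarity, PSF blur and Poisson-Gaussian
    noise) makes every stage testable without real data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
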