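Package: dcadmd
Title: Deformable Margin Delineation for Dynamic Conformal Arc Lung SBRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated deformable margin delineation (DMD) for dynamic
    conformal arc (DCA) stereotactic body radiotherapy of lung tumors.
    Generates synthetic thoracic phantoms, plans conventional conformal
    arcs by fitting multileaf-collimator apertures to the target's
    beam's-eye-view silhouette, computes dose with a simplified arc dose
    engine, locates hot and cold dose regions around the planning target
    volume, deforms the aperture-fitting target accordingly, re-plans and
    renormalizes to 95% coverage of the original target, and quantifies
    plan quality with the RTOG 0915 / Paddick / ICRU index suite
    (conformity index, Paddick conformity number, R50% gradient, D2cm,
    homogeneity index, external index, lung V20/V2.5/mean lung dose),
    plus cohort-level Wilcoxon and Spearman statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
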