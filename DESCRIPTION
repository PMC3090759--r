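Package: mthvr
Title: Ancestry Classification from Mitochondrial Hypervariable-Region Profiles
Version: 0.1.0
Authors@R: person("mthvr", "maintainers", email = "mthvr@example.org", role = c("aut", "cre"))
Description: Tools for inferring coarse population ancestry from mitochondrial
    DNA control-region (HVR1/HVR2) haplotype profiles reported as
    rCRS-relative polymorphism lists. Provides parsing and validation of
    profile tables, binary feature encoding with three missing-data
    strategies (reference imputation, per-position polymorphism rates, and
    common-region restriction), principal component analysis with
    cross-validated dimension selection, four classifiers (soft-margin
    RBF-kernel support vector machines with one-against-one multiclass
    voting, linear and quadratic Gaussian discriminant analysis, and
    Hamming-distance 1-nearest-neighbour), stratified cross-validation with
    micro/macro accuracy statistics, region-informativeness scans, and a
    synthetic profile generator emulating forensic mtDNA population
    databases with haplogroup-conditional motifs and laboratory-dependent
    coverage dropout.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
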