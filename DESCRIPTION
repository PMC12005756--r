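Package: iggfc
Title: Intact IgG Fc/2 Subunit Proteoform Profiling from LC-MS Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling IgG Fc/2 subunit proteoforms released by IdeS
    proteolysis and measured by LC-MS at the intact-subunit level. The package
    models allotype backbones, N-glycan compositions and common Fc
    post-translational modifications; simulates complete MS1 runs with charge
    envelopes, chromatographic peaks and noise; provides a preprocessing
    chain of spectrum smoothing, Tophat baseline subtraction, retention-time
    alignment and zero-charge deconvolution; identifies allotypes by intact
    mass matching; quantifies glycoforms, allotype ratios, CH3-domain site
    occupancy and PTM levels from three-charge-state extracted ion
    chromatograms; and derives glycosylation traits with principal component
    analysis, paired tests, Sidak-adjusted comparisons and Spearman
    correlations for comparing total and antigen-specific IgG fractions from
    plasma and synovial fluid.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mzR,
    yaml,
    cluster,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
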