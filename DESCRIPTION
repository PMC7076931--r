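Package: sadmine
Title: Species Abundance Distribution Model Selection and Co-Occurrence
    Networks for Soil Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether microbial communities are structured by
    niche or neutral processes. Fits zero-truncated Poisson-lognormal and
    negative-binomial species abundance distributions to pooled OTU counts by
    maximum likelihood and compares them with Akaike weights; builds
    co-occurrence networks from maximal-information-coefficient (MIC)
    associations with permutation significance; estimates Chao1 richness and
    individual-based rarefaction curves; explains richness from environmental
    covariates by stepwise-AIC model selection over Gaussian and
    negative-binomial families with optional spline terms. Includes a
    synthetic-data generator with known ground truth (SAD family per group,
    planted co-occurring OTU pairs, true richness drivers) so the whole
    pipeline is testable without sequencing data, plus a single-config
    end-to-end pipeline and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    igraph,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
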