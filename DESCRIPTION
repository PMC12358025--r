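Package: melondiv
Title: Marker-Based Genetic Diversity Analysis for Mixed Dominant and
    Codominant Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing crop germplasm diversity from small mixed
    marker panels that combine dominant presence/absence markers (RAPD) with
    codominant multi-allelic markers (SSR). Implements band-sharing genetic
    similarity and distance with fractional heterozygote sharing, polymorphic
    information content, gene diversity and Nei's standard genetic distance,
    UPGMA clustering with Newick export, principal coordinate analysis, a
    Bayesian admixture-model Gibbs sampler with correlated allele frequencies,
    Evanno delta-K model selection and run alignment, chloroplast (CAPS)
    cytoplasm typing, seed-size classification, morphological trait
    clustering, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
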