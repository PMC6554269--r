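Package: beevision
Title: Randomly Wired Colour-Coding Neurons in the Bee Optic Lobe
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models colour processing in the bee medulla as a three-layer
    circuit: nonlinear photoreceptor transduction (E = P/(P+1)), inhibitory
    one-to-one transmedullary relays, and third-order neurons that sum
    randomly weighted inputs through a thresholded (sigmoidal or piecewise
    linear) activation. Provides a weighted least-squares gradient-descent
    fitter that recovers synaptic weights and activation steepness from
    measured spectral tuning curves, a generator for large libraries of
    randomly wired model neurons, clustering analyses (PCA, truncated
    Dirichlet-process Gaussian mixtures, k-means with silhouettes) of fitted
    weights and simulated tuning curves, and ensemble perceptual-distance
    analyses comparing random and regular opponent wiring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    cluster
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
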