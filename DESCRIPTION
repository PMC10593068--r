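Package: triadic
Title: Ordinal Characterization of Triadic Similarity Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian likelihood-ratio indices that quantify how compatible a
    set of triadic ("which of x, y is more similar to r?") forced-choice
    judgments is with symmetric, ultrametric, and additive-tree distance
    structures on the underlying perceptual space. Choice probabilities are
    given a symmetric beta prior, optionally mixed with a point mass at 1/2;
    compatibility is decided purely from the rank order of dis-similarities
    via indicator tables over sign configurations, so no metrical assumptions
    about the judgment process are required. Includes maximum-likelihood
    fitting of the prior, exact sign-flip surrogate null distributions,
    jackknife standard errors, converters for ranking and odd-one-out
    paradigms, and a simulator of triadic experiments over tree, line,
    circle, and two-ray stimulus geometries with Gaussian decision noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
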