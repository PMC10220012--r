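Package: limnoflux
Title: Lake-Sediment Carbon and Lithogenic Flux Reconstruction Under
    Age-Model Uncertainty
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@limnoflux.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing total organic carbon (TOC) and
    lithogenic mass accumulation fluxes from dated lake-sediment cores
    while propagating chronological uncertainty. Includes a Bacon-style
    Bayesian age-depth model (gamma autoregressive accumulation prior,
    Student-t dating likelihood, Metropolis-within-Gibbs sampling),
    compositional closure and flux computation per posterior ensemble
    member, regime-shift detection by cumulative-sum slope analysis and
    by simultaneous confidence intervals on the first derivative of a
    penalized-spline trend, compositional / Hellinger / age-uncertain
    probabilistic principal component analyses, diatom assemblage
    summaries, and a synthetic multi-lake core generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
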