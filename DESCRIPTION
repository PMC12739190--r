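Package: ddrsim
Title: Dental Diet Risk Score Modeling and In-Silico Dietary Simulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and evaluating the Dental Diet Risk Score
    (DDRS), a weighted composite of four oral-health-relevant dietary
    pathways: free-sugar exposure, acidic-beverage intake, protective-food
    intake, and overall diet quality. Provides a seed-reproducible Monte
    Carlo generator of synthetic dietary profiles with a latent
    diet-quality factor inducing realistic correlations with the
    Mediterranean Diet Adherence Screener (MEDAS), the Dietary
    Phytochemical Index (DPI), and the Healthy Eating Index (HEI);
    index normalization onto a common 0-100 scale; Pearson correlations
    with Fisher-z confidence intervals; covariance-based variance
    decomposition of the composite score; scenario analysis of healthy,
    unhealthy, and mixed dietary patterns; one-at-a-time weight
    perturbation (tornado) sensitivity analysis; and a reproducible
    end-to-end study pipeline with convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
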