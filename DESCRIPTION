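Package: codigest
Title: Taguchi Optimization and Neural Modeling of Anaerobic Co-Digestion
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing multiresponse batch anaerobic co-digestion
    experiments laid out on a Taguchi L9(3^4) orthogonal array. Implements
    larger-the-better signal-to-noise ratio analysis with factor-effect
    ranking and optimal-level selection, an additive main-effects response
    surrogate with Derringer-type desirability for multiresponse
    optimization, process-chemistry metrics (soluble-COD stabilization,
    free ammonia nitrogen equilibrium, ammonia/VFA inhibition diagnostics),
    a from-scratch Levenberg-Marquardt trained multilayer perceptron for
    predicting biogas yield and methane content from digester kinetics, and
    a seed-deterministic generator of synthetic nine-run triplicate
    digestion experiments with Gompertz biogas kinetics for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
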