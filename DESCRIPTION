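Package: ferronox
Title: Coupled Photoferrotrophy and Nitrate-Reducing Fe(II) Oxidation in Batch Reactors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the competition between an anoxygenic photoferrotroph
    and a nitrate-reducing Fe(II)-oxidizing culture in well-mixed anoxic batch
    reactors. The model couples Monod photoferrotrophic growth, a two-step
    dual-Monod denitrification chain with nitric oxide (NO) and nitrous oxide
    (N2O) intermediates, linear-driving-force gas-liquid mass transfer with
    Henry's law partitioning, continuous headspace-sampling dilution, and an
    NO-dependent toxicity term that drives decay of the phototroph. Includes
    bounded nonlinear least-squares calibration in log-parameter space, local
    sensitivity and Gauss-Newton uncertainty analysis, a synthetic incubation
    data generator with configurable measurement noise, and an end-to-end
    generate-fit-predict replication pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
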