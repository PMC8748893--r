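Package: mbode
Title: Mini-Batch Optimization for Calibration of ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates ordinary differential equation (ODE) models of cellular
    signalling against large collections of experimental conditions using
    mini-batch stochastic optimization. Provides per-condition decomposable
    negative log-likelihood objectives with forward-sensitivity gradients on a
    log10 parameter scale, four stochastic optimizers (SGD, SGD with momentum,
    RMSProp, and Adam in standard and balanced tunings) with learning-rate
    schedules, a rescue interceptor and mini-batch backtracking line-search for
    robustness against integration failures, multi-start orchestration with a
    quasi-Newton full-batch reference, benchmark ranking and convergence
    metrics, ROC-based responder classification, and history-based parameter
    ensembles for uncertainty analysis. Includes a generator for synthetic
    benchmark problems (signalling cascades observed over many conditions, and
    a steady-state viability dose-response problem) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
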