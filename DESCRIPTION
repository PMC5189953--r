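Package: clockloops
Title: Feedback-Loop Analysis of a Delay-Differential Circadian Clock Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-gene delay-differential model of the mammalian circadian
    oscillator (Bmal1, Rev-erb-alpha, Per2, Cry1, Dbp) together with the
    machinery needed to dissect which feedback loops generate its rhythm:
    a fixed-step method-of-steps integrator, a limit-cycle classifier,
    node- and edge-clamping operations with an exhaustive 2^17
    edge-configuration census and per-edge importance statistics,
    one-parameter bifurcation sweeps with period-jump and hysteresis
    detection, Goodwin-versus-repressilator prototype robustness analysis,
    and a synthetic qPCR-style profile generator with a seeded
    differential-evolution fitting harness for parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    yaml,
    jsonlite,
    generics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
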