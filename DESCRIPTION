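Package: priorlearn
Title: Simulating and Measuring the Learning of Priors in a Cue-Integration Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how an observer learns the prior distribution
    of target locations in a one-dimensional "coin catching" estimation task.
    Simulates the three experimental protocols (fixed prior, mid-session
    variance switch, repeatedly switching mean), runs ideal and heuristic
    observer models on them (a Normal-scaled-Inverse-Gamma conjugate learner,
    a fixed-learning-rate variance filter, and an exact change-point inference
    model), and recovers the evolving prior from trial logs with the binned
    least-squares analysis used in the sensorimotor learning literature.
    Includes maximum-likelihood fitting of observer hyperparameters to binned
    learning curves and held-out prediction for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    digest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
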