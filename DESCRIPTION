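Package: sedkit
Title: Sedentary-Behavior Analytics from Smartphone Mobility Event Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for desk-scale analysis of smartphone-sensed sedentary
    behavior. Parses newline-delimited event logs (activity transitions, step
    deltas, location fixes, heartbeats, screen and app-interaction events),
    computes heartbeat-based data coverage, bins steps into clock hours and
    labels sedentary hours by a step-count threshold, detects personal
    sedentary places by stay-point extraction and greedy spatial clustering,
    assembles daily and multi-day visualization aggregates, codes the
    specificity of when/where/how action plans, quantifies engagement with
    feedback visualizations, and evaluates change with JZS Cauchy-prior
    Bayes factors, Bayesian Pearson correlations, and small-sample
    nonparametric tests. Includes a synthetic participant simulator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
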