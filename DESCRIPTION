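Package: rgtnet
Title: Rodent Gambling-Task Phenotyping, Permutation Statistics and
    Behavioral Correlation Networks
Version: 0.1.0
Authors@R:
    person("rgtnet", "developers", email = "rgtnet@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for operant decision-making
    phenotyping studies in rodents. Simulates Rat Gambling Task (RGT),
    reversed-RGT and probability discounting task (PDT) sessions as
    trial-level event logs; computes behavioral scores and classifications
    (decision-maker subtypes, flexibility classes, discounting AUC over the
    odds transform, social preference and short-term social recognition
    memory ratios, batch-normalized neurochemistry); provides an inferential
    layer (exact Fisher test, rank tests, two-stratum permutation ANOVA with
    subject as error factor); and builds thresholded Spearman correlation
    networks over behavioral variables with strength centrality. A synthetic
    cohort generator with a Gaussian-copula behavior model makes the full
    pipeline testable end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
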