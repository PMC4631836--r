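Package: actinf
Title: Active Inference Agents with Dirichlet Learning for Discrete
    Markov Decision Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates instrumental conditioning with an active inference
    agent that solves a finite-horizon Markov decision process by
    variational Bayes. Beliefs about the observation and state-transition
    matrices carry conjugate Dirichlet priors, so learning reduces to
    accumulating expected counts, while within-trial inference iterates
    closed-form updates for hidden states, policies and the expected
    precision of policy beliefs. Expected precision acts as an inverse
    temperature on action selection and is read out as a simulated phasic
    dopamine signal by deconvolution with an exponential kernel, with
    optional Poisson spike-count histograms. Includes declarative
    precision-clamp schedules that emulate dopamine depletion and midbrain
    stimulation, and experiment drivers for parameter recovery, reward
    transfer, depletion/restoration, and stimulation-induced preference
    reversal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
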