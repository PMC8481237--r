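Package: pomdpconf
Title: POMDP Models of Perceptual Choice, Confidence, and Post-Decision Wagering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conjugate-Gaussian belief inference for perceptual decision making
    framed as a partially observable Markov decision process (POMDP) with a
    decision maker that has incomplete knowledge of the stimulus generative
    model. Provides belief updating over signed motion coherence, confidence as
    the posterior probability of the chosen direction, cost-based termination
    policies via one-step look-ahead with an exact mapping to drift-diffusion
    collapsing bounds, post-decision wagering (sure-bet) rules, simulators for
    fixed-duration and reaction-time variants of the random-dot task, the
    maximum-likelihood parameter-estimation pipeline (observation noise, prior,
    learned noise, utility ratio, particle-filter likelihood for non-zero
    observation cost), type-1 and type-2 sensitivity (d-prime and meta-d-prime
    for binary confidence ratings), and scripted simulation experiments
    reproducing classic dissociations between accuracy and confidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
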