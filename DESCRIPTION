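Package: transcend
Title: Hierarchical Active-Inference Agents with Cultural Precision and
    Moral Typing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A discrete-state multi-agent simulator for studying how
    cultural priors shape individual behaviour. Agents are partially
    observable Markov decision processes that perceive, learn and act by
    minimising variational and expected free energy. A two-level
    hierarchy lets categorical typing beliefs (in-group/out-group or
    richer taxonomies) constrain lower-level inference through a
    precision gain alpha; observers score each other under a cultural
    versus an egocentric behavioural model by accumulated log-evidence,
    declare norm violations, and trigger sanctions that raise alpha in
    the audience. A foraging world with cooperative yields, signalling,
    concealment and banishment provides the generative process, and
    experiment harnesses measure version fitness, structure-learning
    regimes, signal information content and belief polarization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
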