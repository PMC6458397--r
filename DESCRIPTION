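Package: soclearn
Title: Associative Learning Simulation of Social Learning Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an error-correction model of associative learning in
    which an agent acquires stimulus-response values, response-independent
    stimulus values (conditioned reinforcement), and chooses actions with a
    softmax rule over compound stimuli. Scenario worlds are stochastic state
    machines; built-in scenarios cover learning responses to social stimuli,
    contextual imitation, socially facilitated transfer to non-social stimuli,
    behaviour-sequence learning through response chaining, and avoidance
    learning guided by warning calls. Replicated simulations are summarised
    into tidy per-trial learning curves with plotting, CSV export, and a
    reproducible command-line runner driven by declarative YAML configs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
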