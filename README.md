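# soclearn

Simulation of social learning through associative processes.

`soclearn` is for behavioural ecologists and animal-cognition modellers who
want to ask how far plain associative learning, guided by genetic
predispositions, can carry the phenomena catalogued under "social
learning" — stimulus and local enhancement, contextual imitation,
observational conditioning, socially transmitted avoidance — without any
dedicated social-learning machinery. Social stimuli (a conspecific's
presence, its perceived behaviour `[B]`, its calls) are ordinary stimulus
elements; what is "social" about a scenario lives entirely in its world
structure and initial conditions.

## The model

An agent experiences discrete triplets *S → B → S′* and maintains two
memories: stimulus–response values *v(S → B)* (instrumental) and
response-independent stimulus values *w(S)* (Pavlovian / conditioned
reinforcement). Both are updated by error correction toward the total
value *u(S′) + w(S′)* of the consequence, where *u* is innate value:

    Δv(S → B) = α_v [u(S′) + w(S′) − v(S → B)]
    Δw(S)     = α_w [u(S′) + w(S′) − w(S)]

Choice is softmax: Pr(S → B) ∝ exp(β v(S → B)). Compound stimuli sum the
values of their elements, and one experience updates every element of the
compound. Because learned *w* values act as reinforcers in the *v* update,
behaviour chains can be learned link by link (conditioned reinforcement
and chaining). Defaults: α_v = 0.1, α_w = 0.1, β = 1.

Scenario worlds are small stochastic state machines; replicated runs are
averaged into tidy per-trial learning curves. Five built-in scenarios
cover: learning a response to a social stimulus, learning to imitate,
socially assisted transfer to a non-social stimulus, two-step sequence
learning (backward vs socially assisted forward chaining), and avoidance
learning guided by warning calls (with a heterospecific-call variant). See
the vignette `vignettes/model-and-scenarios.Rmd` for the full account of
the model, the scenario designs, and their assumptions. The package also
includes the two combinatorial helpers behind the scenario discussion —
`count_successions()` (how many two-step stimulus successions k elements
allow) and `count_behaviour_sequences()` (the n^l exploration problem) —
but no code for mapping descriptive social-learning taxonomies onto the
model; that mapping is a discussion-level exercise, not a computation.

## Worked example

```r
library(soclearn)
library(dplyr)

sc <- build_social_response()          # respond B to a social stimulus, reward u = 25
tr <- run_replicates(sc, n_replicates = 200, n_trials = 300, seed = 1)
glance(tr)
#> # A tibble: 1 × 7
#>   arm    trial_index n_replicates `freq:responded` `p:S_social->B` `v:S_social->B` `v:S_social->other`
#> 1 social         300          200                1           1.000            25.0                   0
```

After 300 learning opportunities the stimulus–response value
`v:S_social->B` has converged on 25 — the innate value of the reinforcer —
while the never-rewarded response stays at 0, and the softmax probability
of responding (`p:S_social->B`) is at its ceiling. The same objects plot
directly:

```r
autoplot(tr)                            # response probability | memory values
```

The avoidance scenario compares arms:

```r
tr2 <- run_replicates(build_avoidance(), n_replicates = 500, seed = 1)
glance(tr2) |> select(arm, p_escape, `w:S_predator`)
#> # A tibble: 2 × 3
#>   arm        p_escape `w:S_predator`
#> 1 individual    0.733          -1.11
#> 2 social        0.907          -2.47
```

With warning calls (social arm) the learner escapes the predator far more
reliably after 50 encounters, and the predator stimulus itself has
acquired negative conditioned value.

From a shell, the same runs are reproducible via the bundled script
(installed under the package's `exec/` directory):

```sh
Rscript exec/soclearn run --scenario social_response --seed 1 --out out/
Rscript exec/soclearn count --successions 2     # prints 9
```

`run` writes the learning-curve CSV plus a `manifest.json` that records
every resolved parameter and the seed; re-running from the manifest
reproduces the CSV byte for byte. Custom worlds can be declared in YAML
(elements with innate values, behaviours, priors, emissions, transitions)
and validated with `Rscript exec/soclearn validate --config my.yaml`.

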