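---
title: "The learning model and the built-in social-learning scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The learning model and the built-in social-learning scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soclearn)
library(dplyr)
```

## The model

`soclearn` simulates a discrete-trial associative learner. The agent's
experience is a sequence of triplets $S \to B \to S'$: it perceives a
stimulus $S$, responds with a behaviour $B$ from its repertoire, and
experiences a consequence $S'$. Three quantities drive behaviour:

* $u(S)$ — the **innate reinforcement value** of a stimulus element
  (genetically given; positive for primary rewards such as food, strongly
  negative for innately aversive signals such as a conspecific warning
  call, zero for neutral stimuli);
* $v(S \to B)$ — the learned **stimulus–response value**, the agent's
  estimate of the reward that follows responding with $B$ to $S$
  (instrumental learning);
* $w(S)$ — the learned **stimulus value**, a response-independent estimate
  of the reward expected after $S$ (Pavlovian learning / conditioned
  reinforcement).

After each experience, both memories move toward the *total* value of the
consequence, $u(S') + w(S')$, by error correction:

$$\Delta v(S \to B) = \alpha_v\,[\,u(S') + w(S') - v(S \to B)\,], \qquad
  \Delta w(S) = \alpha_w\,[\,u(S') + w(S') - w(S)\,].$$

Only the performed behaviour's $v$ entry changes; the $w$ update depends
only on which stimulus followed, not on what the agent did. Because $w(S')$
enters the $v$ update, a stimulus that has acquired value can reinforce
responses that merely *lead to it* — this conditioned-reinforcement pathway
is what lets the model chain behaviour sequences.

Decisions use a softmax over the repertoire,

$$\Pr(S \to B) = \frac{e^{\beta v(S \to B)}}{\sum_{B'} e^{\beta v(S \to B')}},$$

computed with max-subtraction so large values cannot overflow. $\beta = 0$
gives uniform choice; large $\beta$ is near-greedy.

**Compound stimuli.** A perceived stimulus may be a compound of elements
(e.g. a conspecific plus a food item). Values add over elements,
$v(S_1 S_2 \to B) = v(S_1 \to B) + v(S_2 \to B)$ (likewise $u$ and $w$),
and one experience with a compound updates *every* element by the same
delta, computed from the compound totals. Two consequences worth noting:
elements compete for a shared prediction (an element with a strong prior
"absorbs" part of the target, which is exactly what makes social
bootstrapping work), and all computed quantities are invariant under
element reordering. All deltas within one update use pre-update values.
Element salience and continuous stimulus dimensions are deliberately not
modelled.

Social stimuli — another individual's presence, its perceived behaviour
(written `[B]`), its calls — are ordinary stimulus elements; the learning
rules never treat them specially. Everything "social" about a scenario
lives in its world structure and its genetically supplied initial
conditions (priors and innate values).

**Parameters.** Defaults are $\alpha_v = 0.1$, $\alpha_w = 0.1$,
$\beta = 1$ (all scenarios use these; the single-response scenarios set
$\alpha_w = 0$ since no stimulus-value learning is needed there). Learning
rates are per-experience fractions of the prediction error; $\beta$ is in
units of inverse value.

## Worlds, trials, replicates

A scenario world is a small stochastic state machine
(`world_machine()`). Each non-terminal state emits a compound stimulus
from a declared mixture, and maps (emission context, behaviour) to a
distribution over outcomes: a consequence compound, a next state, optional
annotation flags, and optional *witnessed successions*. A witnessed
succession $(S, S')$ models observational learning — the learner saw
another individual's stimuli follow one another without acting itself — and
therefore updates only $w$. A transition that was never declared is a
loud error, never a silent default, and `validate_world()` additionally
checks normalisation and that a terminal state is reachable (a 1000-step
guard converts malformed worlds into errors rather than hangs). An outcome
may also carry *no* consequence: the episode simply ends and nothing is
learned from the termination (used in the avoidance scenario, below).

`run_replicates()` simulates many independent agents. Each (arm,
replicate) pair gets a Mersenne–Twister stream seeded by a counter-based
split of the master seed, so results are bitwise reproducible and
independent of execution order. After every trial the runner records the
arm's traced quantities — $v$ and $w$ entries, and *model* response
probabilities from the softmax rather than empirical choice indicators,
which gives smooth curves at any replicate count (empirical frequencies of
annotated events are recorded alongside as `freq:` quantities for
cross-checking). One trial, i.e. one encounter with the relevant
situation, is the unit of the x-axis ("learning opportunities"); trial
index 0 is the state before any learning.

## The five scenarios

All rewards use $u = 25$; "strongly positive" priors use $v = 10$;
"strongly negative" innate values use $u = -10$. Only the reward magnitude
is anchored in the modelled setting; the others are representative
magnitudes, configurable per builder. Replicate defaults are 1000 (2000
for avoidance). Trial-count defaults are not externally given; each was
chosen once so that the figure ends where the socially assisted arm
reaches its visual asymptote while the slower arm is still climbing —
the horizon at which the scenario's qualitative contrast is visible. At
much longer horizons both arms of the single-response scenarios saturate
near probability 1 and the contrast disappears; the contrast is a
statement about speed, not about attainable asymptotes.

**Response to a social stimulus** (`build_social_response()`, 300
trials). One social stimulus; responding `B` yields the reward, any other
response a distinct neutral outcome (a real stimulus, so every triplet is
well formed). $v(S_{social} \to B)$ approaches 25 — the reinforcer's value
— while the unrewarded response's value never moves. Forcing the rewarded
choice every trial gives the exact geometric form
$v_t = 25\,(1 - 0.9^t)$, which the tests assert.

**Imitation** (`build_imitation(k)`, 300 trials). The learner sees one of
$k$ behaviour percepts `[Bj]` per trial and is rewarded for matching.
Since this is just $k$ parallel instances of the first scenario, imitation
here is operational: respond-with-what-you-saw. Exploration over a larger
repertoire slows acquisition, so smaller repertoires imitate faster — the
$k$-sweep test checks this monotonicity.

**Transfer to a non-social stimulus** (`build_transfer()`, 25 trials, 10
behaviours). The rewarded stimulus $S_x$ appears alone 80% of the time and
with a social element 20% of the time; the social arm's prior
$v(S_{social} \to B_1) = 10$ makes the agent respond in company, exposing
it to the reward contingency it would rarely find among 10 behaviours on
its own. Both variants share the 10-behaviour repertoire so their figures
are directly comparable. `with_imitation_prior = TRUE` replaces the social element with
the percept `[B1]` and compares an imitating prior against a naive agent
in the *same* world.

**Behaviour sequence** (`build_sequence()`, 20 trials, 2 choices per
step). The chain $S_x \to B_1 \to S_y \to B_2 \to S_{reward}$, with the
first step never primarily rewarded. Design choices to note:

* Conspecific proximity is innately rewarding, $u(S_{social}) = 10$. The
  first step of a social encounter is "rewarded" only by the company that
  persists at the next stimulus; without this the social arm would have
  no first-step signal at all. The same assumption is what makes the
  witnessed succession below informative.
* With probability 0.5 per social encounter the learner witnesses an
  experienced animal take the second step — the succession
  $S_y \to S_{social}[B_2]$, implemented with predecessor $S_y$ alone, so
  $\Delta w(S_y) = \alpha_w [\,u(S_{social}) - w(S_y)\,]$: observational
  conditioning endows $S_y$ with value before the learner ever completes
  the chain itself.
* Traced step curves use the encounter-weighted response probability (the
  stimulus mixture the arm actually faces); the full-sequence curve uses
  the bare stimuli in both arms, because the interesting outcome is
  autonomous performance without conspecifics.

The individual arm shows backward chaining (the second link crosses
$p = 0.5$ before the first, which cannot move until $w(S_y) > 0$); the
social arm shows the reverse order because the social prior carries the
first link from trial 0. Disabling $w$ learning makes a pre-trained first
link decay — S-R learning alone cannot maintain an unrewarded step.

**Avoidance** (`build_avoidance()`, 50 trials; heterospecific variant 200).
Encounters are multi-step: each step the predator leaves with probability
0.2; otherwise the learner escapes or ignores. A companion is present in
half the encounters and calls in half of those; ignoring during a call is
followed by the call stimulus ($u = -10$), which devalues both
$v(S_{pred} \to B_{ignore})$ and $w(S_{pred})$. Without a call the only
teacher is a rare attack ($u = -10$, probability 0.05 per ignored step) —
the individual arm's sole learning signal, hence its slowness. Escape and
departure end the encounter with *no* experienced consequence: the episode
is over and there is nothing to learn from. This matters: if escaping led
to an experienced neutral "safety" stimulus, every successful escape would
extinguish the predator's acquired negative value toward 0, and the
scenario's defining outcome ($w(S_{pred})$ strongly negative, persisting)
could not survive its own success. A side effect is that
$v(S_{pred} \to B_{escape})$ stays 0 and $w(S_{pred})$ coincides exactly
with $v(S_{pred} \to B_{ignore})$ (both are updated by the same error on
the same ignore steps). The injury-risk trace is the closed-form model
probability of ignoring throughout an encounter — a proxy, since injury
itself is not modelled. At the 50-encounter default the social arm's final
means are around $-2.5$ for both devalued quantities: clearly negative, but
more moderate than the initial punishment value because negative updates
stop once the agent escapes reliably.

The heterospecific variant adds a foreign alarm call $S_x$ heard in
sequence with the conspecific call during call encounters (a witnessed
succession $S_x \to S_{warning}$, since both calls are triggered by the
predator regardless of what the learner does). Because $S_{warning}$ is
itself never a predecessor, $w(S_x)$ converges exactly on $u(S_{warning})$;
at the 200-encounter default the gap is below 0.1.

## What the simulations do and do not show

The generator emulates idealised laboratory-style worlds: discrete trials,
perfectly identifiable stimulus elements, stationary contingencies, a
fixed repertoire, and exact mixture probabilities. Real social learning
adds everything these omit — perceptual confusion between similar motor
patterns, non-stationary companions, correspondence problems beyond the
hand-coded percept elements, salience differences, and memory for
sequences of observations (the model retains none). Passing tests
therefore show that the *mechanism* produces the claimed phenomena under
its stated assumptions, not that any particular species learns this way.
Combinatorial helpers (`count_successions()`, `count_behaviour_sequences()`)
quantify why unguided sequence learning is hard ($n^l$ exploration) and
why entry patterns — where along a chain experience begins — matter.

## Numerical choices

* Probability sums are validated to $10^{-8}$; softmax normalisation is
  asserted to $10^{-12}$ in tests.
* All updates inside one experience use pre-update values (the update is
  simultaneous; the within-step ordering is otherwise unobservable).
* Ties in the softmax need no tie-break: sampling uses the full
  distribution.
* Degenerate inputs fail loudly: empty compounds or repertoires, unknown
  names, non-normalised distributions, unreachable terminal states, and
  missing transition entries are all errors, as is a missing master seed.
* Trace CSV files print 12 significant digits — diffable, and re-reading
  reproduces the written table to that precision (re-writing the re-read
  table is byte-identical).
* Problem sizes in the test suite: full-scale figure properties run at
  the full default 1000/2000 replicates; module-level qualitative checks use
  100–400 replicates, which is ample for the asserted sign and ordering
  contrasts.

## Known limitations

Single learner only (the experienced animal is part of the world, not a
second agent); no eligibility traces, discounting, or salience weighting;
no memory for observed sequences, hence no production imitation of novel
sequences; observational learning affects $w$ only — observational S-R
learning is deliberately outside the model. The avoidance scenario's
magnitudes (warning value, attack probability) are representative choices,
not fits to data; its qualitative claims are robust to them, its printed
curves are not.
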