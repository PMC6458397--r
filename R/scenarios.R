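# Built-in scenarios ------------------------------------------------------
#
# Each builder assembles a `scenario`: shared stimulus elements (with innate
# values u), a behaviour repertoire, learning parameters, and one or more
# arms. An arm is a world machine plus an initial memory (priors) and the
# quantities traced per trial. Qualitative priors from the scenario
# descriptions ("strongly positive", "strongly negative") are concrete,
# configurable magnitudes: v_prior = 10, u_warning = -10, reward u = 25.

new_scenario <- function(name, elements, repertoire, params, arms, defaults,
                         config = list()) {
  sc <- structure(
    list(name = name, elements = elements, repertoire = repertoire,
         params = params, arms = arms, defaults = defaults, config = config),
    class = "scenario"
  )
  for (arm in sc$arms) {
    validate_world(arm$world, elements$name, repertoire)
  }
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, "\n", sep = "")
  cat("  elements:   ", paste(x$elements$name, collapse = ", "), "\n", sep = "")
  cat("  repertoire: ", paste(x$repertoire, collapse = ", "), "\n", sep = "")
  cat("  arms:       ", paste(names(x$arms), collapse = ", "), "\n", sep = "")
  cat("  defaults:   ", x$defaults$n_replicates, " replicates x ",
      x$defaults$n_trials, " trials\n", sep = "")
  invisible(x)
}

element_table <- function(name, u, is_social) {
  tibble::tibble(name = name, u = as.double(u), is_social = is_social)
}

make_memory <- function(elements, repertoire, params, v_prior = NULL,
                        w_prior = NULL) {
  agent_memory(
    u = stats::setNames(elements$u, elements$name),
    repertoire = repertoire, params = params, v_prior = v_prior,
    w_prior = w_prior,
    is_social = stats::setNames(elements$is_social, elements$name)
  )
}

new_arm <- function(world, initial_memory, trace, flag_trace = character()) {
  list(world = world, initial_memory = initial_memory, trace = trace,
       flag_trace = flag_trace)
}

end_state <- function() world_state(terminal = TRUE)

#' Scenario: learning a response to a social stimulus
#'
#' A single social stimulus; responding with B yields a rewarding outcome
#' (innate value 25), any other response a distinct neutral outcome. Only
#' stimulus-response learning operates (\code{alpha_w = 0}): this is plain
#' instrumental acquisition, and v(S_social -> B) climbs towards the
#' reinforcer's value 25 while v(S_social -> other) stays at zero.
#'
#' @param alpha_v,beta Learning parameters.
#' @param u_reward Innate value of the rewarding outcome.
#' @param n_replicates,n_trials Default run sizes.
#' @return A scenario with a single arm \code{"social"}.
#' @examples
#' sc <- build_social_response()
#' run_replicates(sc, n_replicates = 10, n_trials = 30, seed = 1)
#' @export
build_social_response <- function(alpha_v = 0.1, beta = 1, u_reward = 25,
                                  n_replicates = 1000, n_trials = 300) {
  elements <- element_table(
    c("S_social", "S_reward", "S_no_reward"),
    c(0, u_reward, 0),
    c(TRUE, FALSE, FALSE)
  )
  repertoire <- c("B", "other")
  params <- learning_parameters(alpha_v = alpha_v, alpha_w = 0, beta = beta)
  world <- world_machine(
    states = list(
      encounter = world_state(
        emissions = list(emission(1, "S_social", key = "enc")),
        transitions = list(
          "enc::B" = list(outcome(1, "S_reward", "end", flags = "responded")),
          "enc::other" = list(outcome(1, "S_no_reward", "end"))
        )
      ),
      end = end_state()
    ),
    start = "encounter"
  )
  trace <- list(
    trace_p_single("S_social", "B"),
    trace_v("S_social", "B"),
    trace_v("S_social", "other")
  )
  mem <- make_memory(elements, repertoire, params)
  new_scenario(
    "social_response", elements, repertoire, params,
    arms = list(social = new_arm(world, mem, trace, flag_trace = "responded")),
    defaults = list(n_replicates = n_replicates, n_trials = n_trials),
    config = list(u_reward = u_reward)
  )
}

#' Scenario: learning to imitate observed behaviours
#'
#' An experienced animal performs one of k behaviours; the learner perceives
#' the corresponding social stimulus "[Bj]" and is rewarded only for
#' repeating the observed behaviour. Learning to respond with Bj to [Bj] is
#' operational imitation. Larger repertoires dilute exploration, so
#' acquisition slows with k (fewer-behaviour species imitate more readily).
#'
#' @param k Number of observable/performable behaviours (>= 2).
#' @inheritParams build_social_response
#' @return A scenario with a single arm \code{"social"}.
#' @export
build_imitation <- function(k = 2, alpha_v = 0.1, beta = 1, u_reward = 25,
                            n_replicates = 1000, n_trials = 300) {
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("`k` must be at least 2", call. = FALSE)
  }
  k <- as.integer(k)
  behaviours <- paste0("B", seq_len(k))
  percepts <- paste0("[", behaviours, "]")
  elements <- element_table(
    c(percepts, "S_reward", "S_no_reward"),
    c(rep(0, k), u_reward, 0),
    c(rep(TRUE, k), FALSE, FALSE)
  )
  params <- learning_parameters(alpha_v = alpha_v, alpha_w = 0, beta = beta)
  obs_states <- lapply(seq_len(k), function(j) {
    key <- paste0("obs", j)
    transitions <- lapply(behaviours, function(b) {
      if (b == behaviours[[j]]) {
        list(outcome(1, "S_reward", "end", flags = "matched"))
      } else {
        list(outcome(1, "S_no_reward", "end"))
      }
    })
    names(transitions) <- paste0(key, "::", behaviours)
    world_state(
      emissions = list(emission(1, percepts[[j]], key = key)),
      transitions = transitions
    )
  })
  names(obs_states) <- paste0("observe_", seq_len(k))
  world <- world_machine(
    states = c(obs_states, list(end = end_state())),
    start = stats::setNames(rep(1 / k, k), names(obs_states))
  )
  trace <- list(
    trace_p_single(percepts[[1]], behaviours[[1]]),
    trace_v(percepts[[1]], behaviours[[1]]),
    trace_v(percepts[[1]], behaviours[[2]])
  )
  mem <- make_memory(elements, behaviours, params)
  new_scenario(
    "imitation", elements, behaviours, params,
    arms = list(social = new_arm(world, mem, trace, flag_trace = "matched")),
    defaults = list(n_replicates = n_replicates, n_trials = n_trials),
    config = list(k = k, u_reward = u_reward)
  )
}

#' Scenario: social transfer of a response to a non-social stimulus
#'
#' A non-social stimulus S_x is rewarded when answered with B1 out of a
#' 10-behaviour repertoire. In the social arm, S_x appears alone 80% of the
#' time and in compound with a social element 20% of the time; the learner
#' starts with a strong prior to respond B1 to the social element, which
#' bootstraps responding to S_x (stimulus enhancement). The individual arm
#' encounters S_x only, with no prior: pure trial-and-error. With
#' \code{with_imitation_prior = TRUE} the social element is the percept
#' "[B1]" of the rewarded behaviour and both arms see the compound; the
#' "imitating" arm has the prior v([B1] -> B1), the "naive" arm does not.
#'
#' @param with_imitation_prior Build the imitation-assisted variant.
#' @param v_prior Initial value of the social response prior.
#' @param p_social Probability of the compound (social) encounter.
#' @param n_behaviours Repertoire size; B1 is the rewarded behaviour.
#' @inheritParams build_social_response
#' @return A scenario with arms \code{social}/\code{individual} (or
#'   \code{imitating}/\code{naive}).
#' @export
build_transfer <- function(with_imitation_prior = FALSE, v_prior = 10,
                           p_social = 0.2, n_behaviours = 10, alpha_v = 0.1,
                           beta = 1, u_reward = 25, n_replicates = 1000,
                           n_trials = 25) {
  behaviours <- paste0("B", seq_len(n_behaviours))
  social_el <- if (with_imitation_prior) "[B1]" else "S_social"
  elements <- element_table(
    c(social_el, "S_x", "S_reward", "S_no_reward"),
    c(0, 0, u_reward, 0),
    c(TRUE, FALSE, FALSE, FALSE)
  )
  params <- learning_parameters(alpha_v = alpha_v, alpha_w = 0, beta = beta)
  reward_transitions <- function(key) {
    tr <- lapply(behaviours, function(b) {
      if (b == "B1") {
        list(outcome(1, "S_reward", "end", flags = "responded"))
      } else {
        list(outcome(1, "S_no_reward", "end"))
      }
    })
    names(tr) <- paste0(key, "::", behaviours)
    tr
  }
  mixture_world <- world_machine(
    states = list(
      encounter = world_state(
        emissions = list(
          emission(1 - p_social, "S_x", key = "alone"),
          emission(p_social, c(social_el, "S_x"), key = "joint")
        ),
        transitions = c(reward_transitions("alone"), reward_transitions("joint"))
      ),
      end = end_state()
    ),
    start = "encounter"
  )
  alone_world <- world_machine(
    states = list(
      encounter = world_state(
        emissions = list(emission(1, "S_x", key = "alone")),
        transitions = reward_transitions("alone")
      ),
      end = end_state()
    ),
    start = "encounter"
  )
  trace <- list(
    trace_p_single("S_x", "B1"),
    trace_v("S_x", "B1"),
    trace_v(social_el, "B1")
  )
  prior_tbl <- data.frame(element = social_el, behaviour = "B1",
                          value = v_prior)
  mem_prior <- make_memory(elements, behaviours, params, v_prior = prior_tbl)
  mem_naive <- make_memory(elements, behaviours, params)
  arms <- if (with_imitation_prior) {
    list(
      imitating = new_arm(mixture_world, mem_prior, trace, "responded"),
      naive = new_arm(mixture_world, mem_naive, trace, "responded")
    )
  } else {
    list(
      social = new_arm(mixture_world, mem_prior, trace, "responded"),
      individual = new_arm(alone_world, mem_naive, trace, "responded")
    )
  }
  new_scenario(
    if (with_imitation_prior) "transfer_imitation" else "transfer",
    elements, behaviours, params, arms,
    defaults = list(n_replicates = n_replicates, n_trials = n_trials),
    config = list(with_imitation_prior = with_imitation_prior,
                  v_prior = v_prior, p_social = p_social,
                  n_behaviours = n_behaviours, u_reward = u_reward)
  )
}

#' Scenario: learning a two-step behaviour sequence
#'
#' The food-truck chain: S_x answered with B1 leads to S_y, and S_y answered
#' with B2 leads to the reward. The first step is never primarily rewarded,
#' so autonomous performance requires S_y to acquire conditioned value
#' (w(S_y) > 0), which then reinforces the first link (chaining). In the
#' social arm the learner encounters S_x alone 80% of the time and together
#' with experienced conspecifics 20% of the time; conspecific proximity is
#' innately rewarding (u(S_social) = \code{u_social}) and the learner starts
#' with a prior to approach conspecifics. While in company it may also
#' witness an experienced animal perform the second step (the succession
#' S_y -> S_social [B2]), which conditions S_y by observation alone. The
#' individual arm has no social elements: acquisition proceeds by backward
#' chaining (the second link is learned first).
#'
#' @param v_prior Initial v(S_social -> B1).
#' @param u_social Innate value of conspecific proximity.
#' @param p_social Probability that conspecifics are present at the truck.
#' @param p_obs Probability of witnessing the experienced animal's second
#'   step during a social encounter.
#' @inheritParams build_social_response
#' @return A scenario with arms \code{social} and \code{individual}.
#' @export
build_sequence <- function(v_prior = 10, u_social = 10, p_social = 0.2,
                           p_obs = 0.5, alpha_v = 0.1, beta = 1,
                           u_reward = 25, n_replicates = 1000,
                           n_trials = 20) {
  elements <- element_table(
    c("S_social", "[B2]", "S_x", "S_y", "S_reward", "S_no_event"),
    c(u_social, 0, 0, 0, u_reward, 0),
    c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  repertoire <- c("B1", "B2")
  params <- learning_parameters(alpha_v = alpha_v, alpha_w = 0.1, beta = beta)
  observe_b2 <- list(list(prob = p_obs, from = "S_y",
                          to = c("S_social", "[B2]")))
  social_world <- world_machine(
    states = list(
      arrive = world_state(
        emissions = list(
          emission(1 - p_social, "S_x", key = "alone1"),
          emission(p_social, c("S_social", "S_x"), key = "joint1")
        ),
        transitions = list(
          "alone1::B1" = list(outcome(1, "S_y", "second_alone")),
          "alone1::B2" = list(outcome(1, "S_no_event", "end")),
          "joint1::B1" = list(outcome(1, c("S_social", "S_y"), "second_joint",
                                      observations = observe_b2)),
          "joint1::B2" = list(outcome(1, "S_no_event", "end"))
        )
      ),
      second_alone = world_state(
        emissions = list(emission(1, "S_y", key = "alone2")),
        transitions = list(
          "alone2::B2" = list(outcome(1, "S_reward", "end",
                                      flags = "sequence_complete")),
          "alone2::B1" = list(outcome(1, "S_no_event", "end"))
        )
      ),
      second_joint = world_state(
        emissions = list(emission(1, c("S_social", "S_y"), key = "joint2")),
        transitions = list(
          "joint2::B2" = list(outcome(1, "S_reward", "end",
                                      flags = "sequence_complete")),
          "joint2::B1" = list(outcome(1, "S_no_event", "end"))
        )
      ),
      end = end_state()
    ),
    start = "arrive"
  )
  individual_world <- world_machine(
    states = list(
      arrive = world_state(
        emissions = list(emission(1, "S_x", key = "alone1")),
        transitions = list(
          "alone1::B1" = list(outcome(1, "S_y", "second_alone")),
          "alone1::B2" = list(outcome(1, "S_no_event", "end"))
        )
      ),
      second_alone = world_state(
        emissions = list(emission(1, "S_y", key = "alone2")),
        transitions = list(
          "alone2::B2" = list(outcome(1, "S_reward", "end",
                                      flags = "sequence_complete")),
          "alone2::B1" = list(outcome(1, "S_no_event", "end"))
        )
      ),
      end = end_state()
    ),
    start = "arrive"
  )
  # per-step response curves use the encounter-weighted model probability
  # (the stimulus mixture of that arm); the full-sequence curve is always
  # evaluated on the bare non-social stimuli (autonomous performance).
  step1_social <- trace_p(list(
    list(weight = 1 - p_social, stimulus = "S_x", behaviour = "B1"),
    list(weight = p_social, stimulus = c("S_social", "S_x"), behaviour = "B1")
  ), label = "p_step1")
  step2_social <- trace_p(list(
    list(weight = 1 - p_social, stimulus = "S_y", behaviour = "B2"),
    list(weight = p_social, stimulus = c("S_social", "S_y"), behaviour = "B2")
  ), label = "p_step2")
  step1_ind <- trace_p(list(list(weight = 1, stimulus = "S_x",
                                 behaviour = "B1")), label = "p_step1")
  step2_ind <- trace_p(list(list(weight = 1, stimulus = "S_y",
                                 behaviour = "B2")), label = "p_step2")
  p_full <- trace_p_prod(list(
    list(stimulus = "S_x", behaviour = "B1"),
    list(stimulus = "S_y", behaviour = "B2")
  ), label = "p_full_sequence")
  base_trace <- list(p_full, trace_v("S_x", "B1"), trace_v("S_y", "B2"),
                     trace_w("S_y"))
  prior_tbl <- data.frame(element = "S_social", behaviour = "B1",
                          value = v_prior)
  mem_social <- make_memory(elements, repertoire, params, v_prior = prior_tbl)
  mem_ind <- make_memory(elements, repertoire, params)
  new_scenario(
    "sequence", elements, repertoire, params,
    arms = list(
      social = new_arm(social_world, mem_social,
                       c(list(step1_social, step2_social), base_trace),
                       "sequence_complete"),
      individual = new_arm(individual_world, mem_ind,
                           c(list(step1_ind, step2_ind), base_trace),
                           "sequence_complete")
    ),
    defaults = list(n_replicates = n_replicates, n_trials = n_trials),
    config = list(v_prior = v_prior, u_social = u_social,
                  p_social = p_social, p_obs = p_obs, u_reward = u_reward)
  )
}

#' Scenario: avoidance learning guided by warning calls
#'
#' Each trial is one predator encounter. At every time step the predator
#' leaves on its own with probability \code{p_leave}; otherwise the learner
#' either escapes (ending the encounter) or ignores the predator. In the
#' social arm an experienced companion is present in half the encounters and
#' gives a warning call in half of those; the call has a large negative
#' innate value, so ignoring while a call sounds is punished
#' (S_predator -> B_ignore -> S_warning), driving both
#' v(S_predator -> B_ignore) and the conditioned value w(S_predator) down.
#' In encounters without a call the only punishment is a rare attack
#' (probability \code{p_attack} per ignored step), which is all the
#' individual arm ever gets: individual avoidance learning is much slower.
#' Escape and predator departure end the encounter with no experienced
#' outcome. The traced injury-risk proxy is the model probability of
#' ignoring throughout an encounter (injury itself is not modelled).
#'
#' With \code{heterospecific_call = TRUE}, encounters with a warning call
#' also expose the learner to the succession S_x -> S_warning (a
#' heterospecific alarm call followed by the conspecific call, both
#' triggered by the predator), so w(S_x) converges on u(S_warning): the
#' learner comes to treat the foreign call like its own species' call.
#'
#' @param heterospecific_call Add the heterospecific alarm-call element.
#' @param u_warning Innate value of the conspecific warning call (strongly
#'   negative).
#' @param u_attack Innate value of being attacked.
#' @param p_leave Per-step probability that the predator leaves.
#' @param p_companion Probability a companion is present at an encounter.
#' @param p_call Probability the companion calls, given presence.
#' @param p_attack Per-ignored-step attack probability when no call sounds.
#' @inheritParams build_social_response
#' @return A scenario with arms \code{social} and \code{individual}.
#' @export
build_avoidance <- function(heterospecific_call = FALSE, u_warning = -10,
                            u_attack = -10, p_leave = 0.2, p_companion = 0.5,
                            p_call = 0.5, p_attack = 0.05, alpha_v = 0.1,
                            beta = 1, n_replicates = 2000,
                            n_trials = if (heterospecific_call) 200 else 50) {
  el_names <- c("S_predator", "S_warning", "S_attack", "S_safe")
  el_u <- c(0, u_warning, u_attack, 0)
  el_social <- c(FALSE, TRUE, FALSE, FALSE)
  if (heterospecific_call) {
    el_names <- c(el_names, "S_x")
    el_u <- c(el_u, 0)
    el_social <- c(el_social, TRUE)
  }
  elements <- element_table(el_names, el_u, el_social)
  repertoire <- c("B_escape", "B_ignore")
  params <- learning_parameters(alpha_v = alpha_v, alpha_w = 0.1, beta = beta)
  hetero_obs <- if (heterospecific_call) {
    list(list(prob = 1, from = "S_x", to = "S_warning"))
  } else {
    list()
  }
  p_stay <- 1 - p_leave
  nocall_state <- world_state(
    emissions = list(emission(1, "S_predator", key = "pred")),
    transitions = list(
      "pred::B_escape" = list(outcome(1, NULL, "end", flags = "escaped")),
      "pred::B_ignore" = list(
        outcome(p_leave, NULL, "end"),
        outcome(p_stay * p_attack, "S_attack", "end", flags = "attacked"),
        outcome(p_stay * (1 - p_attack), "S_predator", "no_call")
      )
    )
  )
  call_state <- world_state(
    emissions = list(emission(1, "S_predator", key = "pred")),
    transitions = list(
      "pred::B_escape" = list(outcome(1, NULL, "end", flags = "escaped",
                                      observations = hetero_obs)),
      "pred::B_ignore" = list(
        outcome(p_leave, NULL, "end", observations = hetero_obs),
        outcome(p_stay, "S_warning", "with_call", flags = "warned",
                observations = hetero_obs)
      )
    )
  )
  p_warned <- p_companion * p_call
  social_world <- world_machine(
    states = list(no_call = nocall_state, with_call = call_state,
                  end = end_state()),
    start = c(no_call = 1 - p_warned, with_call = p_warned)
  )
  individual_world <- world_machine(
    states = list(no_call = nocall_state, end = end_state()),
    start = "no_call"
  )
  risk_a <- p_leave + p_stay * p_attack
  risk_b <- p_stay * (1 - p_attack)
  trace <- list(
    trace_p_single("S_predator", "B_escape", label = "p_escape"),
    trace_persist("S_predator", "B_ignore", a = risk_a, b = risk_b,
                  label = "p_ignore_throughout"),
    trace_v("S_predator", "B_ignore"),
    trace_v("S_predator", "B_escape"),
    trace_w("S_predator")
  )
  if (heterospecific_call) trace <- c(trace, list(trace_w("S_x")))
  mem <- make_memory(elements, repertoire, params)
  new_scenario(
    if (heterospecific_call) "avoidance_heterospecific" else "avoidance",
    elements, repertoire, params,
    arms = list(
      social = new_arm(social_world, mem, trace, "escaped"),
      individual = new_arm(individual_world, mem, trace, "escaped")
    ),
    defaults = list(n_replicates = n_replicates, n_trials = n_trials),
    config = list(heterospecific_call = heterospecific_call,
                  u_warning = u_warning, u_attack = u_attack,
                  p_leave = p_leave, p_companion = p_companion,
                  p_call = p_call, p_attack = p_attack)
  )
}

# Combinatorics helpers ---------------------------------------------------

#' Count two-step stimulus successions
#'
#' With k base stimulus elements one can form \code{2^k - 1} non-empty
#' compounds, hence \code{(2^k - 1)^2} ordered two-step successions
#' (k = 2 gives 3 x 3 = 9; k = 3 gives 7 x 7 = 49).
#'
#' @param k_base_elements Number of base stimulus elements (>= 1).
#' @return The number of ordered successions, as a double.
#' @examples
#' count_successions(2) # 9
#' count_successions(3) # 49
#' @export
count_successions <- function(k_base_elements) {
  if (!is.numeric(k_base_elements) || length(k_base_elements) != 1L ||
      k_base_elements < 1 || k_base_elements != round(k_base_elements)) {
    stop("`k_base_elements` must be a positive integer", call. = FALSE)
  }
  (2^k_base_elements - 1)^2
}

#' Count behaviour sequences of a given length
#'
#' An animal with a repertoire of n behaviours can try out \code{n^l}
#' behaviour sequences of length l — the exploration problem that makes
#' unguided learning of long sequences take about \code{n^l} trials when
#' every attempt starts at the first step (the "entry pattern" problem).
#'
#' @param n_behaviours Repertoire size (>= 1).
#' @param length Sequence length (>= 1).
#' @return \code{n^l}, as a double.
#' @examples
#' count_behaviour_sequences(2, 3) # 8
#' @export
count_behaviour_sequences <- function(n_behaviours, length) {
  if (!is.numeric(n_behaviours) || length(n_behaviours) != 1L ||
      n_behaviours < 1 || n_behaviours != round(n_behaviours)) {
    stop("`n_behaviours` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(length) || base::length(length) != 1L || length < 1 ||
      length != round(length)) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  n_behaviours^length
}
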