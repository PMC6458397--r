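# Scenario worlds as stochastic state machines.
#
# A world machine is a named list of states plus a start distribution. Each
# non-terminal state emits a compound stimulus from a mixture of emissions
# (each with a context key), and maps (context key, behaviour) to a
# probability distribution over outcomes. An outcome carries the consequence
# compound the agent experiences (possibly NULL: the episode ends with no
# experienced outcome), the next state, optional witnessed stimulus
# successions, and optional annotation flags.

#' Emission rule for a world state
#'
#' @param prob Probability of this emission being chosen at the state.
#' @param stimulus Compound stimulus emitted (character vector of elements).
#' @param key Context key used to look up transitions; defaults to the
#'   elements pasted with "+".
#' @return An emission specification (plain list).
#' @export
emission <- function(prob, stimulus, key = paste(stimulus, collapse = "+")) {
  stopifnot(is.numeric(prob), prob >= 0, length(stimulus) >= 1L)
  list(prob = prob, stimulus = as.character(stimulus), key = key)
}

#' Transition outcome for a world state
#'
#' @param prob Probability of this outcome within its transition entry.
#' @param consequence Consequence compound experienced by the agent, or
#'   \code{NULL} if the episode terminates with no experienced outcome.
#' @param next_state Name of the state entered next (a terminal state name
#'   ends the trial).
#' @param flags Character vector of annotation flags recorded on the trial.
#' @param observations List of witnessed successions, each a list with
#'   elements \code{prob}, \code{from}, \code{to}: with the given
#'   probability the learner witnesses \code{from} followed by \code{to}
#'   (updating w values only).
#' @return An outcome specification (plain list).
#' @export
outcome <- function(prob, consequence, next_state, flags = character(),
                    observations = list()) {
  stopifnot(is.numeric(prob), prob >= 0, is.character(next_state))
  if (!is.null(consequence)) consequence <- as.character(consequence)
  list(prob = prob, consequence = consequence, next_state = next_state,
       flags = flags, observations = observations)
}

#' World state
#'
#' @param emissions List of \code{\link{emission}} specifications (their
#'   probabilities must sum to 1). Ignored for terminal states.
#' @param transitions Named list mapping \code{"<context key>::<behaviour>"}
#'   to a list of \code{\link{outcome}}s whose probabilities sum to 1. A
#'   missing entry for an encountered (context, behaviour) pair is an error
#'   at run time: transitions are never defaulted silently.
#' @param terminal Logical; terminal states end the trial.
#' @return A world state (plain list).
#' @export
world_state <- function(emissions = list(), transitions = list(),
                        terminal = FALSE) {
  list(emissions = emissions, transitions = transitions, terminal = terminal)
}

#' World machine
#'
#' @param states Named list of \code{\link{world_state}}s.
#' @param start Start-state distribution: a named numeric vector of
#'   probabilities over state names (a single unnamed state name is also
#'   accepted).
#' @return An object of class \code{world_machine}.
#' @export
world_machine <- function(states, start) {
  if (is.character(start) && length(start) == 1L && is.null(names(start))) {
    start <- stats::setNames(1, start)
  }
  stopifnot(is.list(states), !is.null(names(states)), is.numeric(start),
            !is.null(names(start)))
  structure(list(states = states, start = start), class = "world_machine")
}

#' Validate a world machine against a scenario's elements and repertoire
#'
#' Checks that every emission and transition distribution sums to one, that
#' every referenced stimulus element, behaviour and state exists, and that a
#' terminal state is reachable from every non-terminal state (so trials
#' cannot run forever).
#'
#' @param world A \code{\link{world_machine}}.
#' @param elements Character vector of known stimulus element names.
#' @param repertoire Character vector of behaviour names.
#' @param tol Tolerance for probability sums.
#' @return \code{TRUE}, invisibly; otherwise an error naming the offending
#'   state.
#' @export
validate_world <- function(world, elements, repertoire, tol = 1e-8) {
  stopifnot(inherits(world, "world_machine"))
  states <- world$states
  bad_start <- setdiff(names(world$start), names(states))
  if (length(bad_start)) {
    stop("start distribution references unknown state(s): ",
         paste(bad_start, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(world$start) - 1) > tol) {
    stop("start-state probabilities must sum to 1", call. = FALSE)
  }
  # states reaching a terminal state (fixed point of backward reachability)
  can_end <- vapply(states, function(s) isTRUE(s$terminal), logical(1))
  for (nm in names(states)) {
    st <- states[[nm]]
    if (isTRUE(st$terminal)) next
    if (length(st$emissions) == 0L) {
      stop("state '", nm, "' is non-terminal but has no emissions", call. = FALSE)
    }
    p_em <- vapply(st$emissions, `[[`, numeric(1), "prob")
    if (abs(sum(p_em) - 1) > tol) {
      stop("emission probabilities in state '", nm, "' sum to ",
           format(sum(p_em)), ", not 1", call. = FALSE)
    }
    for (em in st$emissions) check_compound(em$stimulus, elements)
    for (key in names(st$transitions)) {
      beh <- sub("^.*::", "", key)
      check_behaviours(beh, repertoire)
      outs <- st$transitions[[key]]
      p_out <- vapply(outs, `[[`, numeric(1), "prob")
      if (abs(sum(p_out) - 1) > tol) {
        stop("transition '", key, "' in state '", nm, "' has outcome ",
             "probabilities summing to ", format(sum(p_out)), ", not 1",
             call. = FALSE)
      }
      for (o in outs) {
        if (!is.null(o$consequence)) check_compound(o$consequence, elements)
        if (!o$next_state %in% names(states)) {
          stop("transition '", key, "' in state '", nm,
               "' references unknown state '", o$next_state, "'", call. = FALSE)
        }
        for (ob in o$observations) {
          check_compound(ob$from, elements)
          check_compound(ob$to, elements)
        }
      }
    }
  }
  repeat {
    grew <- FALSE
    for (nm in names(states)) {
      if (can_end[[nm]]) next
      nxt <- unlist(lapply(states[[nm]]$transitions,
                           function(outs) vapply(outs, `[[`, "", "next_state")))
      if (length(nxt) && any(can_end[nxt])) {
        can_end[[nm]] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  stuck <- names(can_end)[!can_end]
  if (length(stuck)) {
    stop("no terminal state reachable from state(s): ",
         paste(stuck, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# internal samplers -------------------------------------------------------

sample_index <- function(probs) {
  if (length(probs) == 1L) return(1L)
  sample.int(length(probs), 1L, prob = probs)
}

sample_emission <- function(state) {
  state$emissions[[sample_index(vapply(state$emissions, `[[`, numeric(1), "prob"))]]
}

lookup_transition <- function(state, state_name, key, behaviour) {
  outs <- state$transitions[[paste0(key, "::", behaviour)]]
  if (is.null(outs)) {
    stop("no transition declared in state '", state_name, "' for context '",
         key, "' and behaviour '", behaviour, "'", call. = FALSE)
  }
  outs
}

sample_outcome <- function(outs) {
  outs[[sample_index(vapply(outs, `[[`, numeric(1), "prob"))]]
}

#' Emit a stimulus from a world state
#'
#' Draws one emission from the state's mixture using the current RNG stream.
#'
#' @param world A \code{\link{world_machine}}.
#' @param state Name of a non-terminal state.
#' @return A list with \code{stimulus} (compound) and \code{key} (context).
#' @export
emit_stimulus <- function(world, state) {
  st <- world$states[[state]]
  if (is.null(st)) stop("unknown state '", state, "'", call. = FALSE)
  if (isTRUE(st$terminal)) stop("state '", state, "' is terminal", call. = FALSE)
  em <- sample_emission(st)
  list(stimulus = em$stimulus, key = em$key)
}

#' Advance a world one step
#'
#' Draws a consequence and next state from the declared transition
#' distribution for the given context and behaviour. Reproducible under a
#' fixed RNG state; a missing transition entry is an error.
#'
#' @param world A \code{\link{world_machine}}.
#' @param state Name of the current (non-terminal) state.
#' @param behaviour The behaviour performed.
#' @param context Context key of the emission the behaviour answered;
#'   defaults to the state's single emission key when unambiguous.
#' @return A list with \code{consequence} (compound or NULL),
#'   \code{next_state}, \code{terminal} (logical), and \code{flags}.
#' @export
advance <- function(world, state, behaviour, context = NULL) {
  st <- world$states[[state]]
  if (is.null(st)) stop("unknown state '", state, "'", call. = FALSE)
  if (isTRUE(st$terminal)) stop("state '", state, "' is terminal", call. = FALSE)
  if (is.null(context)) {
    keys <- unique(vapply(st$emissions, `[[`, "", "key"))
    if (length(keys) != 1L) {
      stop("state '", state, "' has several emission contexts; ",
           "supply `context`", call. = FALSE)
    }
    context <- keys
  }
  out <- sample_outcome(lookup_transition(st, state, context, behaviour))
  list(consequence = out$consequence, next_state = out$next_state,
       terminal = isTRUE(world$states[[out$next_state]]$terminal),
       flags = out$flags)
}

#' Run one trial of an agent in a world
#'
#' Repeatedly emits a stimulus, samples a behaviour from the softmax
#' response distribution, advances the world, applies the learning update
#' for the experienced triplet and the w-only update for any witnessed
#' successions, until a terminal state is reached.
#'
#' @param memory An \code{\link{agent_memory}}.
#' @param world A \code{\link{world_machine}} (validated against the
#'   memory's elements and repertoire).
#' @param record If \code{TRUE}, return the full trial record.
#' @param max_steps Guard limit on steps per trial; exceeding it signals a
#'   malformed world.
#' @return A list with \code{memory} (updated), \code{flags} (character
#'   vector of annotation flags raised during the trial) and, if
#'   \code{record}, \code{record}: a tibble with one row per step and
#'   columns \code{step}, \code{state}, \code{stimulus}, \code{behaviour},
#'   \code{consequence} (stimulus/consequence as "+"-joined element names;
#'   \code{NA} consequence when the episode ended with no outcome).
#' @examples
#' sc <- build_social_response()
#' set.seed(1)
#' tr <- run_trial(sc$arms$social$initial_memory, sc$arms$social$world)
#' tr$record
#' @export
run_trial <- function(memory, world, record = TRUE, max_steps = 1000L) {
  state_name <- names(world$start)[[sample_index(world$start)]]
  flags <- character()
  steps <- 0L
  rec_state <- rec_stim <- rec_beh <- rec_cons <- character()
  while (!isTRUE(world$states[[state_name]]$terminal)) {
    steps <- steps + 1L
    if (steps > max_steps) {
      stop("trial exceeded ", max_steps, " steps: malformed world?",
           call. = FALSE)
    }
    st <- world$states[[state_name]]
    em <- sample_emission(st)
    dist <- softmax_dist(memory, em$stimulus)
    behaviour <- names(dist)[[sample_index(dist)]]
    out <- sample_outcome(lookup_transition(st, state_name, em$key, behaviour))
    memory <- update_experience(memory, em$stimulus, behaviour, out$consequence)
    for (ob in out$observations) {
      if (ob$prob >= 1 || stats::runif(1) < ob$prob) {
        memory <- update_observation(memory, ob$from, ob$to)
      }
    }
    if (length(out$flags)) flags <- c(flags, out$flags)
    if (record) {
      rec_state <- c(rec_state, state_name)
      rec_stim <- c(rec_stim, paste(em$stimulus, collapse = "+"))
      rec_beh <- c(rec_beh, behaviour)
      rec_cons <- c(rec_cons, if (is.null(out$consequence)) NA_character_ else
        paste(out$consequence, collapse = "+"))
    }
    state_name <- out$next_state
  }
  res <- list(memory = memory, flags = flags)
  if (record) {
    res$record <- tibble::tibble(
      step = seq_along(rec_state), state = rec_state, stimulus = rec_stim,
      behaviour = rec_beh, consequence = rec_cons
    )
  }
  res
}
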