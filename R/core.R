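#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Fast internals ----------------------------------------------------------
#
# The exported operations validate their arguments; the trial loop calls
# these unvalidated versions. A compound stimulus is a character vector of
# element names; all arithmetic is plain vector indexing on the memory's
# v matrix and w/u vectors.

sum_v <- function(mem, stimulus, behaviour) {
  sum(mem$v[stimulus, behaviour])
}

total_value <- function(mem, stimulus) {
  sum(mem$u[stimulus]) + sum(mem$w[stimulus])
}

softmax_dist <- function(mem, stimulus) {
  z <- mem$beta * colSums(mem$v[stimulus, , drop = FALSE])
  e <- exp(z - max(z))
  e / sum(e)
}

# One (S, B, S') experience. All deltas use pre-update values; every element
# of the perceived compound receives the same delta (element-wise compound
# update). The w update ignores which behaviour was performed. A NULL
# consequence means the episode ended with no experienced outcome: no update.
update_experience <- function(mem, stimulus, behaviour, consequence) {
  if (is.null(consequence)) return(mem)
  tot <- sum(mem$u[consequence]) + sum(mem$w[consequence])
  dv <- mem$alpha_v * (tot - sum(mem$v[stimulus, behaviour]))
  dw <- mem$alpha_w * (tot - sum(mem$w[stimulus]))
  mem$v[stimulus, behaviour] <- mem$v[stimulus, behaviour] + dv
  if (dw != 0) mem$w[stimulus] <- mem$w[stimulus] + dw
  mem
}

# A witnessed stimulus succession (S, S'): the learner performs no response,
# so only stimulus values are updated.
update_observation <- function(mem, stimulus, consequence) {
  tot <- sum(mem$u[consequence]) + sum(mem$w[consequence])
  dw <- mem$alpha_w * (tot - sum(mem$w[stimulus]))
  if (dw != 0) mem$w[stimulus] <- mem$w[stimulus] + dw
  mem
}

# Exported operations -----------------------------------------------------

#' Stimulus-response value of a compound stimulus
#'
#' The v value of a compound is the sum of the v values of its elements;
#' entries never updated contribute zero.
#'
#' @param memory An \code{\link{agent_memory}}.
#' @param stimulus Character vector of element names (a compound stimulus;
#'   element order is irrelevant).
#' @param behaviour A behaviour name.
#' @return A number: the summed stimulus-response value.
#' @examples
#' mem <- agent_memory(c(X = 0, Y = 0), c("B", "other"))
#' mem <- apply_experience(mem, "X", "B", "Y") # no-op: all values zero
#' compound_v(mem, c("X", "Y"), "B")
#' @export
compound_v <- function(memory, stimulus, behaviour) {
  stopifnot(inherits(memory, "agent_memory"))
  stimulus <- check_compound(stimulus, names(memory$u))
  check_behaviours(behaviour, memory$repertoire)
  sum_v(memory, stimulus, behaviour)
}

#' Total reinforcement value of a compound stimulus
#'
#' The sum of innate (u) and learned (w) values over the compound's elements.
#' This is the quantity a preceding stimulus-response value is driven towards.
#'
#' @inheritParams compound_v
#' @return A number: \code{sum(u) + sum(w)} over the compound's elements.
#' @export
compound_total_value <- function(memory, stimulus) {
  stopifnot(inherits(memory, "agent_memory"))
  stimulus <- check_compound(stimulus, names(memory$u))
  total_value(memory, stimulus)
}

#' Softmax response distribution
#'
#' Choice probabilities over the repertoire given a compound stimulus:
#' \code{Pr(B) = exp(beta * v(S -> B)) / sum_B' exp(beta * v(S -> B'))},
#' computed with max-subtraction so large values cannot overflow. With
#' \code{beta = 0} all behaviours are equally likely.
#'
#' @inheritParams compound_v
#' @param repertoire Optional subset (or reordering) of the memory's
#'   repertoire to restrict the choice to; defaults to the full repertoire.
#' @return A named probability vector over the repertoire (sums to 1).
#' @examples
#' mem <- agent_memory(c(S = 0), c("B", "other"))
#' response_distribution(mem, "S") # uniform before any learning
#' @export
response_distribution <- function(memory, stimulus, repertoire = NULL) {
  stopifnot(inherits(memory, "agent_memory"))
  stimulus <- check_compound(stimulus, names(memory$u))
  if (is.null(repertoire)) {
    repertoire <- memory$repertoire
  } else {
    repertoire <- as.character(repertoire)
    if (length(repertoire) == 0L) stop("empty behaviour repertoire", call. = FALSE)
    check_behaviours(repertoire, memory$repertoire)
  }
  z <- memory$beta * colSums(memory$v[stimulus, repertoire, drop = FALSE])
  e <- exp(z - max(z))
  e / sum(e)
}

#' Sample a behaviour from a response distribution
#'
#' Draws one behaviour with the given probabilities using R's RNG stream, so
#' identical RNG state yields identical choices.
#'
#' @param dist Named probability vector, e.g. from
#'   \code{\link{response_distribution}}.
#' @return The sampled behaviour name.
#' @export
sample_behaviour <- function(dist) {
  if (is.null(names(dist)) || any(dist < 0) || any(!is.finite(dist)) ||
      abs(sum(dist) - 1) > 1e-8) {
    stop("`dist` must be a named probability vector summing to 1", call. = FALSE)
  }
  names(dist)[[sample.int(length(dist), 1L, prob = dist)]]
}

#' Apply one learning experience
#'
#' Updates the memory for one (stimulus, behaviour, consequence) triplet.
#' Writing the consequence's total reinforcement value as
#' \code{T = sum(u) + sum(w)} over its elements, every element \code{S_i} of
#' the perceived compound receives
#' \code{v(S_i -> B) += alpha_v * (T - v(S -> B))} and
#' \code{w(S_i) += alpha_w * (T - w(S))}, where \code{v(S -> B)} and
#' \code{w(S)} are the compound sums *before* the update. Only the performed
#' behaviour's v entries change; the w update is the same whatever behaviour
#' was performed.
#'
#' @inheritParams compound_v
#' @param next_stimulus The consequence compound, or \code{NULL} if the
#'   episode ended with no experienced outcome (no update).
#' @return The updated \code{agent_memory}.
#' @examples
#' mem <- agent_memory(c(S_social = 0, S_reward = 25), c("B", "other"),
#'                     learning_parameters(alpha_w = 0))
#' mem <- apply_experience(mem, "S_social", "B", "S_reward")
#' mem$v["S_social", "B"] # 0.1 * 25 = 2.5
#' @export
apply_experience <- function(memory, stimulus, behaviour, next_stimulus) {
  stopifnot(inherits(memory, "agent_memory"))
  stimulus <- check_compound(stimulus, names(memory$u))
  check_behaviours(behaviour, memory$repertoire)
  if (!is.null(next_stimulus)) {
    next_stimulus <- check_compound(next_stimulus, names(memory$u))
  }
  update_experience(memory, stimulus, behaviour, next_stimulus)
}

#' Apply one witnessed stimulus succession
#'
#' Observational learning: the learner witnesses stimulus \code{stimulus}
#' followed by \code{next_stimulus} without responding, so only stimulus
#' values (w) are updated, by the same error-correction rule as in
#' \code{\link{apply_experience}}.
#'
#' @inheritParams apply_experience
#' @return The updated \code{agent_memory}.
#' @export
apply_observation <- function(memory, stimulus, next_stimulus) {
  stopifnot(inherits(memory, "agent_memory"))
  stimulus <- check_compound(stimulus, names(memory$u))
  next_stimulus <- check_compound(next_stimulus, names(memory$u))
  update_observation(memory, stimulus, next_stimulus)
}
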