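# Trace quantities -------------------------------------------------------
#
# Each scenario arm declares which quantities are recorded after every
# trial. Quantities are evaluated from the model's memory (probabilities
# are softmax model probabilities, not empirical choice frequencies, which
# gives curves as smooth as the averaged figures); annotation-flag
# frequencies are recorded alongside for cross-checking.
#
# Quantity types:
#   v        v(element -> behaviour)
#   w        w(element)
#   p        sum over terms of weight * Pr(behaviour | stimulus)
#   p_prod   product over factors of Pr(behaviour | stimulus)
#   persist  closed-form probability of performing `behaviour` on every
#            step of a geometric episode: p*a / (1 - p*b) with
#            p = Pr(behaviour | stimulus)

trace_v <- function(element, behaviour,
                    label = paste0("v:", element, "->", behaviour)) {
  list(type = "v", label = label, element = element, behaviour = behaviour)
}

trace_w <- function(element, label = paste0("w:", element)) {
  list(type = "w", label = label, element = element)
}

trace_p <- function(terms, label) {
  list(type = "p", label = label, terms = terms)
}

trace_p_single <- function(stimulus, behaviour,
                           label = paste0("p:", paste(stimulus, collapse = "+"),
                                          "->", behaviour)) {
  trace_p(list(list(weight = 1, stimulus = stimulus, behaviour = behaviour)),
          label)
}

trace_p_prod <- function(factors, label) {
  list(type = "p_prod", label = label, factors = factors)
}

trace_persist <- function(stimulus, behaviour, a, b, label) {
  list(type = "persist", label = label, stimulus = stimulus,
       behaviour = behaviour, a = a, b = b)
}

eval_trace_quantities <- function(mem, quantities) {
  vapply(quantities, function(q) {
    switch(q$type,
      v = mem$v[q$element, q$behaviour],
      w = mem$w[[q$element]],
      p = sum(vapply(q$terms, function(tm) {
        tm$weight * softmax_dist(mem, tm$stimulus)[[tm$behaviour]]
      }, numeric(1))),
      p_prod = prod(vapply(q$factors, function(fc) {
        softmax_dist(mem, fc$stimulus)[[fc$behaviour]]
      }, numeric(1))),
      persist = {
        p <- softmax_dist(mem, q$stimulus)[[q$behaviour]]
        p * q$a / (1 - p * q$b)
      },
      stop("unknown trace quantity type: ", q$type)
    )
  }, numeric(1))
}

# Replicate runs ----------------------------------------------------------

# Deterministic counter-based split of the master seed, so each (arm,
# replicate) pair gets its own Mersenne-Twister stream independent of
# execution order. Kept inside 32-bit integer range.
replicate_seed <- function(master_seed, arm_index, replicate_index) {
  (as.double(master_seed) %% 2147483647 +
     1000003 * arm_index + 2654435 * replicate_index) %% 2147483647
}

#' Run replicated simulations of a scenario
#'
#' Runs every arm of a scenario for \code{n_trials} trials in each of
#' \code{n_replicates} independent replicates, each starting from the arm's
#' initial memory with an RNG stream derived deterministically from the
#' master seed, and records the arm's traced quantities after every trial
#' (trial index 0 is the state before any learning). Identical inputs give
#' bitwise-identical output.
#'
#' @param scenario A scenario, e.g. from \code{\link{build_social_response}}.
#' @param n_replicates,n_trials Positive integers; default to the
#'   scenario's declared defaults.
#' @param seed Master seed (required; no silent nondeterminism).
#' @param arms Character vector of arm names to run; defaults to all.
#' @param keep_replicates If \code{TRUE}, attach the per-replicate traces as
#'   attribute \code{"replicates"} (a long tibble with columns \code{arm},
#'   \code{replicate}, \code{trial_index}, \code{quantity}, \code{value}).
#' @return A \code{learning_traces} tibble with columns \code{arm},
#'   \code{trial_index}, \code{quantity}, \code{mean}, \code{stderr},
#'   \code{n_replicates}.
#' @examples
#' sc <- build_social_response()
#' tr <- run_replicates(sc, n_replicates = 20, n_trials = 50, seed = 1)
#' dplyr::filter(tr, trial_index == 50)
#' @export
run_replicates <- function(scenario, n_replicates = NULL, n_trials = NULL,
                           seed, arms = NULL, keep_replicates = FALSE) {
  stopifnot(inherits(scenario, "scenario"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: replicate runs are never silently random",
         call. = FALSE)
  }
  n_replicates <- n_replicates %||% scenario$defaults$n_replicates
  n_trials <- n_trials %||% scenario$defaults$n_trials
  if (!is.numeric(n_replicates) || n_replicates < 1 ||
      !is.numeric(n_trials) || n_trials < 1) {
    stop("`n_replicates` and `n_trials` must be positive", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  n_trials <- as.integer(n_trials)
  arms <- arms %||% names(scenario$arms)
  stopifnot(all(arms %in% names(scenario$arms)))

  out <- vector("list", length(arms))
  reps_out <- if (keep_replicates) vector("list", length(arms))
  for (ai in seq_along(arms)) {
    arm <- scenario$arms[[arms[[ai]]]]
    quantities <- arm$trace
    flag_names <- arm$flag_trace %||% character()
    q_labels <- vapply(quantities, `[[`, "", "label")
    all_labels <- c(q_labels, if (length(flag_names)) paste0("freq:", flag_names))
    # replicate x trial x quantity array of traced values
    vals <- array(NA_real_,
                  dim = c(n_replicates, n_trials + 1L, length(all_labels)))
    arm_index <- match(arms[[ai]], names(scenario$arms))
    for (r in seq_len(n_replicates)) {
      set.seed(replicate_seed(seed, arm_index, r))
      mem <- arm$initial_memory
      vals[r, 1L, seq_along(q_labels)] <- eval_trace_quantities(mem, quantities)
      for (t in seq_len(n_trials)) {
        res <- run_trial(mem, arm$world, record = FALSE)
        mem <- res$memory
        vals[r, t + 1L, seq_along(q_labels)] <-
          eval_trace_quantities(mem, quantities)
        if (length(flag_names)) {
          vals[r, t + 1L, length(q_labels) + seq_along(flag_names)] <-
            as.numeric(flag_names %in% res$flags)
        }
      }
    }
    out[[ai]] <- summarize_trace_array(vals, all_labels, arms[[ai]])
    if (keep_replicates) {
      reps_out[[ai]] <- tibble::tibble(
        arm = arms[[ai]],
        replicate = rep(seq_len(n_replicates), times = (n_trials + 1L) * length(all_labels)),
        trial_index = rep(rep(0:n_trials, each = n_replicates), times = length(all_labels)),
        quantity = rep(all_labels, each = n_replicates * (n_trials + 1L)),
        value = as.vector(vals)
      )
    }
  }
  tbl <- new_learning_traces(dplyr::bind_rows(out))
  if (keep_replicates) {
    attr(tbl, "replicates") <- dplyr::bind_rows(reps_out)
  }
  tbl
}

# means/stderrs over the replicate dimension of a replicate x trial x
# quantity array; drops all-NA cells (flag frequencies at trial 0)
summarize_trace_array <- function(vals, labels, arm) {
  n_rep <- dim(vals)[[1]]
  n_col <- dim(vals)[[2]]
  means <- apply(vals, c(2, 3), mean)
  if (n_rep > 1) {
    sds <- apply(vals, c(2, 3), stats::sd)
    serr <- sds / sqrt(n_rep)
  } else {
    serr <- means * 0
  }
  tbl <- tibble::tibble(
    arm = arm,
    trial_index = rep(0:(n_col - 1L), times = length(labels)),
    quantity = rep(labels, each = n_col),
    mean = as.vector(means),
    stderr = as.vector(serr),
    n_replicates = n_rep
  )
  dplyr::filter(tbl, !is.na(.data$mean))
}

new_learning_traces <- function(tbl) {
  tbl <- dplyr::arrange(tbl, .data$arm, .data$quantity, .data$trial_index)
  class(tbl) <- c("learning_traces", class(tibble::tibble()))
  tbl
}

`%||%` <- function(x, y) if (is.null(x)) y else x
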