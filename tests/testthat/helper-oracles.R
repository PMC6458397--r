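# Shared fixtures and independent oracles, built in code.

# a small two-element, two-behaviour memory with adjustable priors
tiny_memory <- function(alpha_v = 0.1, alpha_w = 0.1, beta = 1,
                        v_prior = NULL, w_prior = NULL) {
  agent_memory(
    u = c(X = 0, Y = 0, S_reward = 25, S_neutral = 0),
    repertoire = c("B", "other"),
    params = learning_parameters(alpha_v, alpha_w, beta),
    v_prior = v_prior, w_prior = w_prior
  )
}

# softmax by the direct formula (no stabilisation): oracle for small values
softmax_oracle <- function(v, beta) exp(beta * v) / sum(exp(beta * v))

# exhaustive-enumeration oracle for ordered two-step successions over all
# non-empty compounds of k base elements
enumerate_successions <- function(k) {
  compounds <- list()
  for (m in seq_len(2^k - 1)) {
    compounds[[m]] <- which(intToBits(m)[1:k] == 1)
  }
  n <- 0L
  for (a in compounds) for (b in compounds) n <- n + 1L
  n
}

# exhaustive-enumeration oracle for behaviour sequences of length l
enumerate_behaviour_sequences <- function(n, l) {
  nrow(do.call(expand.grid, rep(list(seq_len(n)), l)))
}

# a deterministic one-state world: stimulus S, behaviour B rewarded,
# used for the trial-loop vs direct-update equivalence oracle
one_state_world <- function() {
  world_machine(
    states = list(
      enc = world_state(
        emissions = list(emission(1, "X", key = "enc")),
        transitions = list(
          "enc::B" = list(outcome(1, "S_reward", "end")),
          "enc::other" = list(outcome(1, "S_neutral", "end"))
        )
      ),
      end = world_state(terminal = TRUE)
    ),
    start = "enc"
  )
}

final_means <- function(traces, q) {
  df <- dplyr::filter(traces, .data$quantity == q)
  df <- dplyr::filter(dplyr::group_by(df, .data$arm),
                      .data$trial_index == max(.data$trial_index))
  dplyr::ungroup(df)
}

crossing_trial <- function(traces, arm, quantity, threshold = 0.5) {
  df <- traces[traces$arm == arm & traces$quantity == quantity, ]
  hit <- df$trial_index[df$mean > threshold]
  if (length(hit)) min(hit) else Inf
}
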