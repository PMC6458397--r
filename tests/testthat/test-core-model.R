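test_that("compound values sum over elements, with absent entries as zero", {
  mem <- tiny_memory()
  expect_identical(compound_v(mem, c("X", "Y"), "B"), 0)
  mem$v["X", "B"] <- 5
  expect_identical(compound_v(mem, "X", "B"), 5)
  mem$v["X", "B"] <- 3
  mem$v["Y", "B"] <- 4
  expect_identical(compound_v(mem, c("X", "Y"), "B"), 7)
  expect_identical(compound_v(mem, c("Y", "X"), "B"), 7)

  expect_identical(compound_total_value(mem, c("X", "Y")), 0)
  expect_identical(compound_total_value(mem, "S_reward"), 25)
  mem2 <- agent_memory(c(A = 2, B_el = -2), c("B", "other"),
                       w_prior = c(A = 1))
  expect_identical(compound_total_value(mem2, c("A", "B_el")), 1)

  expect_error(compound_v(mem, "nope", "B"), "unknown stimulus")
  expect_error(compound_v(mem, "X", "nope"), "unknown behaviour")
  expect_error(compound_total_value(mem, character()), "non-empty")
})

test_that("softmax response distribution is normalised, stable and matches the closed form", {
  mem <- tiny_memory()
  mem$v["X", "B"] <- 25
  d <- response_distribution(mem, "X")
  expect_equal(unname(d),
               c(1 / (1 + exp(-25)), exp(-25) / (1 + exp(-25))),
               tolerance = 1e-12)

  # beta = 0: all behaviours equally likely whatever the values
  mem0 <- tiny_memory(beta = 0)
  mem0$v["X", ] <- c(40, -3)
  expect_equal(unname(response_distribution(mem0, "X")), c(0.5, 0.5))

  # equal values: uniform at any beta
  mem_eq <- tiny_memory(beta = 3.7)
  mem_eq$v["X", ] <- c(2, 2)
  expect_equal(unname(response_distribution(mem_eq, "X")), c(0.5, 0.5))

  # extreme values do not overflow
  mem$v["X", "B"] <- 5000
  d_big <- response_distribution(mem, "X")
  expect_true(all(is.finite(d_big)))
  expect_equal(sum(d_big), 1, tolerance = 1e-12)

  expect_error(response_distribution(mem, "X", character()), "empty")
})

test_that("softmax properties hold on randomised memories", {
  set.seed(101)
  for (i in 1:200) {
    beta <- runif(1, 0, 3)
    mem <- tiny_memory(beta = beta)
    mem$v[] <- rnorm(length(mem$v), sd = 10)
    d <- response_distribution(mem, c("X", "Y"))
    expect_lt(abs(sum(d) - 1), 1e-12)
    expect_true(all(d >= 0))
    # invariant under element reordering of the compound
    expect_identical(d, response_distribution(mem, c("Y", "X")))
    # oracle: direct unstabilised formula
    v_sum <- mem$v["X", ] + mem$v["Y", ]
    expect_equal(unname(d), unname(softmax_oracle(v_sum, beta)),
                 tolerance = 1e-12)
  }
})

test_that("increasing beta strictly favours the argmax behaviour", {
  probs <- sapply(c(0, 0.5, 1, 2, 4), function(b) {
    mem <- tiny_memory(beta = b)
    mem$v["X", ] <- c(3, 1)
    response_distribution(mem, "X")[["B"]]
  })
  expect_true(all(diff(probs) > 0))
})

test_that("sample_behaviour is reproducible and matches its distribution", {
  expect_identical(sample_behaviour(c(B = 1, other = 0)), "B")
  set.seed(7)
  a <- replicate(20, sample_behaviour(c(B = 0.5, other = 0.5)))
  set.seed(7)
  b <- replicate(20, sample_behaviour(c(B = 0.5, other = 0.5)))
  expect_identical(a, b)
  set.seed(8)
  draws <- replicate(10000, sample_behaviour(c(B = 0.5, other = 0.5)))
  expect_lt(abs(mean(draws == "B") - 0.5), 0.02)
  expect_error(sample_behaviour(c(0.5, 0.5)), "named")
  expect_error(sample_behaviour(c(B = 0.7, other = 0.6)), "summing to 1")
})

test_that("apply_experience implements the error-correction update", {
  mem <- tiny_memory(alpha_w = 0)
  up <- apply_experience(mem, "X", "B", "S_reward")
  expect_equal(up$v["X", "B"], 2.5)          # 0.1 * (25 - 0)
  expect_identical(up$v["X", "other"], 0)    # non-performed response untouched

  # totally neutral consequence, zero memory: no change
  same <- apply_experience(mem, "X", "B", "S_neutral")
  expect_identical(same$v, mem$v)
  expect_identical(same$w, mem$w)

  # NULL consequence: episode ended with no outcome, no update
  expect_identical(apply_experience(mem, "X", "B", NULL)$v, mem$v)

  expect_error(apply_experience(mem, "X", "B", "nope"), "unknown stimulus")
})

test_that("repeated training follows the closed-form geometric approach to the reinforcer value", {
  mem <- tiny_memory(alpha_w = 0)
  v_path <- numeric(300)
  for (t in 1:300) {
    mem <- apply_experience(mem, "X", "B", "S_reward")
    v_path[t] <- mem$v["X", "B"]
  }
  expect_equal(v_path, 25 * (1 - 0.9^(1:300)), tolerance = 1e-12)
  # and with a nonzero start: |v_t - u| = |v_0 - u| * (1 - alpha_v)^t
  mem2 <- tiny_memory(alpha_w = 0,
                      v_prior = data.frame(element = "X", behaviour = "B",
                                           value = -5))
  for (t in 1:50) mem2 <- apply_experience(mem2, "X", "B", "S_reward")
  expect_equal(abs(mem2$v["X", "B"] - 25), 30 * 0.9^50, tolerance = 1e-12)
})

test_that("the w update ignores the performed behaviour (bitwise)", {
  set.seed(5)
  for (i in 1:20) {
    w0 <- c(X = rnorm(1), Y = rnorm(1))
    mem <- tiny_memory(w_prior = w0)
    mem$v[] <- rnorm(length(mem$v))
    up_b <- apply_experience(mem, c("X", "Y"), "B", "S_reward")
    up_o <- apply_experience(mem, c("X", "Y"), "other", "S_reward")
    expect_identical(up_b$w, up_o$w)
  }
})

test_that("a compound update gives every element the same delta", {
  mem <- tiny_memory(v_prior = data.frame(element = c("X", "Y"),
                                          behaviour = "B", value = c(2, 7)))
  before <- compound_v(mem, c("X", "Y"), "B")
  up <- apply_experience(mem, c("X", "Y"), "B", "S_reward")
  d_x <- up$v["X", "B"] - 2
  d_y <- up$v["Y", "B"] - 7
  expect_equal(d_x, d_y)
  expect_equal(d_x, 0.1 * (25 - before))
  expect_equal(compound_v(up, c("X", "Y"), "B") - before, 2 * d_x)
})

test_that("learned stimulus value feeds back as conditioned reinforcement", {
  # the v update uses the full total value u + w of the consequence, so a
  # stimulus with learned value reinforces a preceding response even with
  # zero innate value
  mem <- tiny_memory(w_prior = c(Y = 8))
  up <- apply_experience(mem, "X", "B", "Y")
  expect_equal(up$v["X", "B"], 0.1 * 8)
})

test_that("simultaneous update: all deltas use pre-update values", {
  # consequence shares an element with the stimulus: the w of the shared
  # element must enter the target at its old value
  mem <- agent_memory(c(P = 0, Q = -4), c("B", "other"),
                      w_prior = c(P = 2))
  up <- apply_experience(mem, "P", "B", c("P", "Q"))
  tot <- -4 + 2                      # u(Q) + w(P), pre-update
  expect_equal(up$v["P", "B"], 0.1 * (tot - 0))
  expect_equal(up$w[["P"]], 2 + 0.1 * (tot - 2))
})

test_that("observation updates stimulus values only", {
  mem <- tiny_memory()
  up <- apply_observation(mem, "Y", "S_reward")
  expect_identical(up$v, mem$v)
  expect_equal(up$w[["Y"]], 2.5)
})

test_that("memory construction validates priors and tidies to a long table", {
  expect_error(agent_memory(c(1, 2), c("B", "other")), "named")
  expect_error(agent_memory(c(X = 0), "B"), "two distinct behaviour")
  expect_error(
    agent_memory(c(X = 0), c("B", "other"),
                 v_prior = data.frame(element = "Z", behaviour = "B",
                                      value = 1)),
    "unknown stimulus"
  )
  mem <- tiny_memory(v_prior = data.frame(element = "X", behaviour = "B",
                                          value = 10))
  td <- tidy(mem)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$value[td$type == "v" & td$element == "X" &
                              td$behaviour == "B"], 10)
  expect_identical(nrow(td), 4L * 2L + 4L + 4L)
})
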