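# Scenario builders: initial conditions are asserted exactly; outcome signs
# are checked with reduced replicate counts (the full-scale figures are
# exercised by the acceptance suite).

test_that("succession and sequence counts match exhaustive enumeration", {
  expect_identical(count_successions(1), 1)
  expect_identical(count_successions(2), 9)
  expect_identical(count_successions(3), 49)
  for (k in 1:4) {
    expect_identical(count_successions(k), as.double(enumerate_successions(k)))
  }
  expect_identical(count_behaviour_sequences(1, 5), 1)
  expect_identical(count_behaviour_sequences(2, 3), 8)
  for (n in 1:4) for (l in 1:4) {
    expect_identical(count_behaviour_sequences(n, l),
                     as.double(enumerate_behaviour_sequences(n, l)))
  }
  expect_error(count_successions(0), "positive integer")
  expect_error(count_behaviour_sequences(2, 0), "positive integer")
})

test_that("builders start from their declared initial conditions", {
  sr <- build_social_response()
  m <- sr$arms$social$initial_memory
  expect_true(all(m$v == 0))
  expect_true(all(m$w == 0))
  expect_identical(m$u[["S_reward"]], 25)
  expect_identical(m$alpha_w, 0)
  expect_identical(sr$defaults$n_replicates, 1000)

  im <- build_imitation()
  expect_identical(im$repertoire, c("B1", "B2"))
  expect_true(all(im$arms$social$initial_memory$v == 0))
  expect_error(build_imitation(k = 1), "at least 2")

  tf <- build_transfer()
  expect_identical(tf$arms$social$initial_memory$v["S_social", "B1"], 10)
  expect_identical(tf$arms$individual$initial_memory$v["S_social", "B1"], 0)
  expect_true(all(tf$arms$individual$initial_memory$v == 0))

  tfi <- build_transfer(with_imitation_prior = TRUE)
  expect_identical(tfi$arms$imitating$initial_memory$v["[B1]", "B1"], 10)
  expect_true(all(tfi$arms$naive$initial_memory$v == 0))

  sq <- build_sequence()
  expect_identical(sq$arms$social$initial_memory$v["S_social", "B1"], 10)
  expect_identical(sq$arms$social$initial_memory$u[["S_reward"]], 25)
  expect_true(all(sq$arms$individual$initial_memory$v == 0))
  expect_identical(sq$arms$social$initial_memory$alpha_w, 0.1)

  av <- build_avoidance()
  m_av <- av$arms$social$initial_memory
  expect_identical(m_av$u[["S_warning"]], -10)
  expect_identical(m_av$u[["S_predator"]], 0)
  expect_true(all(m_av$v == 0))
  expect_true(all(m_av$w == 0))
  expect_identical(av$defaults$n_replicates, 2000)
})

test_that("a response to a social stimulus is acquired while the unrewarded response is not", {
  sc <- build_social_response()
  tr <- run_replicates(sc, n_replicates = 150, seed = 17)
  expect_equal(tr$mean[tr$trial_index == 0 & tr$quantity == "p:S_social->B"],
               0.5)
  fin <- glance(tr)
  expect_gt(fin$`v:S_social->B`, 5)          # strongly positive outcome
  expect_gt(fin$`v:S_social->B`, 24)         # approaches the reinforcer value
  expect_lt(abs(fin$`v:S_social->other`), 0.5)
  expect_gt(fin$`p:S_social->B`, 0.95)
})

test_that("imitation is acquired, starting from symmetric responding", {
  sc <- build_imitation()
  tr <- run_replicates(sc, n_replicates = 150, n_trials = 250, seed = 19)
  expect_equal(tr$mean[tr$trial_index == 0 & tr$quantity == "p:[B1]->B1"],
               0.5)
  fin <- glance(tr)
  expect_gt(fin$`p:[B1]->B1`, 0.9)
  expect_gt(fin$`v:[B1]->B1`, 5)
  expect_lt(abs(fin$`v:[B1]->B2`), 1)
})

test_that("larger repertoires slow the acquisition of imitation", {
  trials_to_threshold <- function(k) {
    sc <- build_imitation(k = k)
    tr <- run_replicates(sc, n_replicates = 150, n_trials = 200, seed = 29)
    crossing_trial(tr, "social", "p:[B1]->B1", 0.75)
  }
  t2 <- trials_to_threshold(2)
  t5 <- trials_to_threshold(5)
  expect_lt(t2, t5)
})

test_that("social exposure speeds transfer to the non-social stimulus", {
  sc <- build_transfer()
  tr <- run_replicates(sc, n_replicates = 400, seed = 23)
  fin <- final_means(tr, "p:S_x->B1")
  p_soc <- fin$mean[fin$arm == "social"]
  p_ind <- fin$mean[fin$arm == "individual"]
  se <- sqrt(sum(fin$stderr^2))
  expect_gt(p_soc - p_ind, 3 * se)
  # outcome column: responding to S_x alone is strongly positive in both arms
  v_fin <- final_means(tr, "v:S_x->B1")
  expect_true(all(v_fin$mean > 5))
})

test_that("with no compound encounters the social prior is inert and the arms coincide", {
  sc <- build_transfer(p_social = 0)
  tr <- run_replicates(sc, n_replicates = 200, seed = 27)
  # the social element is never encountered: its prior stays exactly 10
  v_soc <- tr[tr$arm == "social" & tr$quantity == "v:S_social->B1", ]
  expect_true(all(v_soc$mean == 10))
  fin <- final_means(tr, "p:S_x->B1")
  diff <- abs(diff(fin$mean))
  se <- sqrt(sum(fin$stderr^2))
  expect_lt(diff, 4 * se + 1e-6)
})

test_that("sequence learning chains backward alone but forward with social support", {
  sc <- build_sequence()
  tr <- run_replicates(sc, n_replicates = 250, seed = 31)
  # individual arm: second link crosses before the first (backward chaining)
  expect_lt(crossing_trial(tr, "individual", "p_step2"),
            crossing_trial(tr, "individual", "p_step1"))
  # social arm: the social prior carries the first link from the start
  expect_lt(crossing_trial(tr, "social", "p_step1"),
            crossing_trial(tr, "social", "p_step2"))
  # conditioned reinforcement accrues on the intermediate stimulus
  fin_w <- final_means(tr, "w:S_y")
  expect_gt(fin_w$mean[fin_w$arm == "social"], 5)
  # v outcomes of the chain
  fin_v1 <- final_means(tr, "v:S_x->B1")
  expect_true(all(fin_v1$mean > 5))
})

test_that("without conditioned reinforcement the unrewarded first link decays", {
  # w learning disabled and no social support: even an agent that already
  # knows the first link loses it, because that step never pays primarily
  # and the intermediate stimulus cannot acquire conditioned value
  sc_nw <- build_sequence()
  sc_nw$arms$individual$initial_memory$alpha_w <- 0
  sc_nw$arms$individual$initial_memory$v["S_x", "B1"] <- 10
  tr_nw <- run_replicates(sc_nw, n_replicates = 150, n_trials = 80, seed = 37,
                          arms = "individual")
  v_path <- tr_nw$mean[tr_nw$quantity == "v:S_x->B1"]
  expect_equal(v_path[1], 10)
  expect_lt(v_path[length(v_path)], 1)
  p_path <- tr_nw$mean[tr_nw$quantity == "p_full_sequence"]
  expect_gt(max(p_path), p_path[length(p_path)] + 0.2)
  # with w learning on, the same solitary agent consolidates instead
  sc <- build_sequence()
  tr_full <- run_replicates(sc, n_replicates = 150, n_trials = 80, seed = 37,
                            arms = "individual")
  expect_gt(final_means(tr_full, "v:S_x->B1")$mean, 5)
})

test_that("warning calls transmit predator avoidance faster than solitary experience", {
  sc <- build_avoidance()
  tr <- run_replicates(sc, n_replicates = 300, seed = 41)
  fin <- final_means(tr, "p_escape")
  p_soc <- fin$mean[fin$arm == "social"]
  p_ind <- fin$mean[fin$arm == "individual"]
  expect_gt(p_soc - p_ind, 3 * sqrt(sum(fin$stderr^2)))
  # Table 1 outcomes: predator acquires negative value and ignoring is devalued
  fin_w <- final_means(tr, "w:S_predator")
  expect_lt(fin_w$mean[fin_w$arm == "social"], -1)
  fin_v <- final_means(tr, "v:S_predator->B_ignore")
  expect_lt(fin_v$mean[fin_v$arm == "social"], -1)
  # injury-risk proxy declines fastest with warning calls
  risk <- final_means(tr, "p_ignore_throughout")
  expect_lt(risk$mean[risk$arm == "social"], risk$mean[risk$arm == "individual"])
})

test_that("the heterospecific call inherits the conspecific warning value", {
  sc <- build_avoidance(heterospecific_call = TRUE)
  tr <- run_replicates(sc, n_replicates = 100, seed = 43, arms = "social")
  fin <- final_means(tr, "w:S_x")
  expect_lt(abs(fin$mean - (-10)), 0.5)
})
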