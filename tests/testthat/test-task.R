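test_that("reversal criterion fires on 8-of-window correct choices", {
  expect_true(check_reversal(rep(TRUE, 8)))
  expect_false(check_reversal(c(rep(TRUE, 7), FALSE)))
  expect_false(check_reversal(logical(0)))
  expect_false(check_reversal(rep(TRUE, 7)))
  ## window caps at 10: 8 correct spread over the last 10 fire, over 11 don't
  expect_true(check_reversal(c(FALSE, rep(TRUE, 8), FALSE, TRUE)))
  expect_false(check_reversal(c(rep(TRUE, 4), rep(FALSE, 3), rep(TRUE, 4))))
})

test_that("reversal criterion agrees with a brute-force window counter", {
  set.seed(101)
  for (rep in 1:200) {
    len <- sample.int(15, 1)
    seq_ <- stats::runif(len) < 0.7
    expect_identical(check_reversal(seq_), bf_window_fires(seq_))
  }
})

test_that("outcome schedule matches the 85/15 split within 3 binomial SE", {
  n <- 10000
  se3 <- 3 * sqrt(0.85 * 0.15 / n)
  cfg <- task_config()
  set.seed(11)
  state <- init_task_state("left")
  out_correct <- character(n)
  for (i in seq_len(n)) {
    st <- step_environment(state, state$rewarded_side, cfg)
    out_correct[i] <- st$outcome
    state <- st$state
  }
  expect_lt(abs(mean(out_correct == "reward") - 0.85), se3)
  expect_lt(abs(mean(out_correct == "none") - 0.15), se3)

  state <- init_task_state("left")
  out_wrong <- character(n)
  for (i in seq_len(n)) {
    wrong <- if (state$rewarded_side == "left") "right" else "left"
    st <- step_environment(state, wrong, cfg)
    out_wrong[i] <- st$outcome
    state <- st$state
  }
  expect_lt(abs(mean(out_wrong == "punish") - 0.85), se3)
})

test_that("degenerate p_outcome = 1 always rewards correct choices", {
  cfg <- task_config(p_outcome = 1)
  state <- init_task_state("left")
  set.seed(1)
  outs <- replicate(20, {
    st <- step_environment(state, state$rewarded_side, cfg)
    state <<- st$state
    st$outcome
  })
  expect_true(all(outs == "reward"))
})

test_that("simulated sessions replay to identical block boundaries", {
  for (seed in c(1, 2, 3)) {
    s <- simulate_session(400, "qforget",
                          list(alpha = 0.6, beta = 5, phi = 0.2), seed = seed)
    expect_identical(s$trials$block_index, bf_replay_blocks(s))
    expect_true(all(diff(s$trials$block_index) >= 0))
  }
  ## omission trials must not enter the reversal window
  s_om <- simulate_session(400, "qforget",
                           list(alpha = 0.6, beta = 5, phi = 0.2),
                           config = task_config(p_omission = 0.1), seed = 4)
  expect_gt(sum(s_om$trials$choice == "omission"), 0)
  expect_identical(s_om$trials$block_index, bf_replay_blocks(s_om))
})

test_that("trial records satisfy their structural invariants", {
  s <- simulate_session(300, "qforget",
                        list(alpha = 0.6, beta = 5, phi = 0.2),
                        config = task_config(p_omission = 0.05), seed = 9)
  tr <- s$trials
  done <- tr$choice %in% c("left", "right")
  expect_true(all(tr$t_cue[done] < tr$t_init[done]))
  expect_true(all(tr$t_init[done] < tr$t_choice[done]))
  expect_true(all(tr$t_choice[done] < tr$t_outcome[done]))
  expect_true(all(tr$choice[tr$outcome == "reward"] ==
                    tr$rewarded_side[tr$outcome == "reward"]))
  expect_true(all(tr$choice[tr$outcome == "punish"] !=
                    tr$rewarded_side[tr$outcome == "punish"]))
  expect_true(all(is.na(tr$t_choice[!done])))
})

test_that("identical (params, config, seed) reproduce the session exactly", {
  a <- simulate_session(200, "qforget",
                        list(alpha = 0.5, beta = 3, phi = 0.1), seed = 77)
  b <- simulate_session(200, "qforget",
                        list(alpha = 0.5, beta = 3, phi = 0.1), seed = 77)
  expect_identical(a$trials, b$trials)
})

test_that("a random agent picks each side about half the time", {
  s <- simulate_session(2000, "random", seed = 5)
  p_right <- mean(s$trials$choice == "right")
  expect_lt(abs(p_right - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("correct-choice fraction grows with the inverse temperature", {
  ## assessed under a fixed contingency: with reversals active, stronger
  ## exploitation reaches the 8-of-10 criterion sooner and triggers more
  ## block switches, which genuinely caps (and can slightly lower) the raw
  ## correct fraction at high beta
  cfg <- task_config(switch_n_correct = 250, switch_window = 250)
  betas <- c(0, 1, 3, 10)
  mean_correct <- sapply(betas, function(b) {
    mean(sapply(1:20, function(seed) {
      s <- simulate_session(250, "qforget",
                            list(alpha = 0.6, beta = b, phi = 0.2),
                            config = cfg, seed = 1000 + seed)
      tr <- s$trials
      mean(tr$choice == tr$rewarded_side)
    }))
  })
  expect_true(all(diff(mean_correct) >= 0))
  expect_lt(abs(mean_correct[1] - 0.5), 0.05)  # beta = 0: coin flips
  expect_gt(mean_correct[4], 0.9)
})

test_that("unknown policies and invalid parameters are rejected", {
  expect_error(simulate_session(10, "qforget", list(alpha = 0.5)),
               "requires agent_params")
  expect_error(simulate_session(10, "qforget",
                                list(alpha = 2, beta = 1, phi = 0)),
               "alpha")
  expect_error(check_agent_params("bandit", list()), "unknown policy")
  expect_error(step_environment(init_task_state(), "omission"),
               "left.*right")
  expect_error(task_config(p_outcome = 0), "p_outcome")
  expect_error(task_config(switch_n_correct = 11), "switch_n_correct")
})

test_that("light-trial assignment marks the requested fraction reproducibly", {
  s <- simulate_session(1000, "random", seed = 3)
  none <- assign_light_trials(s, fraction = 0, seed = 1)
  expect_false(any(none$trials$light_on))
  all_on <- assign_light_trials(s, fraction = 1, epoch = "outcome", seed = 1)
  expect_true(all(all_on$trials$light_on))
  expect_true(all(all_on$trials$light_epoch == "outcome"))
  a <- assign_light_trials(s, fraction = 0.3, seed = 42)
  b <- assign_light_trials(s, fraction = 0.3, seed = 42)
  expect_identical(a$trials, b$trials)
  expect_identical(sum(a$trials$light_on), 300L)
})
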