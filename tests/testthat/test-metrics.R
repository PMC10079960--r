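test_that("stay probabilities match exhaustive enumeration", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    s <- make_hand_session(
      choice = sample(c("left", "right"), n, TRUE),
      outcome = sample(c("reward", "punish", "none"), n, TRUE),
      light_on = sample(c(TRUE, FALSE), n, TRUE)
    )
    for (cond in c("all", "light_on", "light_off")) {
      st <- stay_probabilities(s, condition = cond)
      expect_equal(unname(st$counts), unname(bf_stay_counts(s, cond)))
    }
  }
})

test_that("stay extremes behave as expected", {
  ## alternating choices, all rewarded: never a win-stay
  alt <- make_hand_session(rep(c("left", "right"), 6), rep("reward", 12))
  expect_equal(stay_probabilities(alt)$p_winstay, 0)
  ## perseveration: always stay, win or lose
  per <- make_hand_session(rep("left", 12),
                           rep(c("reward", "none"), 6))
  st <- stay_probabilities(per)
  expect_equal(st$p_winstay, 1)
  expect_equal(st$p_losestay, 1)
  ## empty cell reported as NA, not 0
  all_win <- make_hand_session(rep("left", 6), rep("reward", 6))
  expect_true(is.na(stay_probabilities(all_win)$p_losestay))
  ## omissions are skipped: the previous COMPLETED trial is the reference
  om <- make_hand_session(c("left", "omission", "left", "right"),
                          c("reward", "none", "reward", "none"))
  st_om <- stay_probabilities(om)
  expect_equal(unname(st_om$counts),
                   c(1, 1, 0, 0))  # (L->L win-stay), (L->R win-shift)
})

test_that("relative reward stay evaluates the log odds ratio", {
  expect_equal(round(relative_reward_stay(c(0.85, 0.5)), 4), 1.7346,
               ignore_attr = TRUE)
  expect_equal(relative_reward_stay(c(0.3, 0.3)), 0, ignore_attr = TRUE)
  ## antisymmetric under swapping the two probabilities
  expect_equal(relative_reward_stay(c(0.8, 0.4)),
               -relative_reward_stay(c(0.4, 0.8)), ignore_attr = TRUE)
  expect_error(relative_reward_stay(c(1, 0.5)), "strictly")
  ## degenerate cells get the 0.5-count correction and are flagged
  per <- make_hand_session(rep("left", 12), rep(c("reward", "none"), 6))
  rrs <- relative_reward_stay(stay_probabilities(per))
  expect_true(attr(rrs, "corrected"))
  expect_true(is.finite(rrs))
  ## a reward-sensitive simulated agent passes the >2 training criterion
  s <- simulate_session(500, "qforget",
                        list(alpha = 0.7, beta = 8, phi = 0.3), seed = 17)
  expect_gt(relative_reward_stay(stay_probabilities(s)), 2)
})

test_that("light contrasts match enumeration on a hand-built session", {
  set.seed(19)
  n <- 20
  s <- make_hand_session(
    choice = sample(c("left", "right"), n, TRUE),
    outcome = sample(c("reward", "none"), n, TRUE),
    light_on = rep(c(TRUE, FALSE), 10)
  )
  d <- delta_stay(s)
  on <- bf_stay_counts(s, "light_on")
  off <- bf_stay_counts(s, "light_off")
  expect_equal(d$delta_winstay,
               on[["win_stay"]] / sum(on[1:2]) -
                 off[["win_stay"]] / sum(off[1:2]))
  expect_equal(d$delta_losestay,
               on[["lose_stay"]] / sum(on[3:4]) -
                 off[["lose_stay"]] / sum(off[3:4]))
})

test_that("null light assignment gives stay contrasts within sampling error", {
  ## light delivered at random to a light-insensitive agent: pooled contrast
  ## over 50 replicate sessions must sit within 3 SE of zero
  sessions <- lapply(1:50, function(i) {
    s <- simulate_session(120, "qforget",
                          list(alpha = 0.6, beta = 5, phi = 0.2),
                          seed = 5000 + i)
    assign_light_trials(s, fraction = 0.3, seed = 6000 + i)
  })
  d <- delta_stay(sessions)
  se_ws <- sqrt(
    d$on$p_winstay * (1 - d$on$p_winstay) / sum(d$on$counts[1:2]) +
      d$off$p_winstay * (1 - d$off$p_winstay) / sum(d$off$counts[1:2])
  )
  se_ls <- sqrt(
    d$on$p_losestay * (1 - d$on$p_losestay) / sum(d$on$counts[3:4]) +
      d$off$p_losestay * (1 - d$off$p_losestay) / sum(d$off$counts[3:4])
  )
  expect_lt(abs(d$delta_winstay), 3 * se_ws)
  expect_lt(abs(d$delta_losestay), 3 * se_ls)
})

test_that("an injected light effect shows up in the lose-stay contrast", {
  ## simulate a lose-shift bias after light-ON trials by editing choices:
  ## after an unrewarded ON trial the agent always shifts
  set.seed(23)
  sessions <- lapply(1:10, function(i) {
    s <- simulate_session(200, "qforget",
                          list(alpha = 0.6, beta = 5, phi = 0.2),
                          seed = 7000 + i)
    s <- assign_light_trials(s, fraction = 0.4, seed = 7100 + i)
    tr <- s$trials
    for (t in 2:nrow(tr)) {
      if (tr$light_on[t - 1] && tr$outcome[t - 1] != "reward" &&
          stats::runif(1) < 0.8) {
        tr$choice[t] <- if (tr$choice[t - 1] == "left") "right" else "left"
        tr$outcome[t] <- "none"
      }
    }
    s$trials <- tr
    s
  })
  d <- delta_stay(sessions)
  expect_lt(d$delta_losestay, 0)
})

test_that("local reward rate follows the window arithmetic", {
  ## 5 prior trials spanning 60 s with 3 rewards of 12 uL -> 36 uL/min
  s <- make_hand_session(
    choice = rep("left", 6),
    outcome = c("reward", "none", "reward", "none", "reward", "none"),
    t_cue = seq(0, 60, by = 12)
  )
  rate <- local_reward_rate(s, window = 5)
  expect_equal(rate[6], 3 * 12 / 1)
  expect_false(attr(rate, "partial")[6])
  expect_true(all(attr(rate, "partial")[1:5]))
  ## no rewards -> zero
  s0 <- make_hand_session(rep("left", 6), rep("none", 6))
  expect_equal(unname(local_reward_rate(s0, 5)), rep(0, 6),
               ignore_attr = TRUE)
  ## doubling the window time halves the rate
  s2 <- make_hand_session(
    choice = rep("left", 6),
    outcome = c("reward", "none", "reward", "none", "reward", "none"),
    t_cue = seq(0, 120, by = 24)
  )
  expect_equal(local_reward_rate(s2, 5)[6], rate[6] / 2)
  expect_error(local_reward_rate(s, window = 0), "window")
})

test_that("engagement metrics normalise trials and recover latencies", {
  a <- simulate_session(300, "random", seed = 31)
  expect_equal(engagement_metrics(a, a)$trials_normalized, 1)
  half <- a
  half$trials <- a$trials[1:150, ]
  expect_equal(engagement_metrics(half, a)$trials_normalized, 0.5)
  ## generator truth: latency = hold + lognormal(log median, sdlog)
  cfg <- task_config()
  sessions <- lapply(1:20, function(i) simulate_session(200, "random",
                                                        seed = 800 + i))
  em <- engagement_metrics(sessions, sessions)
  expected <- cfg$hold + cfg$latency_init * exp(cfg$latency_sdlog^2 / 2)
  expect_lt(abs(em$initiation_latency - expected), 0.02)
})
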