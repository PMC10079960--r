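# Shared fixtures and independent oracles used across the test files.

## Build a session object from explicit trial vectors (hand-built sessions
## for metric oracles). Timestamps default to a regular 10-s trial grid.
make_hand_session <- function(choice, outcome,
                              rewarded_side = rep("left", length(choice)),
                              t_cue = (seq_along(choice) - 1) * 10,
                              light_on = rep(FALSE, length(choice)),
                              light_epoch = ifelse(light_on, "choice", "na"),
                              config = task_config(),
                              hemisphere = "left") {
  n <- length(choice)
  completed <- choice != "omission"
  trials <- data.frame(
    session_id = "hand", animal_id = "hand",
    trial_index = seq_len(n), block_index = 1L,
    rewarded_side = rewarded_side, choice = choice, outcome = outcome,
    t_cue = t_cue,
    t_init = t_cue + 1,
    t_choice = ifelse(completed, t_cue + 2, NA_real_),
    t_outcome = ifelse(completed, t_cue + 2.5, NA_real_),
    light_on = light_on, light_epoch = light_epoch,
    stringsAsFactors = FALSE
  )
  structure(list(trials = trials, config = config, seed = NA_integer_,
                 policy = "hand", agent_params = list(),
                 hemisphere = hemisphere),
            class = "bandit_session")
}

## Brute-force sliding-window reversal counter: counts correct choices in
## the last min(elapsed, window) block trials by explicit enumeration.
bf_window_fires <- function(block_choices, n_correct = 8, window = 10) {
  len <- length(block_choices)
  if (len == 0) return(FALSE)
  k <- min(len, window)
  cnt <- 0
  for (i in (len - k + 1):len) cnt <- cnt + as.integer(block_choices[i])
  cnt >= n_correct
}

## Replay a simulated session's completed choices through the naive counter
## and return the block index sequence it implies.
bf_replay_blocks <- function(session) {
  tr <- session$trials
  blocks <- integer(nrow(tr))
  blk <- 1L
  win <- logical(0)
  for (i in seq_len(nrow(tr))) {
    blocks[i] <- blk
    if (!tr$choice[i] %in% c("left", "right")) next
    win <- c(win, tr$choice[i] == tr$rewarded_side[i])
    if (bf_window_fires(win, session$config$switch_n_correct,
                        session$config$switch_window)) {
      blk <- blk + 1L
      win <- logical(0)
    }
  }
  blocks
}

## Exhaustive stay/shift enumeration over consecutive completed-trial pairs.
bf_stay_counts <- function(session, condition = "all", epoch = "any") {
  tr <- session$trials
  tr <- tr[tr$choice %in% c("left", "right"), ]
  cts <- c(win_stay = 0, win_shift = 0, lose_stay = 0, lose_shift = 0)
  for (i in 2:nrow(tr)) {
    prev <- tr[i - 1, ]
    ok <- switch(condition,
      all = TRUE,
      light_on = prev$light_on && (epoch == "any" || prev$light_epoch == epoch),
      light_off = !prev$light_on
    )
    if (!ok) next
    win <- prev$outcome == "reward"
    stay <- tr$choice[i] == prev$choice
    key <- paste0(if (win) "win" else "lose", "_", if (stay) "stay" else "shift")
    cts[key] <- cts[key] + 1
  }
  cts
}

## Cox-de Boor recursion: independent B-spline evaluation oracle.
bf_bspline <- function(knots, x, k = 4) {
  n_basis <- length(knots) - k
  B <- matrix(0, length(x), length(knots) - 1)
  for (i in seq_len(length(knots) - 1)) {
    B[, i] <- as.numeric(x >= knots[i] & x < knots[i + 1])
  }
  ## right-closed support at the final boundary knot
  hi <- max(knots)
  last_pos <- max(which(knots < hi))
  B[x == hi, last_pos] <- 1
  for (ord in 2:k) {
    Bn <- matrix(0, length(x), length(knots) - ord)
    for (i in seq_len(length(knots) - ord)) {
      d1 <- knots[i + ord - 1] - knots[i]
      d2 <- knots[i + ord] - knots[i + 1]
      t1 <- if (d1 > 0) (x - knots[i]) / d1 * B[, i] else 0
      t2 <- if (d2 > 0) (knots[i + ord] - x) / d2 * B[, i + 1] else 0
      Bn[, i] <- t1 + t2
    }
    B <- Bn
  }
  B[, seq_len(n_basis), drop = FALSE]
}

## Exhaustive ECDF-difference scan: two-sample KS statistic by brute force.
bf_ks_statistic <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

## Small deterministic session + latents + trace bundle for encoding tests.
make_encoding_fixture <- function(n_trials = 60, seed = 11,
                                  tuned = list(o_plus = list(shape = "brief",
                                                             amplitude = 1)),
                                  noise_sigma = 0, frame_rate = 20) {
  s <- simulate_session(n_trials, "qforget",
                        list(alpha = 0.6, beta = 5, phi = 0.2), seed = seed)
  ## latents from the generative parameters themselves (no fit needed)
  lat <- q_trajectory(choice_series(s), list(alpha = 0.6, beta = 5, phi = 0.2))
  hv <- synthesize_head_velocity(s, seed = seed + 2)
  truth <- sample_ground_truth(tuned = tuned, noise_sigma = noise_sigma,
                               seed = seed + 3)
  trace <- synthesize_trace(s, truth, latents = lat,
                            head_velocity = hv, frame_rate = frame_rate,
                            seed = seed + 4)
  design <- build_design_matrix(s, trace$frame_times, latents = lat,
                                head_velocity = hv)
  list(session = s, latents = lat, hv = hv, truth = truth,
       trace = trace, design = design)
}
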