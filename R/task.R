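#' Task configuration for the serial-reversal 2AFC task
#'
#' Bundles the parameters of the two-alternative forced-choice serial-reversal
#' task: probabilistic outcome delivery, the moving-window reversal rule and
#' the trial timing protocol. Defaults reproduce the standard protocol:
#' rewarded/punished outcomes delivered with 85% probability (no outcome
#' otherwise), 12 uL reward volume, and a contingency switch once 8 of the
#' last 10 completed choices in the current block were to the rewarded port.
#'
#' @param p_outcome probability that a correct choice is rewarded and an
#'   incorrect choice is punished; the complement yields no outcome.
#' @param reward_volume reward volume per rewarded trial (uL).
#' @param switch_n_correct number of correct choices within `switch_window`
#'   that triggers a contingency switch.
#' @param switch_window length (trials) of the moving reversal window.
#' @param choice_window time allowed to register a side choice (s).
#' @param outcome_delay delay between choice and outcome (s).
#' @param iti inter-trial interval (s).
#' @param hold center-port holding period required to start a trial (s).
#' @param timeout_punish timeout following punishment or omission (s).
#' @param p_omission probability that a trial ends in an omission (no choice
#'   registered). Omissions are excluded from the reversal window and from all
#'   stay/likelihood computations.
#' @param latency_init median latency from cue to initiation poke (s); trial
#'   timing latencies are drawn from log-normal distributions.
#' @param latency_choice median latency from side-port illumination to choice
#'   poke (s).
#' @param latency_sdlog log-scale standard deviation of the latency
#'   distributions.
#' @return an object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config()
#' cfg$p_outcome
#' @export
task_config <- function(p_outcome = 0.85, reward_volume = 12,
                        switch_n_correct = 8, switch_window = 10,
                        choice_window = 3, outcome_delay = 0.5,
                        iti = 3, hold = 0.5, timeout_punish = 3,
                        p_omission = 0,
                        latency_init = 0.3, latency_choice = 0.5,
                        latency_sdlog = 0.4) {
  cfg <- list(
    p_outcome = p_outcome, reward_volume = reward_volume,
    switch_n_correct = as.integer(switch_n_correct),
    switch_window = as.integer(switch_window),
    choice_window = choice_window, outcome_delay = outcome_delay,
    iti = iti, hold = hold, timeout_punish = timeout_punish,
    p_omission = p_omission,
    latency_init = latency_init, latency_choice = latency_choice,
    latency_sdlog = latency_sdlog
  )
  if (!(cfg$p_outcome > 0 && cfg$p_outcome <= 1)) {
    stop("p_outcome must be in (0, 1]", call. = FALSE)
  }
  if (cfg$switch_n_correct > cfg$switch_window) {
    stop("switch_n_correct must not exceed switch_window", call. = FALSE)
  }
  durs <- c(cfg$choice_window, cfg$outcome_delay, cfg$iti, cfg$hold,
            cfg$timeout_punish)
  if (any(durs < 0)) stop("durations must be >= 0", call. = FALSE)
  if (cfg$p_omission < 0 || cfg$p_omission > 1) {
    stop("p_omission must be in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "task_config"
  cfg
}

#' Does the current block's choice history trigger a contingency switch?
#'
#' The rewarded side switches when at least `n_correct` of the last
#' `window` completed choices of the current block were to the currently
#' rewarded port. The window resets at each switch, so it never spans blocks;
#' with fewer than `window` trials elapsed, the criterion is evaluated over
#' the trials available (8 consecutive correct choices from block start are
#' therefore sufficient).
#'
#' @param block_choices logical vector (`TRUE` = correct) of the completed
#'   choices of the current block, in trial order.
#' @param n_correct,window the reversal rule (default 8 of the last 10).
#' @return `TRUE` if the reversal criterion fires; `FALSE` for an empty
#'   history.
#' @examples
#' check_reversal(rep(TRUE, 8))                 # fires at block trial 8
#' check_reversal(c(rep(TRUE, 7), FALSE))       # 7 of 8: does not fire
#' @export
check_reversal <- function(block_choices, n_correct = 8, window = 10) {
  if (length(block_choices) == 0L) return(FALSE)
  if (!is.logical(block_choices)) {
    block_choices <- block_choices %in% c("correct", "TRUE", "1")
  }
  k <- min(length(block_choices), window)
  tail_choices <- block_choices[(length(block_choices) - k + 1L):length(block_choices)]
  sum(tail_choices) >= n_correct
}

#' Deliver one probabilistic outcome and update the task state
#'
#' A choice of the rewarded side yields `"reward"` with probability
#' `p_outcome` and `"none"` otherwise; the other side yields `"punish"` with
#' probability `p_outcome` and `"none"` otherwise. After the outcome is
#' assigned the completed choice is appended to the block's reversal window
#' and the reversal criterion is checked; if it fires, the rewarded side
#' flips, the block index increments and the window resets.
#'
#' Draws from the current RNG stream; seed with [set.seed()] (or rely on
#' [simulate_session()], which seeds per session).
#'
#' @param state task state as returned by [init_task_state()] or a previous
#'   call: a list with `rewarded_side`, `block_index` and `block_correct`.
#' @param choice `"left"` or `"right"`.
#' @param config a [task_config()].
#' @return list with `outcome` (`"reward"`, `"punish"` or `"none"`),
#'   `correct` (logical) and the updated `state`.
#' @export
step_environment <- function(state, choice, config = task_config()) {
  if (!choice %in% c("left", "right")) {
    stop("choice must be 'left' or 'right' (omissions are handled upstream)",
         call. = FALSE)
  }
  correct <- identical(choice, state$rewarded_side)
  deliver <- stats::runif(1) < config$p_outcome
  outcome <- if (correct) {
    if (deliver) "reward" else "none"
  } else {
    if (deliver) "punish" else "none"
  }
  state$block_correct <- c(state$block_correct, correct)
  if (check_reversal(state$block_correct,
                     n_correct = config$switch_n_correct,
                     window = config$switch_window)) {
    state$rewarded_side <- if (state$rewarded_side == "left") "right" else "left"
    state$block_index <- state$block_index + 1L
    state$block_correct <- logical(0)
  }
  list(outcome = outcome, correct = correct, state = state)
}

#' Initialise the task state
#'
#' @param rewarded_side side rewarded in the first block.
#' @return a task state list for [step_environment()].
#' @export
init_task_state <- function(rewarded_side = "left") {
  list(rewarded_side = rewarded_side, block_index = 1L,
       block_correct = logical(0))
}

## One softmax choice probability P(A) = 1/(1+exp(-beta*(Q_A-Q_B))),
## overflow-safe. Exported from the choice-model file's docs.
#' Softmax choice probability
#'
#' Probability of choosing option A under the softmax decision rule
#' `P_A = 1 / (1 + exp(-beta * (Q_A - Q_B)))`, overflow-safe for extreme
#' `beta * dQ`.
#'
#' @param dq value difference `Q_A - Q_B` (vectorised).
#' @param beta inverse temperature (>= 0).
#' @return probability of choosing A.
#' @examples
#' softmax_p(0.5, 3)   # 0.8176
#' softmax_p(0, 10)    # 0.5
#' @export
softmax_p <- function(dq, beta) {
  if (any(beta < 0)) stop("beta must be >= 0", call. = FALSE)
  plogis_safe(beta * dq)
}

#' Simulate a session of the serial-reversal task
#'
#' Runs a reward-sensitive agent through the probabilistic serial-reversal
#' task and returns a complete session: one row per trial with event
#' timestamps, choice, outcome, block identity and (initially off) light
#' flags. Inter-event intervals are drawn from log-normal distributions with
#' medians set by the task protocol's fixed delays plus typical animal
#' latencies.
#'
#' Available policies:
#' \describe{
#'   \item{`"qforget"`}{Q-learning with forgetting: the chosen port's value
#'     updates as `Q <- Q + alpha * (R - Q)`; the unchosen port decays as
#'     `Q <- Q * (1 - phi)`; choices are softmax in `beta * (Q_right -
#'     Q_left)`. `agent_params = list(alpha, beta, phi)`.}
#'   \item{`"wsls"`}{win-stay/lose-shift with lapse rate `epsilon`: with
#'     probability `epsilon` the choice is uniform random, otherwise the
#'     previous completed choice is repeated after a reward and flipped
#'     otherwise. `agent_params = list(epsilon)`.}
#'   \item{`"random"`}{unbiased coin flips; no parameters.}
#' }
#'
#' @param n_trials number of trials (>= 1).
#' @param policy `"qforget"`, `"wsls"` or `"random"`.
#' @param agent_params named list of policy parameters (see Details).
#' @param config a [task_config()].
#' @param seed integer seed; the same (policy, params, config, seed) always
#'   reproduces the identical session.
#' @param first_rewarded_side rewarded side of block 1.
#' @param hemisphere recording hemisphere label (`"left"` or `"right"`),
#'   used downstream to map choice sides to ipsi/contra.
#' @param session_id,animal_id identifier strings carried into trial tables.
#' @return an object of class `bandit_session`: a list with `trials` (a
#'   data.frame of trial records), `config`, `seed`, `policy`,
#'   `agent_params` and `hemisphere`.
#' @examples
#' s <- simulate_session(200, policy = "qforget",
#'                       agent_params = list(alpha = 0.6, beta = 5, phi = 0.2),
#'                       seed = 1)
#' head(s$trials)
#' @export
simulate_session <- function(n_trials, policy = c("qforget", "wsls", "random"),
                             agent_params = list(), config = task_config(),
                             seed = NULL, first_rewarded_side = "left",
                             hemisphere = "left",
                             session_id = "sim", animal_id = "agent") {
  policy <- match.arg(policy)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  check_agent_params(policy, agent_params)
  with_seed(seed, {
    state <- init_task_state(first_rewarded_side)
    q <- c(left = 0, right = 0)
    prev_choice <- NA_character_
    prev_reward <- NA
    n <- n_trials
    trial_index <- seq_len(n)
    block_index <- integer(n)
    rewarded_side <- character(n)
    choice <- character(n)
    outcome <- character(n)
    t_cue <- t_init <- t_choice <- t_outcome <- rep(NA_real_, n)
    clock <- 0
    for (t in seq_len(n)) {
      block_index[t] <- state$block_index
      rewarded_side[t] <- state$rewarded_side
      t_cue[t] <- clock
      t_init[t] <- t_cue[t] + config$hold +
        stats::rlnorm(1, log(config$latency_init), config$latency_sdlog)
      if (stats::runif(1) < config$p_omission) {
        choice[t] <- "omission"
        outcome[t] <- "none"
        clock <- t_init[t] + config$choice_window + config$timeout_punish +
          config$iti
        next
      }
      p_right <- switch(policy,
        random = 0.5,
        qforget = softmax_p(q[["right"]] - q[["left"]], agent_params$beta),
        wsls = {
          if (is.na(prev_choice)) 0.5 else {
            rule_right <- if (isTRUE(prev_reward)) prev_choice == "right"
                          else prev_choice == "left"
            (1 - agent_params$epsilon) * as.numeric(rule_right) +
              agent_params$epsilon / 2
          }
        }
      )
      ch <- if (stats::runif(1) < p_right) "right" else "left"
      choice[t] <- ch
      t_choice[t] <- t_init[t] +
        stats::rlnorm(1, log(config$latency_choice), config$latency_sdlog)
      stepped <- step_environment(state, ch, config)
      outcome[t] <- stepped$outcome
      state <- stepped$state
      t_outcome[t] <- t_choice[t] + config$outcome_delay
      rwd <- outcome[t] == "reward"
      if (policy == "qforget") {
        other <- if (ch == "right") "left" else "right"
        q[[ch]] <- q[[ch]] + agent_params$alpha * (as.numeric(rwd) - q[[ch]])
        q[[other]] <- q[[other]] * (1 - agent_params$phi)
      }
      prev_choice <- ch
      prev_reward <- rwd
      clock <- t_outcome[t] + config$iti +
        if (outcome[t] == "punish") config$timeout_punish else 0
    }
    trials <- data.frame(
      session_id = session_id, animal_id = animal_id,
      trial_index = trial_index, block_index = block_index,
      rewarded_side = rewarded_side, choice = choice, outcome = outcome,
      t_cue = t_cue, t_init = t_init, t_choice = t_choice,
      t_outcome = t_outcome,
      light_on = FALSE, light_epoch = "na",
      stringsAsFactors = FALSE
    )
    structure(
      list(trials = trials, config = config, seed = seed, policy = policy,
           agent_params = agent_params, hemisphere = hemisphere),
      class = "bandit_session"
    )
  })
}

check_agent_params <- function(policy, agent_params) {
  need <- switch(policy,
    qforget = c("alpha", "beta", "phi"),
    wsls = "epsilon",
    random = character(0),
    stop(sprintf("unknown policy '%s'", policy), call. = FALSE)
  )
  missing <- setdiff(need, names(agent_params))
  if (length(missing)) {
    stop(sprintf("policy '%s' requires agent_params: %s", policy,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (policy == "qforget") {
    with(agent_params, {
      if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]", call. = FALSE)
      if (beta < 0) stop("beta must be >= 0", call. = FALSE)
      if (phi < 0 || phi > 1) stop("phi must be in [0,1]", call. = FALSE)
    })
  }
  if (policy == "wsls" &&
      (agent_params$epsilon < 0 || agent_params$epsilon > 1)) {
    stop("epsilon must be in [0,1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Mark a random subset of trials as optogenetic light trials
#'
#' Sets `light_on = TRUE` on a uniformly random subset of trials (exactly
#' `round(fraction * n)` of them) and records the illuminated epoch.
#'
#' @param session a `bandit_session`.
#' @param fraction fraction of trials illuminated (default 0.3).
#' @param epoch `"choice"` (initiation through choice) or `"outcome"`
#'   (outcome through next cue).
#' @param seed integer seed for the subset draw.
#' @return the session with `light_on`/`light_epoch` updated.
#' @export
assign_light_trials <- function(session, fraction = 0.3,
                                epoch = c("choice", "outcome"), seed = NULL) {
  epoch <- match.arg(epoch)
  if (fraction < 0 || fraction > 1) {
    stop("fraction must be in [0, 1]", call. = FALSE)
  }
  n <- nrow(session$trials)
  k <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, k))
  session$trials$light_on <- FALSE
  session$trials$light_epoch <- "na"
  session$trials$light_on[idx] <- TRUE
  session$trials$light_epoch[idx] <- epoch
  session
}

#' @export
#' @method print bandit_session
print.bandit_session <- function(x, ...) {
  tr <- x$trials
  completed <- tr$choice != "omission"
  cat(sprintf("Serial-reversal session: %d trials (%d completed), %d blocks\n",
              nrow(tr), sum(completed), max(tr$block_index)))
  cat(sprintf("  policy: %s%s\n", x$policy,
              if (length(x$agent_params))
                paste0(" (", paste(names(x$agent_params), "=",
                                   unlist(x$agent_params), collapse = ", "), ")")
              else ""))
  correct <- tr$choice == tr$rewarded_side
  cat(sprintf("  correct-choice fraction: %.3f; rewarded fraction: %.3f\n",
              mean(correct[completed]), mean(tr$outcome == "reward")))
  if (any(tr$light_on)) {
    cat(sprintf("  light trials: %d (%s epoch)\n", sum(tr$light_on),
                unique(tr$light_epoch[tr$light_on])))
  }
  invisible(x)
}
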