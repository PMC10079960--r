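#' Win-stay / lose-stay probabilities
#'
#' For each pair of consecutive completed trials, classifies the transition
#' as win or lose by the earlier trial's outcome (win = rewarded; lose = any
#' unrewarded completed trial, punished or no-outcome) and as stay or shift
#' by whether the later choice repeats the earlier one. Omission trials are
#' skipped: the reference is always the previous completed trial.
#'
#' `condition` restricts transitions by the PRIOR trial's optogenetic light
#' status, the conditioning used for light-effect contrasts.
#'
#' @param session a `bandit_session` or a trial-record data.frame.
#' @param condition `"all"`, `"light_on"` or `"light_off"`.
#' @param epoch when conditioning on light, restrict to trials whose light
#'   epoch matches (`"choice"`, `"outcome"`), or `"any"`.
#' @return an object of class `stay_table`: a list with `p_winstay`,
#'   `p_losestay` (NA when a condition cell is empty), the four transition
#'   counts and the condition label.
#' @examples
#' tr <- data.frame(trial_index = 1:4, choice = c("left","left","right","right"),
#'                  outcome = c("reward","none","punish","reward"),
#'                  light_on = FALSE, light_epoch = "na")
#' stay_probabilities(tr)
#' @export
stay_probabilities <- function(session, condition = c("all", "light_on",
                                                      "light_off"),
                               epoch = "any") {
  condition <- match.arg(condition)
  tr <- if (inherits(session, "bandit_session")) session$trials else session
  tr <- tr[tr$choice %in% c("left", "right"), , drop = FALSE]
  n <- nrow(tr)
  if (n < 2) stop("need >= 2 completed trials", call. = FALSE)
  prev <- tr[-n, , drop = FALSE]
  cur <- tr[-1, , drop = FALSE]
  keep <- switch(condition,
    all = rep(TRUE, n - 1),
    light_on = prev$light_on & (epoch == "any" | prev$light_epoch == epoch),
    light_off = !prev$light_on
  )
  win <- prev$outcome == "reward"
  stay <- cur$choice == prev$choice
  counts <- c(
    win_stay = sum(keep & win & stay),
    win_shift = sum(keep & win & !stay),
    lose_stay = sum(keep & !win & stay),
    lose_shift = sum(keep & !win & !stay)
  )
  p_ws <- if (counts["win_stay"] + counts["win_shift"] > 0) {
    unname(counts["win_stay"] / (counts["win_stay"] + counts["win_shift"]))
  } else NA_real_
  p_ls <- if (counts["lose_stay"] + counts["lose_shift"] > 0) {
    unname(counts["lose_stay"] / (counts["lose_stay"] + counts["lose_shift"]))
  } else NA_real_
  structure(list(p_winstay = p_ws, p_losestay = p_ls, counts = counts,
                 condition = condition), class = "stay_table")
}

#' @export
#' @method print stay_table
print.stay_table <- function(x, ...) {
  cat(sprintf("Stay probabilities (%s): P(stay|win) = %s, P(stay|lose) = %s\n",
              x$condition, format(x$p_winstay, digits = 4),
              format(x$p_losestay, digits = 4)))
  print(x$counts)
  invisible(x)
}

#' Relative reward stay (log odds ratio of win-stay vs lose-stay)
#'
#' `ln[(p_ws / (1 - p_ws)) / (p_ls / (1 - p_ls))]`. A value above 2 is the
#' conventional training criterion for reward-sensitive performance. When
#' any transition cell is empty or a probability sits at 0 or 1, the
#' Haldane-Anscombe correction (0.5 added to all four counts) is applied and
#' the result flagged via the `"corrected"` attribute.
#'
#' @param stay a `stay_table`, or a numeric vector `c(p_winstay, p_losestay)`.
#' @return the log odds-ratio, with attribute `corrected`.
#' @examples
#' relative_reward_stay(c(0.85, 0.5))   # log(17/3) = 1.7346
#' @export
relative_reward_stay <- function(stay) {
  if (inherits(stay, "stay_table")) {
    cts <- stay$counts
    degenerate <- any(cts == 0) || anyNA(c(stay$p_winstay, stay$p_losestay))
    if (degenerate) cts <- cts + 0.5
    p_ws <- cts[["win_stay"]] / (cts[["win_stay"]] + cts[["win_shift"]])
    p_ls <- cts[["lose_stay"]] / (cts[["lose_stay"]] + cts[["lose_shift"]])
    corrected <- degenerate
  } else {
    p_ws <- stay[1]; p_ls <- stay[2]
    corrected <- FALSE
    if (any(c(p_ws, p_ls) <= 0 | c(p_ws, p_ls) >= 1)) {
      stop("probabilities must lie strictly in (0,1); pass a stay_table for ",
           "the count-based correction", call. = FALSE)
    }
  }
  out <- log((p_ws / (1 - p_ws)) / (p_ls / (1 - p_ls)))
  attr(out, "corrected") <- corrected
  out
}

#' Optogenetic stay-probability contrasts
#'
#' `DeltaWinStay = P(stay | win, light ON) - P(stay | win, light OFF)` and
#' the analogous `DeltaLoseStay`, where win/lose is the prior trial's reward
#' status and ON/OFF the prior trial's illumination for the named epoch.
#' Transitions are pooled over sessions.
#'
#' @param sessions a `bandit_session` or list of them.
#' @param epoch light epoch to condition on (`"choice"`, `"outcome"` or
#'   `"any"`).
#' @return list with `delta_winstay`, `delta_losestay`, and the underlying
#'   ON/OFF `stay_table`s. Missing condition cells yield NA with a warning.
#' @export
delta_stay <- function(sessions, epoch = "any") {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  ## pool transitions session by session so pairs never span sessions
  pool <- function(cond) {
    cts <- Reduce(`+`, lapply(sessions, function(s) {
      stay_probabilities(s, condition = cond, epoch = epoch)$counts
    }))
    p_ws <- if (sum(cts[1:2]) > 0) cts[["win_stay"]] / sum(cts[1:2]) else NA_real_
    p_ls <- if (sum(cts[3:4]) > 0) cts[["lose_stay"]] / sum(cts[3:4]) else NA_real_
    structure(list(p_winstay = p_ws, p_losestay = p_ls, counts = cts,
                   condition = cond), class = "stay_table")
  }
  on <- pool("light_on")
  off <- pool("light_off")
  if (anyNA(c(on$p_winstay, on$p_losestay, off$p_winstay, off$p_losestay))) {
    warning("a light/outcome condition cell is empty; contrast undefined",
            call. = FALSE)
  }
  list(delta_winstay = on$p_winstay - off$p_winstay,
       delta_losestay = on$p_losestay - off$p_losestay,
       on = on, off = off)
}

#' Local reward rate over the previous trials
#'
#' Per-trial reward rate in uL/min: rewards collected over the prior
#' `window` trials times the reward volume, divided by the elapsed time of
#' those trials (trial start to trial start of the window's span). Trials
#' with fewer than `window` predecessors use the available history; which
#' trials those are is flagged in the `"partial"` attribute. Trial 1, with no
#' history, gets 0.
#'
#' @param session a `bandit_session`.
#' @param window number of prior trials (default 5).
#' @param reward_volume uL per reward; defaults to the session config.
#' @return numeric vector, one rate per trial (uL/min), with attribute
#'   `partial` marking trials computed from a short window.
#' @export
local_reward_rate <- function(session, window = 5, reward_volume = NULL) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  tr <- if (inherits(session, "bandit_session")) session$trials else session
  if (is.null(reward_volume)) {
    reward_volume <- if (inherits(session, "bandit_session")) {
      session$config$reward_volume
    } else 12
  }
  n <- nrow(tr)
  rate <- numeric(n)
  partial <- logical(n)
  rewarded <- tr$outcome == "reward"
  for (t in seq_len(n)) {
    lo <- max(1L, t - window)
    if (lo == t) { rate[t] <- 0; partial[t] <- TRUE; next }
    partial[t] <- (t - lo) < window
    n_rew <- sum(rewarded[lo:(t - 1)])
    elapsed_min <- (tr$t_cue[t] - tr$t_cue[lo]) / 60
    rate[t] <- if (elapsed_min > 0) n_rew * reward_volume / elapsed_min else 0
  }
  attr(rate, "partial") <- partial
  rate
}

#' Task-engagement metrics relative to baseline sessions
#'
#' Total completed trials normalised to the baseline group's mean, and mean
#' initiation latency (`t_init - t_cue`), per group.
#'
#' @param sessions,baseline_sessions `bandit_session`s or lists of them.
#' @return list with `trials_normalized` (ratio of mean completed trials),
#'   `initiation_latency` and `baseline_initiation_latency` (s).
#' @export
engagement_metrics <- function(sessions, baseline_sessions) {
  as_list <- function(x) if (inherits(x, "bandit_session")) list(x) else x
  sessions <- as_list(sessions)
  baseline_sessions <- as_list(baseline_sessions)
  n_completed <- function(s) sum(s$trials$choice %in% c("left", "right"))
  lat <- function(ss) {
    mean(unlist(lapply(ss, function(s) s$trials$t_init - s$trials$t_cue)),
         na.rm = TRUE)
  }
  list(
    trials_normalized = mean(vapply(sessions, n_completed, numeric(1))) /
      mean(vapply(baseline_sessions, n_completed, numeric(1))),
    initiation_latency = lat(sessions),
    baseline_initiation_latency = lat(baseline_sessions)
  )
}
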