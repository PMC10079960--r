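#' Extract the signed choice/outcome series from a session
#'
#' Converts a session's completed trials into the coded series used by all
#' choice models: `c` (+1 right, -1 left), `R` (1 reward, 0 otherwise) and
#' `r = c * R` (+1 reward after a right choice, -1 reward after a left
#' choice, 0 when no reward). Omission trials are dropped; history lags in
#' the models skip over them.
#'
#' @param session a `bandit_session`, or a data.frame of trial records.
#' @return data.frame with columns `trial_index`, `c`, `R`, `r`.
#' @export
choice_series <- function(session) {
  tr <- if (inherits(session, "bandit_session")) session$trials else session
  tr <- tr[tr$choice %in% c("left", "right"), , drop = FALSE]
  cc <- ifelse(tr$choice == "right", 1, -1)
  RR <- as.numeric(tr$outcome == "reward")
  data.frame(trial_index = tr$trial_index, c = cc, R = RR, r = cc * RR)
}

#' Q-value trajectory under Q-learning with forgetting
#'
#' Replays a choice/outcome series through the value-update rule: both values
#' start at 0; on each trial the chosen port updates as
#' `Q <- Q + alpha * (R - Q)` while the unchosen port decays towards zero,
#' `Q <- Q * (1 - phi)`. Setting `phi = 0` recovers plain Q-learning.
#'
#' Reported `Q_left`/`Q_right` are the values in force when the trial's
#' choice was made (pre-update); `Q_left_post`/`Q_right_post` are the values
#' after the trial's outcome, which is when internal-value predictors of the
#' encoding model step. The reward prediction error is `rpe = R - Q(chosen)`
#' with the pre-update value.
#'
#' @param series a [choice_series()] data.frame.
#' @param params list with `alpha` (learning rate), `phi` (forgetting rate)
#'   and optionally `beta` (inverse temperature, used for `p_right`).
#' @return data.frame of per-trial latents: `Q_left`, `Q_right`, `dQ`
#'   (`Q_left - Q_right`), `sQ` (`Q_left + Q_right`), `rpe`, post-outcome
#'   values, and `p_right` when `beta` is supplied.
#' @examples
#' s <- data.frame(trial_index = 1:2, c = c(1, -1), R = c(1, 0), r = c(1, 0))
#' q_trajectory(s, list(alpha = 0.5, phi = 0.1))
#' @export
q_trajectory <- function(series, params) {
  n <- nrow(series)
  ql <- qr_ <- dq <- sq <- rpe <- qlp <- qrp <- numeric(n)
  q <- c(0, 0)  # (left, right)
  for (t in seq_len(n)) {
    ql[t] <- q[1]; qr_[t] <- q[2]
    chosen <- if (series$c[t] > 0) 2L else 1L
    other <- 3L - chosen
    rpe[t] <- series$R[t] - q[chosen]
    q[chosen] <- q[chosen] + params$alpha * rpe[t]
    q[other] <- q[other] * (1 - params$phi)
    qlp[t] <- q[1]; qrp[t] <- q[2]
  }
  out <- data.frame(
    trial_index = series$trial_index,
    Q_left = ql, Q_right = qr_, dQ = ql - qr_, sQ = ql + qr_, rpe = rpe,
    Q_left_post = qlp, Q_right_post = qrp,
    dQ_post = qlp - qrp, sQ_post = qlp + qrp
  )
  if (!is.null(params$beta)) {
    out$p_right <- softmax_p(out$Q_right - out$Q_left, params$beta)
  }
  out
}

#' Recursive logistic-regression state estimate
#'
#' Computes the exponentially weighted reward-history state
#' `rho(t) = beta * r(t) + exp(-1/tau) * rho(t-1)` (equal to the explicit sum
#' `beta * sum_i exp(-i/tau) * r(t-i)`) and the choice logit
#' `h(t) = gamma + alpha * c(t-1) + rho(t-1)`, with `rho(0) = 0` and
#' `c(0) = 0` so that the first trial's logit is the bias alone.
#'
#' @param series a [choice_series()] data.frame.
#' @param params list with `alpha_stick` (choice stickiness), `beta_rew`
#'   (reward-history sensitivity), `gamma` (side bias) and `tau` (memory time
#'   constant in trials, > 0).
#' @return data.frame with per-trial `rho`, `h` and `p_right`.
#' @examples
#' s <- data.frame(trial_index = 1:3, c = c(1, 1, 1), R = c(1, 0, 1),
#'                 r = c(1, 0, 1))
#' rlogreg_state(s, list(alpha_stick = 0, beta_rew = 1, gamma = 0, tau = 1))$rho
#' @export
rlogreg_state <- function(series, params) {
  if (params$tau <= 0) stop("tau must be > 0", call. = FALSE)
  n <- nrow(series)
  decay <- exp(-1 / params$tau)
  rho <- numeric(n)
  h <- numeric(n)
  rho_prev <- 0
  c_prev <- 0
  for (t in seq_len(n)) {
    h[t] <- params$gamma + params$alpha_stick * c_prev + rho_prev
    rho[t] <- params$beta_rew * series$r[t] + decay * rho_prev
    rho_prev <- rho[t]
    c_prev <- series$c[t]
  }
  data.frame(trial_index = series$trial_index, rho = rho, h = h,
             p_right = plogis_safe(h))
}

## per-trial P(right) under each model; used by both the likelihood and the
## fitted-object predict method
model_p_right <- function(model, series, params) {
  n <- nrow(series)
  switch(model,
    qforget = ,
    qlearn = {
      pars <- params
      if (model == "qlearn") pars$phi <- 0
      traj <- q_trajectory(series, pars)
      softmax_p(traj$Q_right - traj$Q_left, pars$beta)
    },
    rlogreg = rlogreg_state(series, params)$p_right,
    wsls = {
      p <- rep(0.5, n)
      if (n > 1) {
        stay_right <- ifelse(series$R[-n] == 1, series$c[-n] > 0,
                             series$c[-n] < 0)
        p[-1] <- (1 - params$epsilon) * as.numeric(stay_right) +
          params$epsilon / 2
      }
      p
    },
    logreg = {
      h <- rep(NA_real_, n)
      if (n > 5) {
        for (t in 6:n) {
          lags <- (t - 1):(t - 5)
          h[t] <- params$beta0 +
            sum(params$beta1 * series$c[lags]) +
            sum(params$beta2 * series$r[lags])
        }
      }
      plogis_safe(h)
    },
    stop(sprintf("unknown model '%s'", model), call. = FALSE)
  )
}

#' Negative log-likelihood of a choice model
#'
#' `nll = -sum(log P(observed choice))` over the trials the model assigns a
#' probability to: all completed trials for the Q-learning, recursive
#' logistic regression and win-stay/lose-shift models (trials lacking the
#' needed history get P = 0.5), and trials 6 onwards for the 5-lag logistic
#' regression. Probabilities are clamped away from 0/1 before the log.
#'
#' Models: `"qforget"` (alpha, beta, phi), `"qlearn"` (alpha, beta; phi fixed
#' at 0), `"rlogreg"` (alpha_stick, beta_rew, gamma, tau), `"wsls"`
#' (epsilon: with probability epsilon the choice is uniform random, else
#' stay-after-win / shift-after-loss, so P(stay | win) = (1 - epsilon) +
#' epsilon/2), `"logreg"` (beta0, beta1[5], beta2[5]).
#'
#' @param model model name.
#' @param series a [choice_series()] data.frame.
#' @param params named list of parameters for the model.
#' @return the negative log-likelihood (scalar).
#' @export
model_loglik <- function(model, series, params) {
  ## lean loops for the models the optimizer hammers
  if (model %in% c("qforget", "qlearn")) {
    phi <- if (model == "qlearn") 0 else params$phi
    return(nll_qforget(series$c, series$R, params$alpha, params$beta, phi))
  }
  if (model == "rlogreg") {
    return(nll_rlogreg(series$c, series$r, params$alpha_stick,
                       params$beta_rew, params$gamma, params$tau))
  }
  p_right <- model_p_right(model, series, params)
  p_obs <- ifelse(series$c > 0, p_right, 1 - p_right)
  p_obs <- p_obs[!is.na(p_obs)]
  -sum(log(clamp_p(p_obs)))
}

nll_qforget <- function(cc, RR, alpha, beta, phi) {
  ql <- qr_ <- 0
  nll <- 0
  for (t in seq_along(cc)) {
    h <- beta * (qr_ - ql)
    logp <- if (cc[t] > 0) -log1p(exp(-h)) else -log1p(exp(h))
    nll <- nll - max(logp, log(1e-12))
    if (cc[t] > 0) {
      qr_ <- qr_ + alpha * (RR[t] - qr_)
      ql <- ql * (1 - phi)
    } else {
      ql <- ql + alpha * (RR[t] - ql)
      qr_ <- qr_ * (1 - phi)
    }
  }
  nll
}

nll_rlogreg <- function(cc, rr, alpha_stick, beta_rew, gamma, tau) {
  decay <- exp(-1 / tau)
  rho <- 0
  c_prev <- 0
  nll <- 0
  for (t in seq_along(cc)) {
    h <- gamma + alpha_stick * c_prev + rho
    logp <- if (cc[t] > 0) -log1p(exp(-h)) else -log1p(exp(h))
    nll <- nll - max(logp, log(1e-12))
    rho <- beta_rew * rr[t] + decay * rho
    c_prev <- cc[t]
  }
  nll
}

## parameter space per model: names, lower and upper bounds
model_param_space <- function(model) {
  switch(model,
    qforget = list(names = c("alpha", "beta", "phi"),
                   lower = c(0, 0, 0), upper = c(1, 50, 1)),
    qlearn = list(names = c("alpha", "beta"),
                  lower = c(0, 0), upper = c(1, 50)),
    rlogreg = list(names = c("alpha_stick", "beta_rew", "gamma", "tau"),
                   lower = c(-10, -10, -10, 0.01), upper = c(10, 10, 10, 50)),
    wsls = list(names = "epsilon", lower = 0, upper = 1),
    stop(sprintf("no optimizer parameter space for model '%s'", model),
         call. = FALSE)
  )
}

vec_to_params <- function(model, x) {
  sp <- model_param_space(model)
  as.list(stats::setNames(x, sp$names))
}
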