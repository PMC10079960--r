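series_from <- function(c_, R_) {
  data.frame(trial_index = seq_along(c_), c = c_, R = R_, r = c_ * R_)
}

test_that("Q updates follow the learn/forget rules", {
  s <- series_from(c(1, -1), c(1, 0))
  traj <- q_trajectory(s, list(alpha = 0.5, phi = 0.1))
  ## trial 1: values in force are (0, 0); right rewarded -> Q_right 0.5
  expect_equal(traj$Q_left, c(0, 0))
  expect_equal(traj$Q_right, c(0, 0.5))
  ## after trial 2 (left unrewarded): Q_left stays 0, Q_right decays to 0.45
  expect_equal(traj$Q_left_post[2], 0)
  expect_equal(traj$Q_right_post[2], 0.45)
  expect_equal(traj$rpe, c(1, 0))
  ## dQ/sQ algebra holds everywhere
  expect_equal(traj$dQ, traj$Q_left - traj$Q_right)
  expect_equal(traj$sQ, traj$Q_left + traj$Q_right)
})

test_that("with no forgetting the unchosen value never changes", {
  set.seed(2)
  s <- series_from(sample(c(-1, 1), 50, TRUE), rbinom(50, 1, 0.5))
  traj <- q_trajectory(s, list(alpha = 0.7, phi = 0))
  unchosen_pre <- ifelse(s$c > 0, traj$Q_left, traj$Q_right)
  unchosen_post <- ifelse(s$c > 0, traj$Q_left_post, traj$Q_right_post)
  expect_equal(unchosen_pre, unchosen_post)
})

test_that("softmax probabilities match direct evaluation", {
  expect_equal(softmax_p(0.5, 3), 1 / (1 + exp(-1.5)))
  expect_equal(round(softmax_p(0.5, 3), 5), 0.81757)
  expect_equal(softmax_p(0, 7), 0.5)
  expect_equal(softmax_p(c(-2, 0, 2), 0), rep(0.5, 3))
  ## overflow-safe at extreme arguments
  expect_equal(softmax_p(50, 50), 1)
  expect_equal(softmax_p(-50, 50), 0)
  expect_error(softmax_p(1, -1), "beta")
})

test_that("the recursive state estimate reproduces the hand recursion", {
  s <- series_from(c(1, 1, 1), c(1, 0, 1))
  st <- rlogreg_state(s, list(alpha_stick = 0, beta_rew = 1, gamma = 0,
                              tau = 1))
  expect_equal(round(st$rho, 5), c(1, 0.36788, 1.13534))
  ## no rewards -> state identically zero
  s0 <- series_from(c(1, -1, 1, -1), rep(0, 4))
  expect_equal(rlogreg_state(s0, list(alpha_stick = 1, beta_rew = 2,
                                      gamma = 0, tau = 3))$rho, rep(0, 4))
  expect_error(rlogreg_state(s, list(alpha_stick = 0, beta_rew = 1,
                                     gamma = 0, tau = 0)), "tau")
})

test_that("recursion equals the explicit exponentially weighted sum", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(500, 1)
    r <- sample(c(-1, 0, 1), n, TRUE, prob = c(0.3, 0.3, 0.4))
    s <- data.frame(trial_index = 1:n, c = sample(c(-1, 1), n, TRUE),
                    R = as.numeric(r != 0), r = r)
    beta <- stats::runif(1, -3, 3)
    tau <- stats::runif(1, 0.2, 20)
    rho <- rlogreg_state(s, list(alpha_stick = 0, beta_rew = beta,
                                 gamma = 0, tau = tau))$rho
    explicit <- vapply(1:n, function(t) {
      beta * sum(exp(-(0:(t - 1)) / tau) * r[t:1])
    }, numeric(1))
    expect_lt(max(abs(rho - explicit)), 1e-10)
  }
})

test_that("model likelihoods match an exhaustive hand recursion", {
  ## win-stay/lose-shift lapse semantics
  s2 <- series_from(c(1, 1), c(1, 1))  # win then stay
  expect_equal(exp(-model_loglik("wsls", s2, list(epsilon = 0.2))),
               0.5 * 0.9)  # first trial 0.5, then P(stay|win) = 0.9
  ## full lapse: every trial is a coin flip
  set.seed(4)
  s <- series_from(sample(c(-1, 1), 40, TRUE), rbinom(40, 1, 0.6))
  expect_equal(model_loglik("wsls", s, list(epsilon = 1)), 40 * log(2))
  ## flat softmax likewise
  expect_equal(model_loglik("qforget", s,
                            list(alpha = 0.5, beta = 0, phi = 0.2)),
               40 * log(2))

  ## trial-by-trial hand recursion on a short series, all models
  sh <- series_from(c(1, -1, 1, 1, -1, -1, 1, 1, -1, 1, 1, -1),
                    c(1, 0, 1, 1, 0, 1, 0, 1, 0, 1, 1, 0))
  pars_q <- list(alpha = 0.4, beta = 2.5, phi = 0.15)
  q <- c(0, 0); nll_q <- 0
  for (t in 1:12) {
    p_r <- 1 / (1 + exp(-pars_q$beta * (q[2] - q[1])))
    nll_q <- nll_q - log(if (sh$c[t] > 0) p_r else 1 - p_r)
    ch <- if (sh$c[t] > 0) 2 else 1
    q[ch] <- q[ch] + pars_q$alpha * (sh$R[t] - q[ch])
    q[3 - ch] <- q[3 - ch] * (1 - pars_q$phi)
  }
  expect_equal(model_loglik("qforget", sh, pars_q), nll_q)

  pars_r <- list(alpha_stick = 0.8, beta_rew = 1.2, gamma = -0.3, tau = 2)
  rho <- 0; cprev <- 0; nll_r <- 0
  for (t in 1:12) {
    h <- pars_r$gamma + pars_r$alpha_stick * cprev + rho
    p_r <- 1 / (1 + exp(-h))
    nll_r <- nll_r - log(if (sh$c[t] > 0) p_r else 1 - p_r)
    rho <- pars_r$beta_rew * sh$r[t] + exp(-1 / pars_r$tau) * rho
    cprev <- sh$c[t]
  }
  expect_equal(model_loglik("rlogreg", sh, pars_r), nll_r)

  pars_l <- list(beta0 = 0.1, beta1 = c(0.5, 0.2, 0, -0.1, 0.05),
                 beta2 = c(0.8, 0.3, 0.1, 0, -0.05))
  nll_l <- 0
  for (t in 6:12) {
    h <- pars_l$beta0 +
      sum(pars_l$beta1 * sh$c[(t - 1):(t - 5)]) +
      sum(pars_l$beta2 * sh$r[(t - 1):(t - 5)])
    p_r <- 1 / (1 + exp(-h))
    nll_l <- nll_l - log(if (sh$c[t] > 0) p_r else 1 - p_r)
  }
  expect_equal(model_loglik("logreg", sh, pars_l), nll_l)
})

test_that("forgetting fixed at zero reproduces the plain Q model exactly", {
  set.seed(8)
  s <- series_from(sample(c(-1, 1), 120, TRUE), rbinom(120, 1, 0.5))
  pars <- list(alpha = 0.35, beta = 4)
  expect_identical(model_loglik("qlearn", s, pars),
                   model_loglik("qforget", s, c(pars, list(phi = 0))))
})

test_that("latent correlation handles identity, negation and degeneracy", {
  x <- stats::rnorm(50)
  expect_equal(latent_correlation(x, x), 1)
  expect_equal(latent_correlation(x, -x), -1)
  expect_warning(r <- latent_correlation(x, rep(1, 50)), "constant")
  expect_true(is.na(r))
  expect_error(latent_correlation(x, x[-1]), "equal length")
})
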