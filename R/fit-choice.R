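#' Fit a trial-by-trial choice model by maximum likelihood
#'
#' Fits one of five choice models to a session's completed trials by
#' minimising the negative log-likelihood. The nonlinear models (`qforget`,
#' `qlearn`, `rlogreg`, `wsls`) use bounded L-BFGS-B optimisation from
#' `n_restarts` uniform-random starting points within the parameter bounds
#' (alpha, phi, epsilon in \[0,1\]; beta in \[0,50\]; tau in (0.01,50\];
#' stickiness/bias weights in \[-10,10\]); the best restart wins, ties broken
#' by first index. The 5-lag logistic regression (`logreg`, 11 parameters) is
#' an ordinary logistic GLM and is fitted with [stats::glm.fit()], dropping
#' the first 5 trials for lack of history.
#'
#' @param session a `bandit_session` or a [choice_series()] data.frame.
#' @param model one of `"qforget"`, `"qlearn"`, `"rlogreg"`, `"wsls"`,
#'   `"logreg"`.
#' @param n_restarts number of random restarts for the nonlinear models.
#' @param seed integer seed controlling the restart draws (fits are exactly
#'   reproducible given the same session and seed).
#' @param min_trials minimum number of completed trials required.
#' @return an object of class `choice_fit` with elements `model`, `params`
#'   (named vector), `nll`, `n_params`, `n_obs` (trials entering the
#'   likelihood), `aic` (`2k + 2 nll`), `bic` (`k log n + 2 nll`), `p_right`
#'   (per completed trial), `latents` (Q-value trajectory for the Q models,
#'   state estimate for `rlogreg`), `converged`, and `boundary` (TRUE when
#'   the optimum sits on a parameter bound, e.g. beta driven to its cap by
#'   near-deterministic data).
#' @seealso [compare_choice_models()], [model_loglik()]
#' @examples
#' \donttest{
#' s <- simulate_session(400, "qforget",
#'                       list(alpha = 0.6, beta = 5, phi = 0.2), seed = 1)
#' fit <- fit_choice_model(s, "qforget", seed = 1)
#' coef(fit)
#' }
#' @export
fit_choice_model <- function(session, model = c("qforget", "qlearn",
                                                "rlogreg", "wsls", "logreg"),
                             n_restarts = 20, seed = NULL, min_trials = 50) {
  model <- match.arg(model)
  series <- if (is.data.frame(session) && all(c("c", "R", "r") %in%
                                              names(session))) {
    session
  } else {
    choice_series(session)
  }
  if (nrow(series) < min_trials) {
    stop(sprintf("need >= %d completed trials (got %d)", min_trials,
                 nrow(series)), call. = FALSE)
  }

  if (model == "logreg") {
    fit <- fit_logreg(series)
  } else {
    fit <- with_seed(seed, fit_optim(model, series, n_restarts))
  }

  params_list <- as_model_params(model, fit$params)
  p_right <- model_p_right(model, series, params_list)
  n_obs <- sum(!is.na(p_right))
  k <- length(fit$params)
  latents <- switch(model,
    qforget = q_trajectory(series, params_list),
    qlearn = q_trajectory(series, c(params_list, list(phi = 0))),
    rlogreg = rlogreg_state(series, params_list),
    NULL
  )
  structure(
    list(model = model, params = fit$params, nll = fit$nll, n_params = k,
         n_obs = n_obs, aic = 2 * k + 2 * fit$nll,
         bic = k * log(n_obs) + 2 * fit$nll,
         p_right = p_right, latents = latents, series = series,
         converged = fit$converged, boundary = fit$boundary,
         n_restarts = if (model == "logreg") NA_integer_ else n_restarts,
         seed = seed),
    class = "choice_fit"
  )
}

fit_optim <- function(model, series, n_restarts) {
  sp <- model_param_space(model)
  k <- length(sp$names)
  obj <- function(x) model_loglik(model, series, vec_to_params(model, x))
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(n_restarts)) {
    start <- sp$lower + stats::runif(k) * (sp$upper - sp$lower)
    res <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = sp$lower, upper = sp$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop(sprintf("all %d restarts failed for model '%s'", n_restarts, model),
         call. = FALSE)
  }
  if (!any_conv) {
    warning(sprintf("no restart converged for model '%s'; returning best value",
                    model), call. = FALSE)
  }
  tol <- 1e-4 * (sp$upper - sp$lower)
  boundary <- any(best$par <= sp$lower + tol | best$par >= sp$upper - tol)
  list(params = stats::setNames(best$par, sp$names), nll = best$value,
       converged = any_conv, boundary = boundary)
}

fit_logreg <- function(series) {
  n <- nrow(series)
  if (n <= 10) stop("logreg needs more than 10 completed trials", call. = FALSE)
  rows <- 6:n
  X <- cbind(1,
             sapply(1:5, function(i) series$c[rows - i]),
             sapply(1:5, function(i) series$r[rows - i]))
  colnames(X) <- c("beta0", paste0("beta1_", 1:5), paste0("beta2_", 1:5))
  y <- as.numeric(series$c[rows] > 0)
  g <- stats::glm.fit(X, y, family = stats::binomial())
  co <- stats::coef(g)
  params <- stats::setNames(as.numeric(co), colnames(X))
  nll <- g$deviance / 2
  list(params = params, nll = nll, converged = g$converged, boundary = FALSE)
}

## logreg params come back as a flat named vector; model_p_right wants the
## beta1/beta2 lag vectors
as_model_params <- function(model, params) {
  if (model == "logreg") {
    list(beta0 = params[["beta0"]],
         beta1 = unname(params[paste0("beta1_", 1:5)]),
         beta2 = unname(params[paste0("beta2_", 1:5)]))
  } else {
    as.list(params)
  }
}

#' Compare choice models on one session by AIC/BIC
#'
#' Fits each requested model to the same session and tabulates negative
#' log-likelihood, parameter count (wsls = 1, qlearn = 2, qforget = 3,
#' rlogreg = 4, logreg = 11), AIC and BIC, ranked by AIC.
#'
#' @param session a `bandit_session`.
#' @param models character vector of at least two model names.
#' @param n_restarts,seed passed to [fit_choice_model()]; each model gets a
#'   distinct sub-seed derived from `seed`.
#' @return an object of class `choice_model_comparison`: a data.frame with
#'   one row per model (columns `model`, `n_params`, `n_obs`, `nll`, `aic`,
#'   `bic`, `delta_aic`, `rank`) carrying the individual fits in
#'   `attr(, "fits")`.
#' @export
compare_choice_models <- function(session,
                                  models = c("qforget", "qlearn", "rlogreg",
                                             "wsls", "logreg"),
                                  n_restarts = 20, seed = NULL) {
  if (length(models) < 2) {
    stop("model comparison needs at least 2 models", call. = FALSE)
  }
  fits <- lapply(seq_along(models), function(i) {
    sub_seed <- if (is.null(seed)) NULL else (seed + 1000L * i) %% .Machine$integer.max
    fit_choice_model(session, models[i], n_restarts = n_restarts,
                     seed = sub_seed)
  })
  tab <- data.frame(
    model = models,
    n_params = vapply(fits, function(f) f$n_params, integer(1)),
    n_obs = vapply(fits, function(f) f$n_obs, integer(1)),
    nll = vapply(fits, function(f) f$nll, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$rank <- rank(tab$aic, ties.method = "first")
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- stats::setNames(fits, models)
  class(tab) <- c("choice_model_comparison", "data.frame")
  tab
}

#' Correlation between two latent series
#'
#' Pearson correlation between two per-trial latent series, e.g. the
#' recursive-regression state estimate rho and the Q-value difference dQ.
#'
#' @param a,b numeric vectors of equal length.
#' @return the correlation coefficient, or `NA` (with a warning) when either
#'   series is constant.
#' @export
latent_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("correlation undefined for a constant series", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' @export
#' @method print choice_fit
print.choice_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Choice model '%s' (%d parameters, %d trials)\n",
              x$model, x$n_params, x$n_obs))
  cat("  params: ", paste(names(x$params),
                          format(x$params, digits = digits),
                          sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  nll = %.2f, AIC = %.2f, BIC = %.2f\n", x$nll, x$aic, x$bic))
  if (isTRUE(x$boundary)) cat("  note: optimum on a parameter bound\n")
  if (!isTRUE(x$converged)) cat("  warning: optimizer did not converge\n")
  invisible(x)
}

#' @export
#' @method summary choice_fit
summary.choice_fit <- function(object, ...) {
  out <- list(
    model = object$model, params = object$params, nll = object$nll,
    aic = object$aic, bic = object$bic, n_obs = object$n_obs,
    converged = object$converged, boundary = object$boundary,
    mean_p_obs = mean(ifelse(object$series$c > 0, object$p_right,
                             1 - object$p_right), na.rm = TRUE)
  )
  class(out) <- "summary.choice_fit"
  out
}

#' @export
#' @method print summary.choice_fit
print.summary.choice_fit <- function(x, ...) {
  cat(sprintf("Choice model '%s'\n", x$model))
  print(x$params)
  cat(sprintf("nll %.2f | AIC %.2f | BIC %.2f | n %d\n",
              x$nll, x$aic, x$bic, x$n_obs))
  cat(sprintf("mean P(observed choice) = %.3f\n", x$mean_p_obs))
  invisible(x)
}

#' @export
coef.choice_fit <- function(object, ...) object$params

#' @export
logLik.choice_fit <- function(object, ...) {
  structure(-object$nll, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Predicted choice probabilities from a fitted choice model
#'
#' @param object a `choice_fit`.
#' @param newdata optionally a new `bandit_session` or series to evaluate the
#'   fitted parameters on.
#' @param ... unused.
#' @return per-trial probability of a right choice.
#' @export
predict.choice_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$p_right)
  series <- if (is.data.frame(newdata)) newdata else choice_series(newdata)
  model_p_right(object$model, series, as_model_params(object$model,
                                                      object$params))
}

#' Simulate new sessions from a fitted choice model
#'
#' Generates sessions in which an agent governed by the fitted policy plays
#' the serial-reversal task. Only the generative policies (`qforget`,
#' `qlearn`, `wsls`) can be simulated.
#'
#' @param object a `choice_fit`.
#' @param nsim number of sessions.
#' @param seed integer seed.
#' @param n_trials trials per simulated session.
#' @param config a [task_config()].
#' @param ... unused.
#' @return a list of `bandit_session` objects.
#' @export
simulate.choice_fit <- function(object, nsim = 1, seed = NULL,
                                n_trials = 500, config = task_config(), ...) {
  pol <- switch(object$model,
    qforget = list(policy = "qforget", params = as.list(object$params)),
    qlearn = list(policy = "qforget",
                  params = c(as.list(object$params), list(phi = 0))),
    wsls = list(policy = "wsls", params = as.list(object$params)),
    stop(sprintf("model '%s' is not generative; cannot simulate",
                 object$model), call. = FALSE)
  )
  base_seed <- if (is.null(seed)) sample.int(1e6, 1) else seed
  lapply(seq_len(nsim), function(i) {
    simulate_session(n_trials, pol$policy, pol$params, config = config,
                     seed = (base_seed + i - 1L) %% .Machine$integer.max)
  })
}

#' @export
#' @method print choice_model_comparison
print.choice_model_comparison <- function(x, ...) {
  cat("Choice model comparison (ranked by AIC)\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
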