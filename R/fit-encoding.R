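#' Fraction of variance explained
#'
#' `1 - Var(observed - predicted) / Var(observed)`.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return the FVE (1 for a perfect prediction, 0 for predicting the mean,
#'   negative for worse-than-mean predictions); `NA` with a warning when the
#'   observed signal has zero variance.
#' @export
compute_fve <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  v <- stats::var(observed)
  if (v == 0) {
    warning("observed signal has zero variance; FVE undefined", call. = FALSE)
    return(NA_real_)
  }
  1 - stats::var(observed - predicted) / v
}

#' Assign cross-validation folds at chunk granularity, stratified by trial
#'
#' Frames are grouped into 200-ms temporal chunks (about 4 imaging frames at
#' 20 Hz); folds are assigned to whole chunks so temporally adjacent frames
#' never straddle folds, and each trial's chunks are dealt across folds in a
#' rotating order so every trial is represented roughly equally in each fold.
#'
#' @param design an `encoding_design`.
#' @param n_folds number of folds (default 50).
#' @param seed integer seed for the within-trial chunk shuffle.
#' @return integer fold id per frame.
#' @export
assign_cv_folds <- function(design, n_folds = 50, seed = NULL) {
  chunk_id <- design$chunk_id
  n_chunks <- max(chunk_id)
  if (n_chunks < n_folds) {
    stop(sprintf("need at least %d chunks for %d-fold CV (got %d)",
                 n_folds, n_folds, n_chunks), call. = FALSE)
  }
  ## each chunk belongs to the trial of its first frame
  chunk_trial <- design$trial_id[match(seq_len(n_chunks), chunk_id)]
  chunk_fold <- integer(n_chunks)
  with_seed(seed, {
    counter <- 0L
    for (tr in unique(chunk_trial)) {
      chunks <- which(chunk_trial == tr)
      if (length(chunks) > 1) chunks <- sample(chunks)
      for (ch in chunks) {
        chunk_fold[ch] <- (counter %% n_folds) + 1L
        counter <- counter + 1L
      }
    }
  })
  chunk_fold[chunk_id]
}

#' Fit the penalized linear encoding model to a calcium trace
#'
#' Fits the linear encoding model `y(t) = alpha + sum_i beta_i x_i(t) +
#' sum_jkn gamma_k^(j) f_k^(j)(t - t_n^(j)) + noise` by elastic net with
#' near-lasso mixing (`alpha_mixing = 0.95`), selecting the shrinkage
#' parameter lambda by chunked, trial-stratified cross-validation and the
#' one-standard-error rule: the largest lambda whose cross-validated FVE is
#' within one standard deviation (across folds, at the FVE-maximising
#' lambda) of the maximum. Continuous predictor columns are z-scored before
#' fitting and coefficients mapped back to the original scale; spline
#' columns enter as-is. The intercept is never penalized.
#'
#' @param design an `encoding_design` from [build_design_matrix()].
#' @param trace a `calcium_trace` or a numeric vector aligned to the design's
#'   frames.
#' @param alpha_mixing elastic-net mixing parameter (1 = lasso).
#' @param n_folds number of cross-validation folds (default 50).
#' @param n_lambda length of the lambda path.
#' @param lambda_min_ratio smallest path lambda as a fraction of the largest;
#'   the deep default lets near-noiseless traces reach an essentially
#'   unpenalized solution.
#' @param seed integer seed for fold assignment.
#' @param fold_id optional explicit per-frame fold assignment (used to give a
#'   reduced model the exact folds of its full model).
#' @param fve_mode `"cv"` (default: report FVE of pooled held-out
#'   predictions) or `"train"`.
#' @return an object of class `encoding_fit`: intercept, named coefficient
#'   vector (original scale), `lambda_selected`, `lambda_path`,
#'   `cv_fve_mean`/`cv_fve_sd` per lambda, per-frame `fold_id`, `fve`
#'   (cross-validated), `fve_train`, and the design's column metadata.
#' @export
fit_encoding <- function(design, trace, alpha_mixing = 0.95, n_folds = 50,
                         n_lambda = 60, lambda_min_ratio = 1e-6, seed = NULL,
                         fold_id = NULL, fve_mode = c("cv", "train")) {
  fve_mode <- match.arg(fve_mode)
  y <- if (inherits(trace, "calcium_trace")) trace$values else trace
  if (length(y) != nrow(design$X)) {
    stop("trace and design are not frame-aligned", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    warning("all-zero-variance trace; returning intercept-only fit",
            call. = FALSE)
  }
  if (is.null(fold_id)) fold_id <- assign_cv_folds(design, n_folds, seed)
  n_folds <- max(fold_id)

  ## z-score continuous columns; leave bounded spline columns untouched
  X <- design$X
  cont <- which(design$col_meta$kind == "continuous")
  centers <- rep(0, ncol(X)); scales <- rep(1, ncol(X))
  for (j in cont) {
    s <- stats::sd(X[, j])
    if (s > 0) {
      centers[j] <- mean(X[, j]); scales[j] <- s
      X[, j] <- (X[, j] - centers[j]) / s
    }
  }

  if (ncol(X) == 0) {
    ## intercept-only degenerate design (all predictors dropped)
    return(intercept_only_fit(design, y, fold_id, fve_mode))
  }

  ## explicit log-spaced lambda sequence: every fold fits the whole path, so
  ## fold FVEs line up lambda-by-lambda without truncation artifacts
  lmax <- glmnet::glmnet(X, y, alpha = alpha_mixing,
                         nlambda = 3, standardize = FALSE)$lambda[1]
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = n_lambda))
  full_path <- glmnet::glmnet(X, y, alpha = alpha_mixing, lambda = lambda,
                              standardize = FALSE)
  lambda <- full_path$lambda

  cv_pred <- matrix(NA_real_, nrow = length(y), ncol = length(lambda))
  fold_fve <- matrix(NA_real_, nrow = n_folds, ncol = length(lambda))
  for (f in seq_len(n_folds)) {
    test <- fold_id == f
    fit_f <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                            alpha = alpha_mixing, lambda = lambda,
                            standardize = FALSE)
    pred <- stats::predict(fit_f, X[test, , drop = FALSE])
    ## a fold fit may truncate the path; align by lambda index
    k <- ncol(pred)
    cv_pred[test, seq_len(k)] <- pred
    fold_fve[f, seq_len(k)] <- apply(pred, 2, compute_fve, observed = y[test])
    if (k < length(lambda)) {
      cv_pred[test, (k + 1):length(lambda)] <- pred[, k]
      fold_fve[f, (k + 1):length(lambda)] <- fold_fve[f, k]
    }
  }
  cv_fve_mean <- colMeans(fold_fve)
  cv_fve_sd <- apply(fold_fve, 2, stats::sd)
  i_max <- which.max(cv_fve_mean)
  threshold <- cv_fve_mean[i_max] - cv_fve_sd[i_max]
  ## lambda path is decreasing: the first index meeting the threshold is the
  ## largest (sparsest) such lambda
  i_sel <- which(cv_fve_mean >= threshold)[1]
  lambda_selected <- lambda[i_sel]

  beta_std <- as.numeric(stats::coef(full_path, s = lambda_selected,
                                     exact = FALSE))
  a0 <- beta_std[1]
  b <- beta_std[-1]
  ## undo the z-scoring so coefficients live on the original predictor scale
  b_orig <- b / scales
  a0 <- a0 - sum(b * centers / scales)

  fitted_train <- as.numeric(design$X %*% b_orig) + a0
  fve_train <- compute_fve(fitted_train, y)
  fve_cv <- compute_fve(cv_pred[, i_sel], y)

  structure(
    list(intercept = a0,
         coefficients = stats::setNames(b_orig, colnames(design$X)),
         lambda_selected = lambda_selected, lambda_path = lambda,
         lambda_index = i_sel, cv_fve_mean = cv_fve_mean,
         cv_fve_sd = cv_fve_sd, fold_id = fold_id,
         alpha_mixing = alpha_mixing,
         fve = if (fve_mode == "cv") fve_cv else fve_train,
         fve_cv = fve_cv, fve_train = fve_train, fve_mode = fve_mode,
         col_meta = design$col_meta, specs = design$specs,
         fitted_values = fitted_train, residuals = y - fitted_train,
         y = y, seed = seed),
    class = "encoding_fit"
  )
}

intercept_only_fit <- function(design, y, fold_id, fve_mode) {
  n_folds <- max(fold_id)
  cv_pred <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    test <- fold_id == f
    cv_pred[test] <- mean(y[!test])
  }
  fve_cv <- compute_fve(cv_pred, y)
  structure(
    list(intercept = mean(y), coefficients = numeric(0),
         lambda_selected = Inf, lambda_path = numeric(0),
         lambda_index = NA_integer_, cv_fve_mean = fve_cv, cv_fve_sd = NA_real_,
         fold_id = fold_id, alpha_mixing = NA_real_,
         fve = if (fve_mode == "cv") fve_cv else 0,
         fve_cv = fve_cv, fve_train = 0, fve_mode = fve_mode,
         col_meta = design$col_meta, specs = design$specs,
         fitted_values = rep(mean(y), length(y)),
         residuals = y - mean(y), y = y, seed = NULL),
    class = "encoding_fit"
  )
}

#' Tuning index of a predictor (or predictor group)
#'
#' Refits the encoding model from scratch on the design with the predictors
#' of interest removed (the reduced model selects its own lambda on the same
#' cross-validation folds) and reports
#' `tuning index = FVE(full) - FVE(reduced)`, a lower bound on the dropped
#' predictors' explanatory contribution. A neuron is classified `tuned` when
#' the index exceeds `threshold` AND the full model itself is task-tuned
#' (full FVE at least `fve_threshold`).
#'
#' @param full an `encoding_fit` of the full model.
#' @param design the `encoding_design` the full model was fit on.
#' @param trace the same trace.
#' @param predictors,groups which predictors to drop (either may be NULL;
#'   dropping nothing returns an index of 0).
#' @param threshold tuning threshold on the index (default 0.05).
#' @param fve_threshold task-tuned gate on the full model's FVE (default
#'   0.05).
#' @param ... passed to [fit_encoding()] for the reduced refit.
#' @return list with `index`, `fve_full`, `fve_reduced`, `tuned`,
#'   `task_tuned` and the reduced fit.
#' @export
tuning_index <- function(full, design, trace, predictors = NULL,
                         groups = NULL, threshold = 0.05,
                         fve_threshold = 0.05, ...) {
  task_tuned <- is.finite(full$fve) && full$fve >= fve_threshold
  if (is.null(predictors) && is.null(groups)) {
    return(list(index = 0, fve_full = full$fve, fve_reduced = full$fve,
                tuned = FALSE, task_tuned = task_tuned, reduced = NULL))
  }
  reduced_design <- drop_predictors(design, predictors, groups)
  reduced <- fit_encoding(reduced_design, trace,
                          alpha_mixing = if (is.finite(full$alpha_mixing))
                            full$alpha_mixing else 0.95,
                          fold_id = full$fold_id, fve_mode = full$fve_mode,
                          ...)
  index <- full$fve - reduced$fve
  list(index = index, fve_full = full$fve, fve_reduced = reduced$fve,
       tuned = task_tuned && index > threshold, task_tuned = task_tuned,
       reduced = reduced)
}

#' Extract an event kernel from a fitted encoding model
#'
#' `kernel(lag) = sum_k gamma_k f_k(lag)` over the predictor's lag window.
#'
#' @param fit an `encoding_fit`.
#' @param predictor name of an event predictor.
#' @param n_points number of lag-grid points.
#' @return an object of class `kernel_estimate`: data.frame with `predictor`,
#'   `lag` (s) and `value` (dF/F).
#' @export
extract_kernel <- function(fit, predictor, n_points = 121) {
  spec <- fit$specs[[predictor]]
  if (is.null(spec)) stop(sprintf("unknown predictor '%s'", predictor),
                          call. = FALSE)
  if (spec$kind != "event") {
    stop(sprintf("'%s' is continuous; its effect is the scalar coefficient %s",
                 predictor,
                 format(fit$coefficients[[predictor]], digits = 4)),
         call. = FALSE)
  }
  lag <- seq(spec$basis$window[1], spec$basis$window[2],
             length.out = n_points)
  B <- build_spline_basis(spec$basis, lag)
  gam <- fit$coefficients[fit$col_meta$predictor == predictor]
  out <- data.frame(predictor = predictor, lag = lag,
                    value = as.numeric(B %*% gam))
  class(out) <- c("kernel_estimate", "data.frame")
  out
}

#' @export
#' @method print encoding_fit
print.encoding_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Encoding model fit: %d coefficients, elastic net alpha = %s\n",
              length(x$coefficients), format(x$alpha_mixing)))
  cat(sprintf("  lambda (1-SE rule): %s; FVE (%s): %.4f [train %.4f]\n",
              format(x$lambda_selected, digits = digits), x$fve_mode,
              x$fve_cv, x$fve_train))
  cat(sprintf("  nonzero coefficients: %d / %d\n",
              sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' @export
#' @method summary encoding_fit
summary.encoding_fit <- function(object, ...) {
  by_pred <- split(object$coefficients, object$col_meta$predictor)
  tab <- data.frame(
    predictor = names(by_pred),
    n_coef = vapply(by_pred, length, integer(1)),
    n_nonzero = vapply(by_pred, function(b) sum(b != 0), integer(1)),
    max_abs = vapply(by_pred, function(b) max(abs(b)), numeric(1))
  )
  rownames(tab) <- NULL
  out <- list(fve_cv = object$fve_cv, fve_train = object$fve_train,
              lambda = object$lambda_selected, predictors = tab)
  class(out) <- "summary.encoding_fit"
  out
}

#' @export
#' @method print summary.encoding_fit
print.summary.encoding_fit <- function(x, ...) {
  cat(sprintf("FVE: %.4f (cv), %.4f (train); lambda = %s\n",
              x$fve_cv, x$fve_train, format(x$lambda, digits = 4)))
  print(x$predictors, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.encoding_fit <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.encoding_fit <- function(object, design = NULL, ...) {
  if (is.null(design)) return(object$fitted_values)
  if (!identical(colnames(design$X), names(object$coefficients))) {
    stop("design columns do not match the fitted coefficients", call. = FALSE)
  }
  as.numeric(design$X %*% object$coefficients) + object$intercept
}

#' @export
fitted.encoding_fit <- function(object, ...) object$fitted_values

#' @export
residuals.encoding_fit <- function(object, ...) object$residuals

#' Plot fitted event kernels
#'
#' @param x an `encoding_fit`.
#' @param predictors event predictors to draw (default: all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.encoding_fit <- function(x, predictors = NULL, ...) {
  ev <- unique(x$col_meta$predictor[x$col_meta$kind == "event"])
  if (!is.null(predictors)) ev <- intersect(ev, predictors)
  if (!length(ev)) stop("no event predictors to plot", call. = FALSE)
  kernels <- lapply(ev, function(p) extract_kernel(x, p))
  ylim <- range(unlist(lapply(kernels, function(k) k$value)))
  graphics::plot(NA, xlim = range(unlist(lapply(kernels, function(k) k$lag))),
                 ylim = ylim, xlab = "lag from event (s)",
                 ylab = "kernel (dF/F)", ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  for (i in seq_along(kernels)) {
    graphics::lines(kernels[[i]]$lag, kernels[[i]]$value, col = i)
  }
  graphics::legend("topright", legend = ev, col = seq_along(ev), lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
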