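## Coerce a list of kernel_estimate data.frames to a neurons x lags matrix,
## enforcing a common lag grid.
kernel_matrix <- function(kernels) {
  if (is.matrix(kernels)) return(kernels)
  lags <- kernels[[1]]$lag
  K <- t(vapply(kernels, function(k) {
    if (!isTRUE(all.equal(k$lag, lags))) {
      stop("kernels are not on a common lag grid", call. = FALSE)
    }
    k$value
  }, numeric(length(lags))))
  attr(K, "lag") <- lags
  K
}

## per-lag RMS over neurons for a neurons x lags matrix
rms_over_neurons <- function(K) sqrt(colMeans(K^2))

#' Pathway RMS kernel
#'
#' The pathway-level kernel for a predictor is the per-lag root-mean-square
#' of the single-neuron kernels of the task-relevant neurons in that
#' pathway: `rms(lag) = sqrt(mean_n kernel_n(lag)^2)`. It captures the
#' magnitude (never the direction) of the population modulation, so it is
#' non-negative by construction.
#'
#' @param kernels list of `kernel_estimate`s on a common lag grid, or a
#'   neurons x lags matrix.
#' @param lag optional lag grid when `kernels` is a matrix.
#' @return an object of class `pathway_kernel`: data.frame with `lag` and
#'   `rms` (confidence bands are added by [bootstrap_kernel_ci()]).
#' @export
pathway_rms <- function(kernels, lag = NULL) {
  K <- kernel_matrix(kernels)
  if (is.null(lag)) lag <- attr(K, "lag")
  if (is.null(lag)) lag <- seq_len(ncol(K))
  out <- data.frame(lag = lag, rms = rms_over_neurons(K))
  attr(out, "K") <- K
  attr(out, "n_neurons") <- nrow(K)
  class(out) <- c("pathway_kernel", "data.frame")
  out
}

## BCa interval from a bootstrap sample, an observed statistic and jackknife
## replicates; falls back to percentile when the correction is degenerate.
bca_interval <- function(boot, obs, jack, conf = 0.95) {
  alpha <- (1 - conf) / 2
  probs <- c(alpha, 1 - alpha)
  fallback <- function() {
    list(ci = stats::quantile(boot, probs, names = FALSE, type = 6),
         method = "percentile")
  }
  if (length(unique(boot)) == 1L) {
    return(list(ci = c(boot[1], boot[1]), method = "degenerate"))
  }
  prop <- (sum(boot < obs) + 0.5 * sum(boot == obs)) / length(boot)
  if (prop <= 0 || prop >= 1) return(fallback())
  z0 <- stats::qnorm(prop)
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  if (denom == 0) return(fallback())
  a <- sum(d^3) / (6 * denom)
  zq <- stats::qnorm(probs)
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  if (anyNA(adj)) return(fallback())
  list(ci = stats::quantile(boot, adj, names = FALSE, type = 6),
       method = "bca")
}

#' Bootstrap confidence band for a pathway RMS kernel
#'
#' Resamples neurons with replacement (the same resample across all lags, so
#' the band is a band over curves) and builds a per-lag 95% interval with
#' the bias-corrected and accelerated (BCa) correction; acceleration is
#' estimated by jackknifing over neurons. Degenerate lags (all resampled
#' statistics identical) fall back to percentile intervals and are flagged.
#'
#' @param kernels as in [pathway_rms()] (needs >= 2 neurons).
#' @param n_boot number of bootstrap samples (default 10000).
#' @param conf confidence level.
#' @param seed integer seed.
#' @param lag optional lag grid for matrix input.
#' @return a `pathway_kernel` data.frame with `rms`, `ci_low`, `ci_high`,
#'   and an attribute `ci_method` per lag.
#' @export
bootstrap_kernel_ci <- function(kernels, n_boot = 10000, conf = 0.95,
                                seed = NULL, lag = NULL) {
  pk <- pathway_rms(kernels, lag)
  K <- attr(pk, "K")
  n <- nrow(K)
  if (n < 2) stop("bootstrap needs >= 2 neurons", call. = FALSE)
  L <- ncol(K)
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    t(apply(idx, 1, function(ii) rms_over_neurons(K[ii, , drop = FALSE])))
  })
  jack <- t(vapply(seq_len(n), function(i) {
    rms_over_neurons(K[-i, , drop = FALSE])
  }, numeric(L)))
  ci_low <- ci_high <- numeric(L)
  method <- character(L)
  for (l in seq_len(L)) {
    b <- bca_interval(boot[, l], pk$rms[l], jack[, l], conf)
    ci_low[l] <- b$ci[1]; ci_high[l] <- b$ci[2]; method[l] <- b$method
  }
  pk$ci_low <- ci_low
  pk$ci_high <- ci_high
  attr(pk, "ci_method") <- method
  attr(pk, "conf") <- conf
  pk
}

#' Per-lag bootstrap test for a pathway kernel difference
#'
#' Tests `rms_A(lag) != rms_B(lag)` at each lag by bootstrapping the
#' difference of the two pathway RMS kernels over neurons (resampling within
#' each pathway) and building a BCa confidence interval for the difference;
#' a lag is significant when the interval excludes zero. Per-lag tests are
#' not corrected for multiple comparisons across lags.
#'
#' @param kernels_a,kernels_b kernel sets of the two pathways (each >= 2
#'   neurons) on a common lag grid.
#' @param n_boot bootstrap samples (default 10000).
#' @param conf confidence level of the interval (0.95 gives a 5% two-sided
#'   test).
#' @param seed integer seed.
#' @param lag optional lag grid for matrix input.
#' @return data.frame with `lag`, `diff` (rms_A - rms_B), `ci_low`,
#'   `ci_high` and logical `sig`.
#' @export
kernel_difference_test <- function(kernels_a, kernels_b, n_boot = 10000,
                                   conf = 0.95, seed = NULL, lag = NULL) {
  KA <- kernel_matrix(kernels_a)
  KB <- kernel_matrix(kernels_b)
  if (ncol(KA) != ncol(KB)) {
    stop("pathway kernels have no common lag grid", call. = FALSE)
  }
  lag_a <- attr(KA, "lag")
  if (is.null(lag)) lag <- if (is.null(lag_a)) seq_len(ncol(KA)) else lag_a
  na <- nrow(KA); nb <- nrow(KB)
  if (na < 2 || nb < 2) stop("each pathway needs >= 2 neurons", call. = FALSE)
  L <- ncol(KA)
  obs <- rms_over_neurons(KA) - rms_over_neurons(KB)
  boot <- with_seed(seed, {
    ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), nrow = n_boot)
    ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = n_boot)
    t(vapply(seq_len(n_boot), function(r) {
      rms_over_neurons(KA[ia[r, ], , drop = FALSE]) -
        rms_over_neurons(KB[ib[r, ], , drop = FALSE])
    }, numeric(L)))
  })
  ## jackknife over the pooled neuron set: leaving one neuron out of its own
  ## pathway perturbs the difference statistic
  jack <- rbind(
    t(vapply(seq_len(na), function(i) {
      rms_over_neurons(KA[-i, , drop = FALSE]) - rms_over_neurons(KB)
    }, numeric(L))),
    t(vapply(seq_len(nb), function(i) {
      rms_over_neurons(KA) - rms_over_neurons(KB[-i, , drop = FALSE])
    }, numeric(L)))
  )
  out <- data.frame(lag = lag, diff = obs, ci_low = NA_real_,
                    ci_high = NA_real_, sig = NA)
  for (l in seq_len(L)) {
    b <- bca_interval(boot[, l], obs[l], jack[, l], conf)
    out$ci_low[l] <- b$ci[1]; out$ci_high[l] <- b$ci[2]
    out$sig[l] <- b$ci[1] > 0 || b$ci[2] < 0
  }
  out
}

#' Compare tuning-index distributions between two neuron groups
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on the tuning-index
#' distributions, a Welch t-test on the means, and the proportion of tuned
#' neurons at the classification threshold in each group.
#'
#' @param group_a,group_b numeric vectors of tuning indices.
#' @param threshold tuned/not-tuned threshold (default 0.05).
#' @return list with `ks_statistic`, `ks_p`, `mean_diff`, `t_p`,
#'   `prop_tuned_a`, `prop_tuned_b`.
#' @export
compare_tuning <- function(group_a, group_b, threshold = 0.05) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(group_a, group_b,
                                        alternative = "two.sided"))
  tt <- if (length(group_a) > 1 && length(group_b) > 1) {
    stats::t.test(group_a, group_b)
  } else NULL
  list(
    ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
    mean_diff = mean(group_a) - mean(group_b),
    t_p = if (is.null(tt)) NA_real_ else tt$p.value,
    prop_tuned_a = mean(group_a > threshold),
    prop_tuned_b = mean(group_b > threshold)
  )
}

#' @export
#' @method print pathway_kernel
print.pathway_kernel <- function(x, ...) {
  cat(sprintf("Pathway RMS kernel: %d neurons, %d lags (%.2f to %.2f s)\n",
              attr(x, "n_neurons"), nrow(x), min(x$lag), max(x$lag)))
  cat(sprintf("  peak rms %.4f at lag %.2f s\n",
              max(x$rms), x$lag[which.max(x$rms)]))
  if (!is.null(x$ci_low)) {
    cat(sprintf("  with %d%% bootstrap band\n",
                round(100 * attr(x, "conf"))))
  }
  invisible(x)
}

#' Plot a pathway RMS kernel with its confidence band
#'
#' @param x a `pathway_kernel`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pathway_kernel <- function(x, ...) {
  ylim <- if (is.null(x$ci_high)) range(x$rms) else c(0, max(x$ci_high))
  graphics::plot(x$lag, x$rms, type = "l", xlab = "lag from event (s)",
                 ylab = "RMS kernel (dF/F)", ylim = ylim, ...)
  if (!is.null(x$ci_low)) {
    graphics::polygon(c(x$lag, rev(x$lag)), c(x$ci_low, rev(x$ci_high)),
                      border = NA, col = grDevices::adjustcolor("grey40", 0.3))
    graphics::lines(x$lag, x$rms)
  }
  graphics::abline(v = 0, lty = 3, col = "grey60")
  invisible(x)
}
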