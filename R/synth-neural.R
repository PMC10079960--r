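## Raised-cosine bump: amplitude/2 * (1 + cos(pi (t - center)/halfwidth))
## inside |t - center| <= halfwidth, zero outside.
raised_cosine <- function(lag, center, halfwidth, amplitude) {
  out <- numeric(length(lag))
  inside <- abs(lag - center) <= halfwidth
  out[inside] <- amplitude / 2 *
    (1 + cos(pi * (lag[inside] - center) / halfwidth))
  out
}

## kernel-shape templates: "brief" emulates a sharp ~1 s transient after the
## event; "persistent" a slow increase lasting beyond 5 s (as seen after
## reward omission); "biphasic" a fast positive followed by a slow negative
## component.
kernel_shape <- function(lag, shape, amplitude) {
  switch(shape,
    brief = raised_cosine(lag, center = 0.5, halfwidth = 0.5, amplitude),
    persistent = raised_cosine(lag, center = 3, halfwidth = 2.9, amplitude),
    biphasic = raised_cosine(lag, 0.4, 0.4, amplitude) -
      raised_cosine(lag, 2.5, 2, amplitude / 2),
    stop(sprintf("unknown kernel shape '%s'", shape), call. = FALSE)
  )
}

#' Sample a ground-truth generative model for a synthetic neuron
#'
#' Builds the generative parameters the encoding model assumes: an intercept
#' (baseline dF/F), one temporal kernel per tuned event predictor, scalar
#' gains for tuned continuous predictors, and a noise SD. Kernels are smooth
#' raised-cosine shapes projected onto the predictor's own cubic B-spline
#' basis, so every ground truth is exactly representable by the encoding
#' model (noiseless traces are then reproduced exactly by the design matrix
#' times the true coefficients). Untuned predictors get exactly zero effect.
#'
#' @param specs named list of [predictor_spec()]s.
#' @param tuned named list describing the tuned predictors. For an event
#'   predictor, `list(shape = "brief"|"persistent"|"biphasic", amplitude =
#'   dF/F peak)`; for a continuous predictor a scalar gain. Example:
#'   `list(o_plus = list(shape = "brief", amplitude = 1), dQ = 0.5)`.
#'   An empty list gives an untuned neuron (intercept only).
#' @param intercept baseline dF/F.
#' @param noise_sigma SD of the additive Gaussian noise (dF/F).
#' @param amplitude_jitter multiplicative log-normal jitter applied to each
#'   tuned amplitude (0 disables; gives across-neuron variability).
#' @param seed integer seed.
#' @return an object of class `ground_truth`: intercept, per-event-predictor
#'   basis coefficients (`gammas`) and kernel curves, continuous gains, and
#'   `noise_sigma`.
#' @export
sample_ground_truth <- function(specs = default_predictor_specs(),
                                tuned = list(), intercept = 0.1,
                                noise_sigma = 0.1, amplitude_jitter = 0,
                                seed = NULL) {
  unknown <- setdiff(names(tuned), names(specs))
  if (length(unknown)) {
    stop("tuned predictors not in specs: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    gammas <- list()
    gains <- numeric(0)
    for (nm in names(specs)) {
      spec <- specs[[nm]]
      if (spec$kind == "event") {
        if (nm %in% names(tuned)) {
          tn <- tuned[[nm]]
          amp <- tn$amplitude
          if (amplitude_jitter > 0) {
            amp <- amp * exp(stats::rnorm(1, 0, amplitude_jitter))
          }
          grid <- seq(spec$basis$window[1], spec$basis$window[2],
                      length.out = 400)
          target <- kernel_shape(grid, tn$shape, amp)
          B <- build_spline_basis(spec$basis, grid)
          gam <- stats::lsfit(B, target, intercept = FALSE)$coefficients
          gammas[[nm]] <- unname(gam)
        } else {
          gammas[[nm]] <- rep(0, spec$basis$n_basis)
        }
      } else {
        g <- if (nm %in% names(tuned)) as.numeric(tuned[[nm]]) else 0
        if (g != 0 && amplitude_jitter > 0) {
          g <- g * exp(stats::rnorm(1, 0, amplitude_jitter))
        }
        gains[[nm]] <- g
      }
    }
    structure(
      list(intercept = intercept, gammas = gammas, gains = gains,
           noise_sigma = noise_sigma, specs = specs, tuned = names(tuned)),
      class = "ground_truth"
    )
  })
}

#' Ground-truth coefficient vector aligned to a design matrix
#'
#' @param truth a `ground_truth`.
#' @param design an `encoding_design` built from the same predictor specs.
#' @return named numeric vector matching `colnames(design$X)`.
#' @export
truth_coefficients <- function(truth, design) {
  beta <- numeric(ncol(design$X))
  names(beta) <- colnames(design$X)
  for (i in seq_len(nrow(design$col_meta))) {
    m <- design$col_meta[i, ]
    beta[i] <- if (m$kind == "event") {
      truth$gammas[[m$predictor]][m$basis_index]
    } else {
      truth$gains[[m$predictor]]
    }
  }
  beta
}

#' True kernel curve of a ground truth
#'
#' @param truth a `ground_truth`.
#' @param predictor event predictor name.
#' @param n_points lag-grid length.
#' @return a `kernel_estimate` data.frame (predictor, lag, value).
#' @export
true_kernel <- function(truth, predictor, n_points = 121) {
  spec <- truth$specs[[predictor]]
  if (is.null(spec) || spec$kind != "event") {
    stop(sprintf("'%s' is not an event predictor", predictor), call. = FALSE)
  }
  lag <- seq(spec$basis$window[1], spec$basis$window[2], length.out = n_points)
  B <- build_spline_basis(spec$basis, lag)
  out <- data.frame(predictor = predictor, lag = lag,
                    value = as.numeric(B %*% truth$gammas[[predictor]]))
  class(out) <- c("kernel_estimate", "data.frame")
  out
}

#' Synthesize a calcium trace from a session and a ground truth
#'
#' Builds a dF/F trace as the linear superposition the encoding model
#' assumes: intercept + continuous gains times their predictor series +
#' event kernels placed at each event occurrence (overlapping kernels add) +
#' white Gaussian noise. An optional AR(1) noise switch exists for
#' robustness experiments only.
#'
#' @param session a `bandit_session`.
#' @param truth a `ground_truth`.
#' @param latents per-trial latents for the session's completed trials
#'   (needed when value predictors are tuned or present).
#' @param head_velocity optional velocity series (list of `times`,
#'   `values`).
#' @param frame_rate imaging frame rate (Hz, default 20).
#' @param duration trace duration (s); defaults to the last event plus the
#'   longest kernel window. All session events must fall inside it.
#' @param seed integer seed for the noise draw.
#' @param ar1 AR(1) coefficient for temporally correlated noise (0 = white).
#' @param neuron_id,pathway labels carried on the trace.
#' @return an object of class `calcium_trace`: `frame_times`, `values`,
#'   noiseless component (`noiseless`), labels and the embedded truth.
#' @export
synthesize_trace <- function(session, truth, latents = NULL,
                             head_velocity = NULL, frame_rate = 20,
                             duration = NULL, seed = NULL, ar1 = 0,
                             neuron_id = "n1", pathway = "A") {
  tr <- session$trials
  max_lag <- max(vapply(truth$specs, function(s) {
    if (s$kind == "event") s$basis$window[2] else 0
  }, numeric(1)))
  t_last <- max(c(tr$t_cue, tr$t_init, tr$t_choice, tr$t_outcome), na.rm = TRUE)
  if (is.null(duration)) duration <- t_last + max_lag + 1
  if (t_last > duration) {
    stop("session events extend beyond the requested trace duration",
         call. = FALSE)
  }
  frame_times <- seq(0, duration, by = 1 / frame_rate)
  values <- rep(truth$intercept, length(frame_times))
  for (nm in names(truth$specs)) {
    spec <- truth$specs[[nm]]
    if (spec$kind == "event") {
      gam <- truth$gammas[[nm]]
      if (all(gam == 0)) next
      occ <- event_occurrences(session, latents, nm)
      w <- spec$basis$window
      for (i in seq_along(occ$times)) {
        lag <- frame_times - occ$times[i]
        inside <- which(lag >= w[1] & lag <= w[2])
        if (!length(inside)) next
        values[inside] <- values[inside] + occ$scale[i] *
          as.numeric(build_spline_basis(spec$basis, lag[inside]) %*% gam)
      }
    } else {
      g <- truth$gains[[nm]]
      if (g == 0) next
      x <- continuous_predictor_series(session, latents, nm, frame_times,
                                       head_velocity)
      values <- values + g * x
    }
  }
  noiseless <- values
  if (truth$noise_sigma > 0) {
    noise <- with_seed(seed, {
      e <- stats::rnorm(length(values), 0, truth$noise_sigma)
      if (ar1 != 0) as.numeric(stats::filter(e, ar1, method = "recursive"))
      else e
    })
    values <- values + noise
  }
  structure(
    list(frame_times = frame_times, values = values, noiseless = noiseless,
         neuron_id = neuron_id, pathway = pathway, frame_rate = frame_rate,
         truth = truth),
    class = "calcium_trace"
  )
}

#' @export
#' @method print calcium_trace
print.calcium_trace <- function(x, ...) {
  cat(sprintf(
    "Calcium trace '%s' (pathway %s): %d frames at %g Hz, sd = %.3f dF/F\n",
    x$neuron_id, x$pathway, length(x$values), x$frame_rate,
    stats::sd(x$values)))
  if (!is.null(x$truth)) {
    cat(sprintf("  synthetic; tuned predictors: %s; noise sigma = %g\n",
                if (length(x$truth$tuned)) paste(x$truth$tuned, collapse = ", ")
                else "(none)", x$truth$noise_sigma))
  }
  invisible(x)
}

#' Synthesize a head-velocity series for a session
#'
#' Smooth stochastic velocity (exponentially smoothed positive noise around a
#' baseline) with movement bursts around initiation and choice pokes,
#' sampled on the imaging frame grid. With all amplitudes zero the animal is
#' stationary (zero velocity).
#'
#' @param session a `bandit_session`.
#' @param frame_rate sampling rate (Hz).
#' @param duration series duration (s); defaults to cover the session.
#' @param baseline mean baseline speed (cm/s).
#' @param burst_amp peak amplitude of poke-locked bursts (cm/s).
#' @param burst_sd temporal SD of each burst (s).
#' @param noise_sd SD of the baseline fluctuation (cm/s).
#' @param smooth_tau smoothing time constant (s).
#' @param seed integer seed.
#' @return list with `times` and `values` (velocity, never negative).
#' @export
synthesize_head_velocity <- function(session, frame_rate = 20,
                                     duration = NULL, baseline = 2,
                                     burst_amp = 15, burst_sd = 0.15,
                                     noise_sd = 1, smooth_tau = 0.25,
                                     seed = NULL) {
  tr <- session$trials
  t_last <- max(c(tr$t_cue, tr$t_init, tr$t_choice, tr$t_outcome),
                na.rm = TRUE)
  if (is.null(duration)) duration <- t_last + 5
  times <- seq(0, duration, by = 1 / frame_rate)
  v <- rep(baseline, length(times))
  pokes <- c(tr$t_init, tr$t_choice)
  pokes <- pokes[!is.na(pokes)]
  for (p in pokes) {
    v <- v + burst_amp * exp(-(times - p)^2 / (2 * burst_sd^2))
  }
  if (noise_sd > 0) {
    v <- v + with_seed(seed, {
      e <- stats::rnorm(length(times), 0, noise_sd)
      a <- exp(-1 / (smooth_tau * frame_rate))
      as.numeric(stats::filter(e * sqrt(1 - a^2), a, method = "recursive"))
    })
  }
  list(times = times, values = pmax(v, 0))
}
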