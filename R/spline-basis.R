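#' Cubic B-spline basis specification for an event kernel
#'
#' Event-tethered kernels are represented as weighted sums of cubic B-spline
#' basis functions over a fixed lag window around the event. Knots are
#' uniformly spaced with clamped (repeated) boundary knots, so the bases form
#' a partition of unity on the window's interior.
#'
#' @param window numeric length-2, `c(lag_min, lag_max)` in seconds relative
#'   to the event.
#' @param n_basis number of basis functions (>= 4; the cubic degree requires
#'   at least 4).
#' @return an object of class `spline_basis_spec` with the knot vector.
#' @export
spline_basis_spec <- function(window, n_basis) {
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be c(lag_min, lag_max) with lag_min < lag_max",
         call. = FALSE)
  }
  if (n_basis < 4) stop("n_basis must be >= 4 for cubic splines", call. = FALSE)
  lo <- window[1]; hi <- window[2]
  interior <- if (n_basis > 4) {
    seq(lo, hi, length.out = n_basis - 2)[2:(n_basis - 3)]
  } else numeric(0)
  knots <- c(rep(lo, 4), interior, rep(hi, 4))
  structure(list(window = c(lo, hi), n_basis = as.integer(n_basis),
                 degree = 3L, knots = knots),
            class = "spline_basis_spec")
}

#' Evaluate a cubic B-spline basis on a lag grid
#'
#' @param spec a [spline_basis_spec()].
#' @param lags numeric vector of lags (s); lags outside the window evaluate
#'   to zero in every basis function.
#' @return matrix `length(lags) x n_basis`.
#' @examples
#' sp <- spline_basis_spec(c(-1, 2), 7)
#' B <- build_spline_basis(sp, seq(-1, 2, by = 0.1))
#' range(rowSums(B))  # partition of unity
#' @export
build_spline_basis <- function(spec, lags) {
  B <- matrix(0, nrow = length(lags), ncol = spec$n_basis)
  inside <- lags >= spec$window[1] & lags <= spec$window[2]
  if (any(inside)) {
    B[inside, ] <- splines::splineDesign(spec$knots, lags[inside], ord = 4)
  }
  colnames(B) <- paste0("b", seq_len(spec$n_basis))
  B
}

#' Declare an encoding-model predictor
#'
#' @param name predictor name.
#' @param kind `"event"` (spline-expanded kernel) or `"continuous"` (single
#'   column).
#' @param group predictor group used for grouped tuning indices:
#'   `"pre_outcome"`, `"outcome"`, `"internal_value"` or `"movement"`.
#' @param window,n_basis basis window and size (event predictors only).
#' @return an object of class `predictor_spec`.
#' @export
predictor_spec <- function(name, kind = c("event", "continuous"),
                           group = c("pre_outcome", "outcome",
                                     "internal_value", "movement"),
                           window = NULL, n_basis = NULL) {
  kind <- match.arg(kind)
  group <- match.arg(group)
  basis <- NULL
  if (kind == "event") {
    if (is.null(window) || is.null(n_basis)) {
      stop("event predictors need window and n_basis", call. = FALSE)
    }
    basis <- spline_basis_spec(window, n_basis)
  }
  structure(list(name = name, kind = kind, group = group, basis = basis),
            class = "predictor_spec")
}

#' Default predictor set for the encoding model
#'
#' Task events (cue, initiation, choice) carry 7 bases over a \[-1, +2\] s
#' window; outcome-tethered predictors (reward O+, unrewarded O-, their
#' choice-side interactions ChxO+/-, and signed reward-prediction-error
#' kernels RPE+/-) carry 10 bases over \[-0.5, +6\] s, wide enough for the
#' slow persistent transients that follow reward omission. Continuous
#' predictors are the Q-value difference and sum (dQ, sQ; piecewise constant,
#' stepping at outcome), the local reward rate (uL/min, stepping at trial
#' start) and head velocity.
#'
#' @param event_window,event_n_basis basis for cue/init/choice.
#' @param outcome_window,outcome_n_basis basis for outcome-tethered kernels.
#' @return named list of [predictor_spec()]s.
#' @export
default_predictor_specs <- function(event_window = c(-1, 2),
                                    event_n_basis = 7,
                                    outcome_window = c(-0.5, 6),
                                    outcome_n_basis = 10) {
  ev <- function(name, group) {
    predictor_spec(name, "event", group, event_window, event_n_basis)
  }
  ov <- function(name, group) {
    predictor_spec(name, "event", group, outcome_window, outcome_n_basis)
  }
  cont <- function(name, group) predictor_spec(name, "continuous", group)
  specs <- list(
    ev("cue", "pre_outcome"), ev("init", "pre_outcome"),
    ev("choice", "pre_outcome"),
    ov("o_plus", "outcome"), ov("o_minus", "outcome"),
    ov("ch_o_plus", "outcome"), ov("ch_o_minus", "outcome"),
    ov("rpe_plus", "internal_value"), ov("rpe_minus", "internal_value"),
    cont("dQ", "internal_value"), cont("sQ", "internal_value"),
    cont("reward_rate", "internal_value"), cont("head_velocity", "movement")
  )
  stats::setNames(specs, vapply(specs, function(s) s$name, character(1)))
}
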