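## Event times and per-event scales for each event predictor. The scale is 1
## for plain events and the signed prediction-error magnitude for RPE
## kernels. Choice-side interactions are coded contralateral to the recording
## hemisphere.
event_occurrences <- function(session, latents, name) {
  tr <- session$trials
  completed <- tr$choice %in% c("left", "right")
  contra_side <- if (identical(session$hemisphere, "right")) "left" else "right"
  rewarded <- completed & tr$outcome == "reward"
  unrewarded <- completed & tr$outcome != "reward"
  contra <- tr$choice == contra_side
  switch(name,
    cue = list(times = tr$t_cue, scale = rep(1, nrow(tr))),
    init = { t <- tr$t_init[!is.na(tr$t_init)]
             list(times = t, scale = rep(1, length(t))) },
    choice = { t <- tr$t_choice[completed]
               list(times = t, scale = rep(1, length(t))) },
    o_plus = { t <- tr$t_outcome[rewarded]
               list(times = t, scale = rep(1, length(t))) },
    o_minus = { t <- tr$t_outcome[unrewarded]
                list(times = t, scale = rep(1, length(t))) },
    ch_o_plus = { sel <- rewarded & contra
                  list(times = tr$t_outcome[sel],
                       scale = rep(1, sum(sel))) },
    ch_o_minus = { sel <- unrewarded & contra
                   list(times = tr$t_outcome[sel],
                        scale = rep(1, sum(sel))) },
    rpe_plus = ,
    rpe_minus = {
      if (is.null(latents) || is.null(latents$rpe)) {
        stop("RPE predictors need fitted latents", call. = FALSE)
      }
      rpe <- latents$rpe
      t_out <- tr$t_outcome[completed]
      if (length(t_out) != length(rpe)) {
        stop("latents are not aligned to the session's completed trials",
             call. = FALSE)
      }
      sel <- if (name == "rpe_plus") rpe > 0 else rpe < 0
      list(times = t_out[sel], scale = abs(rpe[sel]))
    },
    stop(sprintf("unknown event predictor '%s'", name), call. = FALSE)
  )
}

## Continuous predictor sampled at frame times. dQ/sQ are piecewise constant,
## stepping to the post-update value at each completed trial's outcome;
## reward rate steps at trial start; head velocity is linearly interpolated.
continuous_predictor_series <- function(session, latents, name, frame_times,
                                        head_velocity = NULL,
                                        reward_rate = NULL) {
  tr <- session$trials
  completed <- tr$choice %in% c("left", "right")
  switch(name,
    dQ = ,
    sQ = {
      if (is.null(latents)) stop("dQ/sQ need fitted latents", call. = FALSE)
      t_out <- tr$t_outcome[completed]
      post <- if (name == "dQ") latents$dQ_post else latents$sQ_post
      idx <- findInterval(frame_times, t_out)
      c(0, post)[idx + 1]
    },
    reward_rate = {
      rr <- if (is.null(reward_rate)) local_reward_rate(session) else reward_rate
      idx <- pmax(findInterval(frame_times, tr$t_cue), 1L)
      rr[idx]
    },
    head_velocity = {
      if (is.null(head_velocity)) {
        stop("head_velocity predictor requires a velocity series", call. = FALSE)
      }
      stats::approx(head_velocity$times, head_velocity$values,
                    xout = frame_times, rule = 2)$y
    },
    stop(sprintf("unknown continuous predictor '%s'", name), call. = FALSE)
  )
}

## One event predictor's spline-expanded columns: sum over occurrences of
## scale_n * f_k(t - t_n).
event_design_columns <- function(spec, frame_times, occ) {
  X <- matrix(0, nrow = length(frame_times), ncol = spec$basis$n_basis)
  w <- spec$basis$window
  for (i in seq_along(occ$times)) {
    lag <- frame_times - occ$times[i]
    inside <- which(lag >= w[1] & lag <= w[2])
    if (!length(inside)) next
    X[inside, ] <- X[inside, ] +
      occ$scale[i] * build_spline_basis(spec$basis, lag[inside])
  }
  X
}

#' Build the time-resolved design matrix of the encoding model
#'
#' Pairs spline-expanded event columns with continuous columns on a common
#' imaging frame grid. Each event predictor contributes `n_basis` columns
#' holding `sum_n scale_n f_k(t - t_n)` over its occurrences; continuous
#' predictors contribute one column each. Every frame is annotated with its
#' trial and its 200-ms temporal chunk, the granularity at which
#' cross-validation folds are later assigned.
#'
#' @param session a `bandit_session`.
#' @param frame_times imaging frame timestamps (s), strictly increasing.
#' @param specs named list of [predictor_spec()]s
#'   (default [default_predictor_specs()]).
#' @param latents per-trial latents of the session's completed trials, as
#'   returned by [q_trajectory()] (needed for dQ/sQ/RPE predictors).
#' @param head_velocity list with `times` and `values`, interpolated to the
#'   frame grid (needed when a `head_velocity` predictor is present).
#' @param reward_rate optional per-trial reward rate; computed with
#'   [local_reward_rate()] when absent.
#' @param chunk_ms temporal chunk length (ms) for cross-validation grouping.
#' @return an object of class `encoding_design`: list with the matrix `X`,
#'   `frame_times`, `col_meta` (predictor, kind, group and basis index per
#'   column), `trial_id` and `chunk_id` per frame, and the predictor specs.
#' @export
build_design_matrix <- function(session, frame_times,
                                specs = default_predictor_specs(),
                                latents = NULL, head_velocity = NULL,
                                reward_rate = NULL, chunk_ms = 200) {
  stopifnot(all(diff(frame_times) > 0))
  dt <- diff(frame_times)
  if (any(dt > 2 * stats::median(dt))) {
    warning("frame gaps exceeding 2 frame periods detected", call. = FALSE)
  }
  cols <- list()
  meta <- list()
  for (spec in specs) {
    if (spec$kind == "event") {
      occ <- event_occurrences(session, latents, spec$name)
      X <- event_design_columns(spec, frame_times, occ)
      colnames(X) <- paste0(spec$name, "_b", seq_len(ncol(X)))
      cols[[spec$name]] <- X
      meta[[spec$name]] <- data.frame(
        column = colnames(X), predictor = spec$name, kind = "event",
        group = spec$group, basis_index = seq_len(ncol(X)),
        stringsAsFactors = FALSE
      )
    } else {
      x <- continuous_predictor_series(session, latents, spec$name,
                                       frame_times, head_velocity,
                                       reward_rate)
      cols[[spec$name]] <- matrix(x, ncol = 1,
                                  dimnames = list(NULL, spec$name))
      meta[[spec$name]] <- data.frame(
        column = spec$name, predictor = spec$name, kind = "continuous",
        group = spec$group, basis_index = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  X <- do.call(cbind, cols)
  col_meta <- do.call(rbind, meta)
  rownames(col_meta) <- NULL
  t_cue <- session$trials$t_cue
  trial_id <- pmax(findInterval(frame_times, t_cue), 1L)
  chunk_s <- chunk_ms / 1000
  ## epsilon keeps frames on exact chunk boundaries in the earlier chunk
  chunk_raw <- floor((frame_times - frame_times[1]) / chunk_s - 1e-9)
  chunk_id <- match(chunk_raw, unique(chunk_raw))
  structure(
    list(X = X, frame_times = frame_times, col_meta = col_meta,
         trial_id = trial_id, chunk_id = chunk_id, specs = specs,
         chunk_ms = chunk_ms),
    class = "encoding_design"
  )
}

#' @export
#' @method print encoding_design
print.encoding_design <- function(x, ...) {
  cat(sprintf(
    "Encoding design: %d frames x %d columns (%d predictors), %d trials, %d chunks of %d ms\n",
    nrow(x$X), ncol(x$X), length(x$specs), max(x$trial_id),
    max(x$chunk_id), x$chunk_ms))
  invisible(x)
}

#' Drop predictors from a design matrix
#'
#' Removes all columns belonging to the named predictors (or to the named
#' groups), yielding the reduced design used for tuning indices.
#'
#' @param design an `encoding_design`.
#' @param predictors character vector of predictor names to drop.
#' @param groups character vector of predictor groups to drop.
#' @return the reduced `encoding_design`.
#' @export
drop_predictors <- function(design, predictors = NULL, groups = NULL) {
  drop <- design$col_meta$predictor %in% predictors |
    design$col_meta$group %in% groups
  if (all(drop)) {
    ## intercept-only reduced model: keep an explicit empty design
    design$X <- design$X[, 0, drop = FALSE]
    design$col_meta <- design$col_meta[0, ]
    design$specs <- design$specs[0]
    return(design)
  }
  design$X <- design$X[, !drop, drop = FALSE]
  design$col_meta <- design$col_meta[!drop, ]
  rownames(design$col_meta) <- NULL
  kept <- unique(design$col_meta$predictor)
  design$specs <- design$specs[names(design$specs) %in% kept]
  design
}
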