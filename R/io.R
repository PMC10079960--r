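trial_table_columns <- c("session_id", "animal_id", "trial_index",
                         "block_index", "rewarded_side", "choice", "outcome",
                         "t_cue", "t_init", "t_choice", "t_outcome",
                         "light_on", "light_epoch")

#' Write sessions to a trial-table file
#'
#' One row per trial, tab-delimited, with the standard header (session and
#' animal ids, trial and block indices, rewarded side, choice, outcome,
#' event timestamps in seconds, light flags). The write/read round trip is
#' lossless for the trial records.
#'
#' @param sessions a `bandit_session` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(sessions, path) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  tab <- do.call(rbind, lapply(sessions, function(s) {
    s$trials[, trial_table_columns]
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sessions from a trial-table file
#'
#' Validates the schema (all required columns, known categorical
#' vocabularies, monotone timestamps within each session) and splits rows
#' into one session per `session_id`. Errors name the offending column or
#' row.
#'
#' @param path trial-table file.
#' @param config [task_config()] attached to the returned sessions.
#' @return list of `bandit_session` objects.
#' @export
read_trial_table <- function(path, config = task_config()) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(trial_table_columns, names(tab))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_side <- which(!tab$rewarded_side %in% c("left", "right"))
  if (length(bad_side)) {
    stop("invalid rewarded_side at row(s): ",
         paste(utils::head(bad_side, 5), collapse = ", "), call. = FALSE)
  }
  bad_choice <- which(!tab$choice %in% c("left", "right", "omission"))
  if (length(bad_choice)) {
    stop("invalid choice at row(s): ",
         paste(utils::head(bad_choice, 5), collapse = ", "), call. = FALSE)
  }
  bad_outcome <- which(!tab$outcome %in% c("reward", "punish", "none"))
  if (length(bad_outcome)) {
    stop("invalid outcome at row(s): ",
         paste(utils::head(bad_outcome, 5), collapse = ", "), call. = FALSE)
  }
  tab$light_on <- as.logical(tab$light_on)
  lapply(split(tab, tab$session_id), function(st) {
    st <- st[order(st$trial_index), ]
    rownames(st) <- NULL
    non_mono <- which(diff(st$t_cue) <= 0)
    if (length(non_mono)) {
      stop(sprintf("non-monotone t_cue in session '%s' at row %d",
                   st$session_id[1], non_mono[1] + 1L), call. = FALSE)
    }
    structure(list(trials = st, config = config, seed = NA_integer_,
                   policy = "unknown", agent_params = list(),
                   hemisphere = "left"),
              class = "bandit_session")
  })
}

#' Write calcium traces to a trace file
#'
#' Tab-delimited matrix (frame_times plus one dF/F column per neuron) with a
#' JSON sidecar (`<path>.json`) holding frame rate, pathway labels and, for
#' synthetic traces, the ground-truth summary.
#'
#' @param traces list of `calcium_trace`s sharing a frame grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_file <- function(traces, path) {
  ft <- traces[[1]]$frame_times
  for (tr in traces) {
    if (!isTRUE(all.equal(tr$frame_times, ft))) {
      stop("traces do not share a frame grid", call. = FALSE)
    }
  }
  m <- cbind(frame_times = ft,
             sapply(traces, function(tr) tr$values))
  colnames(m) <- c("frame_times",
                   vapply(traces, function(tr) tr$neuron_id, character(1)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(
    frame_rate = traces[[1]]$frame_rate,
    neurons = lapply(traces, function(tr) {
      list(neuron_id = tr$neuron_id, pathway = tr$pathway,
           synthetic = !is.null(tr$truth),
           tuned = if (!is.null(tr$truth)) tr$truth$tuned else NULL,
           noise_sigma = if (!is.null(tr$truth)) tr$truth$noise_sigma
                         else NULL)
    })
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a trace file written by [write_trace_file()]
#'
#' @param path trace file path.
#' @return list of `calcium_trace` objects (without ground truth).
#' @export
read_trace_file <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = FALSE)
  } else NULL
  ids <- setdiff(colnames(m), "frame_times")
  lapply(seq_along(ids), function(i) {
    info <- if (!is.null(meta)) meta$neurons[[i]] else NULL
    structure(
      list(frame_times = m$frame_times, values = m[[ids[i]]],
           noiseless = NULL, neuron_id = ids[i],
           pathway = if (!is.null(info)) info$pathway else NA_character_,
           frame_rate = if (!is.null(meta)) meta$frame_rate
                        else 1 / stats::median(diff(m$frame_times)),
           truth = NULL),
      class = "calcium_trace"
    )
  })
}

#' Write kernel estimates as a tidy table
#'
#' @param kernels a `kernel_estimate` or list of them (optionally named by
#'   neuron).
#' @param path output path (tab-delimited: neuron, predictor, lag, value).
#' @return `path`, invisibly.
#' @export
write_kernel_table <- function(kernels, path) {
  if (inherits(kernels, "kernel_estimate")) kernels <- list(kernels)
  ids <- names(kernels)
  if (is.null(ids)) ids <- paste0("n", seq_along(kernels))
  tab <- do.call(rbind, lapply(seq_along(kernels), function(i) {
    cbind(neuron = ids[i], as.data.frame(kernels[[i]]))
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The full set of pipeline constants in one structured list: task schedule
#' (85% outcome probability, 8-of-10 reversal rule), agent parameters,
#' encoding-model settings (elastic-net mixing 0.95, 50 folds, 200 ms
#' chunks, 5% FVE and tuning thresholds), bootstrap settings (10,000
#' samples) and seeds. Serializable to YAML with [write_run_config()].
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    task = list(p_outcome = 0.85, reward_volume = 12, switch_n_correct = 8,
                switch_window = 10, n_trials = 500),
    agents = list(policy = "qforget",
                  params = list(alpha = 0.6, beta = 5, phi = 0.2)),
    encoding = list(alpha_mixing = 0.95, n_folds = 50, chunk_ms = 200,
                    fve_threshold = 0.05, tuning_threshold = 0.05,
                    frame_rate = 20,
                    event_window = c(-1, 2), event_n_basis = 7,
                    outcome_window = c(-0.5, 6), outcome_n_basis = 10),
    bootstrap = list(n_boot = 10000, conf = 0.95),
    seeds = list(task = 1L, encoding = 2L, bootstrap = 3L)
  ), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config` list (defaults filled
#'   in for missing sections); `write_run_config()` returns `path`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (section in names(raw)) {
    for (key in names(raw[[section]])) {
      cfg[[section]][[key]] <- raw[[section]][[key]]
    }
  }
  if (is.null(raw$seeds)) {
    stop("run config must set explicit seeds", call. = FALSE)
  }
  cfg
}

#' @rdname read_run_config
#' @param config a `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
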