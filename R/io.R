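#' Write trial records as a per-epoch CSV
#'
#' One row per epoch: trial, epoch, observation, action (the control taken
#' into the epoch; NA for the first), the epoch-final expected precision and
#' the epoch free energy.
#'
#' @param records List of `trial_record` objects (e.g. from
#'   [run_session()] with `keep_records = TRUE`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    T <- length(r$observations)
    it <- length(r$gamma_trace) %/% T
    data.frame(
      trial = r$trial, epoch = seq_len(T), observation = r$observations,
      action = c(NA_integer_, r$actions),
      gamma = r$gamma_trace[seq_len(T) * it],
      free_energy = r$free_energy
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write precision traces as a long-format CSV
#'
#' One row per variational iteration: trial, iteration, gamma.
#'
#' @param records List of `trial_record` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gamma_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(trial = r$trial, iteration = seq_along(r$gamma_trace),
               gamma = r$gamma_trace)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write dopamine replay traces as a long-format CSV
#'
#' One row per bin: condition, iteration, signal, and (when spike counts are
#' supplied) the mean spike count.
#'
#' @param traces Named list of [deconvolve_precision()] results.
#' @param path Output CSV path.
#' @param spikes Optional named list of [simulate_spikes()] results aligned
#'   with `traces`.
#' @return `path`, invisibly.
#' @export
write_dopamine_csv <- function(traces, path, spikes = NULL) {
  rows <- lapply(names(traces), function(nm) {
    df <- data.frame(condition = nm,
                     iteration = seq_along(traces[[nm]]$signal),
                     signal = traces[[nm]]$signal)
    df$mean_spikes <- if (!is.null(spikes) && !is.null(spikes[[nm]])) {
      spikes[[nm]]$mean_counts
    } else {
      NA_real_
    }
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Maps a YAML document onto the arguments of the experiment drivers. The
#' recognized top-level keys are `task` (`high`, `low`, or `p1`/`p2` with
#' `single_cue: true`, plus optional `cue_probs`), `agent` (any
#' [agent_config()] argument), and the experiment sizes `n_sessions`,
#' `n_trials`, `n_trials_lesion`, `n_trials_restore`, `n_blocks`, `clamp`,
#' `session_index`, `seed`.
#'
#' @param path YAML file path.
#' @return List with `task` (a [conditioning_task()]), `cfg` (an
#'   [agent_config()]) and `args` (remaining experiment arguments).
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read experiment configs")
  }
  doc <- yaml::read_yaml(path)
  tsk <- doc$task
  if (is.null(tsk)) tsk <- list()
  if (isTRUE(tsk$single_cue)) {
    probs <- single_cue_contingencies(
      p1 = tsk$p1 %||% 0, p2 = tsk$p2 %||% 0.5)
    cue_probs <- tsk$cue_probs %||% c(1, 0)
  } else {
    probs <- make_contingencies(high = tsk$high %||% 0.8,
                                low = tsk$low %||% 0.2)
    cue_probs <- tsk$cue_probs %||% c(0.5, 0.5)
  }
  task <- conditioning_task(probs, cue_probs = as.numeric(cue_probs))
  cfg <- do.call(agent_config, doc$agent %||% list())
  args <- doc[setdiff(names(doc), c("task", "agent"))]
  list(task = task, cfg = cfg, args = args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
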