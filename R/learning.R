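#' Accumulate observation evidence into the A-matrix beliefs
#'
#' Hebbian-style Dirichlet update: the concentration of the observed outcome
#' row is incremented by the state posterior, `a_post[o_t, j] += s_hat[j]`,
#' adding exactly unit mass per epoch. Expected precision never enters the
#' parameter updates: accumulation depends only on the observation and the
#' state posterior.
#'
#' @param beliefs A [dirichlet_beliefs()] object.
#' @param o_t Observed outcome index.
#' @param s_hat State posterior for the epoch (simplex vector).
#' @param refresh Recompute the cached expectation matrices (default `TRUE`;
#'   set `FALSE` when batching updates and refreshing once at the end).
#' @return The updated beliefs.
#' @export
accumulate_observation_counts <- function(beliefs, o_t, s_hat,
                                          refresh = TRUE) {
  if (o_t < 1L || o_t > nrow(beliefs$a_post)) stop("invalid outcome index")
  beliefs$a_post[o_t, ] <- beliefs$a_post[o_t, ] + s_hat
  if (refresh) beliefs <- refresh_beliefs(beliefs)
  beliefs
}

#' Accumulate transition evidence into the B-matrix beliefs
#'
#' Outer-product Dirichlet update for the matrix of the action actually
#' taken: `b_post(a_prev) += s_hat_t %o% s_hat_prev`. Only that control's
#' matrix changes (the Iverson bracket over actions), and exactly unit mass
#' is added per transition.
#'
#' @param beliefs A [dirichlet_beliefs()] object.
#' @param a_prev Control index of the action taken.
#' @param s_hat_t State posterior after the transition.
#' @param s_hat_prev State posterior before the transition.
#' @param refresh Recompute cached expectation matrices (default `TRUE`).
#' @return The updated beliefs.
#' @export
accumulate_transition_counts <- function(beliefs, a_prev, s_hat_t,
                                         s_hat_prev, refresh = TRUE) {
  if (a_prev < 1L || a_prev > length(beliefs$b_post)) {
    stop("invalid control index")
  }
  beliefs$b_post[[a_prev]] <- beliefs$b_post[[a_prev]] +
    tcrossprod(s_hat_t, s_hat_prev)
  if (refresh) beliefs <- refresh_beliefs(beliefs)
  beliefs
}

#' Apply a completed trial's evidence to the Dirichlet beliefs
#'
#' Runs the observation update over all epochs and the transition update over
#' all transitions of the trial, using the final (most informed) per-epoch
#' state posteriors. Updates are applied once, at trial end, so within-trial
#' revisions of the state posteriors are not double counted. The returned
#' beliefs carry, as attribute `"param_complexity"`, the Dirichlet KL
#' divergence of the updated against the pre-trial concentrations — the
#' parameter-complexity increment this trial contributes to the free energy.
#'
#' @param beliefs A [dirichlet_beliefs()] object.
#' @param record A trial record from [run_trial()] (uses `$observations`,
#'   `$actions`, `$s_hat_final`).
#' @param learn_A,learn_B Flags enabling the two updates.
#' @return The updated beliefs (caches refreshed).
#' @export
end_of_trial_update <- function(beliefs, record, learn_A = TRUE,
                                learn_B = TRUE) {
  T <- length(record$observations)
  s_hat <- record$s_hat_final
  a_pre <- beliefs$a_post
  b_pre <- beliefs$b_post
  if (learn_A) {
    for (t in seq_len(T)) {
      beliefs <- accumulate_observation_counts(
        beliefs, record$observations[t], s_hat[, t], refresh = FALSE)
    }
  }
  if (learn_B) {
    for (t in seq_len(T - 1L)) {
      beliefs <- accumulate_transition_counts(
        beliefs, record$actions[t], s_hat[, t + 1L], s_hat[, t],
        refresh = FALSE)
    }
  }
  beliefs <- refresh_beliefs(beliefs)
  pc <- dirichlet_kl(beliefs$a_post, a_pre)
  for (u in seq_along(b_pre)) {
    pc <- pc + dirichlet_kl(beliefs$b_post[[u]], b_pre[[u]])
  }
  attr(beliefs, "param_complexity") <- pc
  beliefs
}

#' Append per-trial belief snapshots to a JSON-lines log
#'
#' One gzip-compressed JSON object per trial holding the trial index and the
#' posterior concentration arrays, from which learning curves can be
#' reconstructed offline.
#'
#' @param beliefs A [dirichlet_beliefs()] object.
#' @param trial Trial index.
#' @param path Path to a `.jsonl.gz` file (created on first call).
#' @return `path`, invisibly.
#' @export
write_belief_log <- function(beliefs, trial, path) {
  con <- gzfile(path, open = "ab")
  on.exit(close(con))
  line <- jsonlite::toJSON(
    list(trial = trial, a_post = beliefs$a_post, b_post = beliefs$b_post),
    digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  writeLines(line, con)
  invisible(path)
}
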