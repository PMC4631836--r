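#' Declarative precision-clamp schedule
#'
#' A clamp schedule fixes expected precision at a given value during selected
#' epochs of selected trials, optionally only on trials where a particular
#' action was taken at the choice point. During clamped epochs the precision
#' update is skipped entirely, so the precision trace shows a plateau at the
#' clamp value. Clamps act on the precision pathway only — state updates and
#' learning receive the clamped value but are otherwise untouched.
#'
#' @param value Positive clamp value for expected precision.
#' @param epochs Integer vector of epochs to clamp, or `"all"`.
#' @param trials `NULL` (all trials) or an inclusive `c(first, last)` range.
#' @param contingent_on `NULL`, or a control index: the clamp applies only on
#'   trials where that control was taken at the choice transition.
#' @return Object of class `clamp_schedule`.
#' @export
clamp_schedule <- function(value, epochs = "all", trials = NULL,
                           contingent_on = NULL) {
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  if (!identical(epochs, "all")) {
    epochs <- as.integer(epochs)
    stopifnot(all(epochs >= 1L))
  }
  if (!is.null(trials)) {
    trials <- as.integer(trials)
    stopifnot(length(trials) == 2L, trials[1L] <= trials[2L])
  }
  if (!is.null(contingent_on)) {
    contingent_on <- as.integer(contingent_on)
    stopifnot(contingent_on >= 1L)
  }
  structure(
    list(value = value, epochs = epochs, trials = trials,
         contingent_on = contingent_on),
    class = "clamp_schedule"
  )
}

#' Simulated dopamine depletion
#'
#' Clamps expected precision to a low value at every epoch of every trial in
#' range, rendering policy selection nearly outcome-insensitive while
#' leaving state estimation and Dirichlet learning to proceed.
#'
#' @param value Clamp value (default 0.1).
#' @param trials Optional inclusive trial range.
#' @return A [clamp_schedule()].
#' @export
depletion_schedule <- function(value = 0.1, trials = NULL) {
  clamp_schedule(value = value, epochs = "all", trials = trials)
}

#' Simulated midbrain stimulation at outcome time
#'
#' Clamps expected precision at the final epoch of each trial to a high
#' value, optionally only on trials where a given action was selected. The
#' default clamp of 16 far exceeds the unclamped ceiling
#' `prec_shape / prec_rate`, which is what forces the agent to explain the
#' anomalously high precision by inferring a valuable (win) outcome state.
#'
#' @param value Clamp value (default 16).
#' @param final_epoch The trial's final epoch index (default 6).
#' @param contingent_on Optional control index the clamp is contingent on.
#' @param trials Optional inclusive trial range.
#' @return A [clamp_schedule()].
#' @export
stimulation_schedule <- function(value = 16, final_epoch = 6,
                                 contingent_on = NULL, trials = NULL) {
  clamp_schedule(value = value, epochs = as.integer(final_epoch),
                 trials = trials, contingent_on = contingent_on)
}

#' Resolve a schedule to a clamp value for one epoch
#'
#' @param schedule A [clamp_schedule()], a list of them (first match wins),
#'   or `NULL`.
#' @param trial Trial index.
#' @param epoch Epoch index.
#' @param choice_action Control taken at the choice transition this trial
#'   (`NA` if not yet taken); used for action-contingent clamps.
#' @return The clamp value, or `NULL` when no clamp applies.
#' @export
clamp_value <- function(schedule, trial, epoch, choice_action = NA) {
  if (is.null(schedule)) return(NULL)
  if (inherits(schedule, "clamp_schedule")) schedule <- list(schedule)
  for (sch in schedule) {
    if (!identical(sch$epochs, "all") && !(epoch %in% sch$epochs)) next
    if (!is.null(sch$trials) &&
        (trial < sch$trials[1L] || trial > sch$trials[2L])) next
    if (!is.null(sch$contingent_on) &&
        (is.na(choice_action) || choice_action != sch$contingent_on)) next
    return(sch$value)
  }
  NULL
}

#' @export
print.clamp_schedule <- function(x, ...) {
  ep <- if (identical(x$epochs, "all")) "all epochs" else
    paste("epoch(s)", paste(x$epochs, collapse = ", "))
  tr <- if (is.null(x$trials)) "all trials" else
    sprintf("trials %d-%d", x$trials[1L], x$trials[2L])
  ct <- if (is.null(x$contingent_on)) "" else
    sprintf(", contingent on control %d", x$contingent_on)
  cat(sprintf("<clamp_schedule> gamma = %g at %s, %s%s\n",
              x$value, ep, tr, ct))
  invisible(x)
}
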