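#' Deconvolve a precision trace into a phasic dopamine signal
#'
#' Models the precision time series as the convolution of an innovation
#' (phasic firing) signal with an exponentially decaying kernel
#' `K(tau) = exp(-tau / tau_c)`, one bin per variational iteration, and
#' recovers the innovations by solving the lower-triangular system by
#' forward substitution: `d[1] = g[1]`, `d[n] = g[n] - exp(-1/tau_c) g[n-1]`.
#' The first bin has no history, so the first epoch shows a boundary
#' artifact; `drop_first_epoch` zeroes those bins for plotting/readout.
#'
#' @param gamma_trace Positive numeric vector, one precision value per
#'   variational iteration.
#' @param tau Kernel time constant in iterations (default 16).
#' @param iters_per_epoch Bins per epoch (used when dropping the first
#'   epoch).
#' @param drop_first_epoch Zero the first epoch's bins (default `FALSE`).
#' @return Object of class `dopamine_trace`: list with `signal` (the signed
#'   innovations), `gamma_trace`, `tau`, `iters_per_epoch`,
#'   `drop_first_epoch`.
#' @export
deconvolve_precision <- function(gamma_trace, tau = 16,
                                 iters_per_epoch = 16,
                                 drop_first_epoch = FALSE) {
  if (length(gamma_trace) == 0L) stop("empty precision trace")
  if (tau <= 0) stop("kernel time constant must be positive")
  kappa <- exp(-1 / tau)
  n <- length(gamma_trace)
  signal <- gamma_trace - kappa * c(0, gamma_trace[-n])
  if (drop_first_epoch) {
    signal[seq_len(min(iters_per_epoch, n))] <- 0
  }
  structure(
    list(signal = signal, gamma_trace = gamma_trace, tau = tau,
         iters_per_epoch = as.integer(iters_per_epoch),
         drop_first_epoch = drop_first_epoch),
    class = "dopamine_trace"
  )
}

#' Convolve an innovation signal with the exponential kernel
#'
#' The inverse of [deconvolve_precision()]: `g[n] = sum_{m <= n} d[m] *
#' exp(-(n - m) / tau)`. Convolving a deconvolved trace reconstructs the
#' original precision series (round-trip identity).
#'
#' @param signal Numeric innovation vector.
#' @param tau Kernel time constant in iterations.
#' @return Numeric vector of the same length.
#' @export
convolve_kernel <- function(signal, tau = 16) {
  if (tau <= 0) stop("kernel time constant must be positive")
  kappa <- exp(-1 / tau)
  out <- numeric(length(signal))
  acc <- 0
  for (n in seq_along(signal)) {
    acc <- kappa * acc + signal[n]
    out[n] <- acc
  }
  out
}

#' Per-epoch phasic responses of a dopamine trace
#'
#' Sums, within each epoch, the deconvolved innovation in excess of the tonic
#' level needed to sustain the running precision (`(1 - exp(-1/tau)) *
#' g[n-1]` per bin). The sum telescopes to the net change in expected
#' precision across the epoch, so a positive response is a within-epoch rise
#' in precision and a negative response a dip. The first epoch's response is
#' reported as `NA` when the trace was deconvolved with
#' `drop_first_epoch = TRUE`.
#'
#' @param trace A [deconvolve_precision()] result.
#' @param gamma0 Precision level preceding the first bin (default: the first
#'   traced value, making the first epoch's response zero bar the boundary
#'   artifact).
#' @return Numeric vector with one response per epoch.
#' @export
epoch_responses <- function(trace, gamma0 = NULL) {
  stopifnot(inherits(trace, "dopamine_trace"))
  g <- trace$gamma_trace
  it <- trace$iters_per_epoch
  n_epochs <- length(g) %/% it
  if (is.null(gamma0)) gamma0 <- g[1L]
  prev <- c(gamma0, g[seq_len(n_epochs - 1L) * it])
  resp <- g[seq_len(n_epochs) * it] - prev
  if (trace$drop_first_epoch) resp[1L] <- NA_real_
  resp
}

#' Poisson spike-count simulation of a dopamine trace
#'
#' Converts the deconvolved signal into per-bin firing rates and draws
#' independent Poisson counts per simulated trial. An innovation of 1
#' (unit expected precision) adds `scale` spikes per bin on top of the
#' `background` rate. With `dip_mode = "rectify"` (default) negative
#' innovations are clipped at zero before scaling, so dips never reduce the
#' rate below background; with `dip_mode = "subtract"` the signed signal is
#' scaled and the total rate floored at zero, allowing below-baseline dips.
#'
#' @param trace A [deconvolve_precision()] result.
#' @param scale Spikes per bin per unit innovation (default 4).
#' @param background Background rate, spikes per bin (default 4).
#' @param n_trials Number of simulated trials to average over (default 64).
#' @param dip_mode `"rectify"` or `"subtract"`; see Details.
#' @return List with `rate` (per-bin rate), `mean_counts` (per-bin mean over
#'   trials), `total_counts` (per-bin totals) and `n_trials`.
#' @export
simulate_spikes <- function(trace, scale = 4, background = 4, n_trials = 64,
                            dip_mode = c("rectify", "subtract")) {
  stopifnot(inherits(trace, "dopamine_trace"), scale >= 0, background >= 0,
            n_trials >= 1)
  dip_mode <- match.arg(dip_mode)
  rate <- switch(dip_mode,
    rectify = background + scale * pmax(trace$signal, 0),
    subtract = pmax(background + scale * trace$signal, 0)
  )
  counts <- matrix(stats::rpois(length(rate) * n_trials, rate),
                   nrow = length(rate))
  list(rate = rate, mean_counts = rowMeans(counts),
       total_counts = rowSums(counts), n_trials = as.integer(n_trials))
}

#' @export
print.dopamine_trace <- function(x, ...) {
  cat(sprintf(
    "<dopamine_trace> %d bins (%d per epoch), tau = %g iterations%s\n",
    length(x$signal), x$iters_per_epoch, x$tau,
    if (x$drop_first_epoch) ", first epoch dropped" else ""))
  invisible(x)
}
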