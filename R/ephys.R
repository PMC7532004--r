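#' Construct a current trace
#'
#' A time-stamped macroscopic current record. Agonist-evoked responses are
#' analyzed as positive magnitudes; recordings of inward current at negative
#' holding potential (negative deflections) are flipped with
#' \code{sign = -1}.
#'
#' @param time_s strictly increasing time stamps, seconds.
#' @param current_nA current samples, nanoamperes.
#' @param sign +1 if evoked responses are already positive, -1 to flip an
#'   inward-current record.
#' @param metadata optional free-text acquisition note.
#' @return An object of class \code{"current_trace"} (a data frame with
#'   columns \code{time_s}, \code{current_nA}).
#' @export
current_trace <- function(time_s, current_nA, sign = 1, metadata = "") {
  stopifnot(length(time_s) == length(current_nA), length(time_s) >= 2L,
            sign %in% c(-1, 1))
  if (any(!is.finite(time_s)) || any(diff(time_s) <= 0))
    stop("time_s must be finite and strictly increasing")
  if (any(!is.finite(current_nA))) stop("current_nA must be finite")
  structure(data.frame(time_s = time_s, current_nA = sign * current_nA),
            class = c("current_trace", "data.frame"),
            metadata = metadata)
}

window_idx <- function(trace, t_start, t_end) {
  if (t_start >= t_end) stop("window must have t_start < t_end")
  if (t_start < trace$time_s[1L] - 1e-12 ||
      t_end > trace$time_s[nrow(trace)] + 1e-12)
    stop(sprintf("window [%g, %g] s lies outside the trace span [%g, %g] s",
                 t_start, t_end, trace$time_s[1L], trace$time_s[nrow(trace)]))
  idx <- which(trace$time_s >= t_start & trace$time_s <= t_end)
  if (length(idx) == 0L) stop("window contains no samples")
  idx
}

#' Baseline-subtract a current trace
#'
#' Subtracts the mean current over a pre-application window so the holding
#' current reads zero.
#'
#' @param trace a [current_trace()].
#' @param t_start,t_end bounds of the baseline window (seconds), before
#'   agonist application.
#' @return The baseline-corrected trace.
#' @export
baseline_subtract <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "current_trace"))
  idx <- window_idx(trace, t_start, t_end)
  trace$current_nA <- trace$current_nA - mean(trace$current_nA[idx])
  trace
}

#' Peak response amplitude within a window
#'
#' Maximum of the (optionally moving-average smoothed) current in the window.
#' Smoothing defaults to none: the oocyte recordings this targets are low
#' noise.
#'
#' @inheritParams baseline_subtract
#' @param smooth_width_s moving-average width in seconds (0 = raw maximum).
#' @return Peak amplitude, nA.
#' @export
measure_peak <- function(trace, t_start, t_end, smooth_width_s = 0) {
  stopifnot(inherits(trace, "current_trace"), smooth_width_s >= 0)
  cur <- trace$current_nA
  if (smooth_width_s > 0) {
    dt <- median(diff(trace$time_s))
    k <- max(1L, round(smooth_width_s / dt))
    if (k > 1L)
      cur <- stats::filter(cur, rep(1 / k, k), sides = 2)
  }
  idx <- window_idx(trace, t_start, t_end)
  max(cur[idx], na.rm = TRUE)
}

#' Steady-state response amplitude
#'
#' Mean current over a late window of a long agonist application. The default
#' analysis window is the final 10\% of the application (see
#' [steady_state_window()]).
#'
#' @inheritParams baseline_subtract
#' @return Mean amplitude over the window, nA.
#' @export
measure_steady_state <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "current_trace"))
  idx <- window_idx(trace, t_start, t_end)
  mean(trace$current_nA[idx])
}

#' Default steady-state analysis window: the final 10% of an application
#'
#' @param t_start,t_end bounds of the agonist application window (seconds).
#' @param fraction tail fraction to average over (default 0.1).
#' @return Numeric vector \code{c(t_start, t_end)} of the analysis window.
#' @export
steady_state_window <- function(t_start, t_end, fraction = 0.1) {
  stopifnot(t_start < t_end, fraction > 0, fraction <= 1)
  c(t_end - fraction * (t_end - t_start), t_end)
}

#' Convert an amplitude to open probability
#'
#' Normalizes to the peak response to 1 mM GABA + 50 uM propofol, taken to
#' have peak open probability indistinguishable from 1. Values exceeding 1 by
#' at most 2\% (measurement scatter) are clipped to 1 with a warning; larger
#' excesses error.
#'
#' @param amplitude_nA response amplitude, nA, >= 0.
#' @param reference_peak_nA amplitude of the reference response, nA, > 0.
#' @return Open probability in [0, 1].
#' @export
to_popen <- function(amplitude_nA, reference_peak_nA) {
  if (any(amplitude_nA < 0)) stop("amplitude must be >= 0")
  if (!is.finite(reference_peak_nA) || reference_peak_nA <= 0)
    stop("reference peak must be > 0")
  p <- amplitude_nA / reference_peak_nA
  if (any(p > 1.02))
    stop(sprintf("amplitude exceeds the P_open = 1 reference by more than 2%% (ratio %.3f)",
                 max(p)))
  if (any(p > 1)) {
    warning("amplitude marginally exceeds the reference; clipping P_open to 1")
    p <- pmin(p, 1)
  }
  p
}

#' Percent desensitization of the steady-state current
#'
#' Percent reduction of the steady-state current produced by a modulator,
#' with the baseline steady-state current (e.g. at 1 mM GABA) defined as
#' 100\%.
#'
#' @param ss_baseline_nA baseline steady-state amplitude, > 0.
#' @param ss_with_modulator_nA steady-state amplitude with modulator, >= 0.
#' @return Percent reduction, 100 * (1 - with/baseline).
#' @export
percent_desensitization <- function(ss_baseline_nA, ss_with_modulator_nA) {
  if (any(ss_baseline_nA <= 0)) stop("baseline steady-state must be > 0")
  if (any(ss_with_modulator_nA < 0)) stop("amplitudes must be >= 0")
  100 * (1 - ss_with_modulator_nA / ss_baseline_nA)
}

#' Potentiation ratio of peak currents
#'
#' Ratio of the peak current with agonist + modulator to the peak with
#' agonist alone (the low-agonist potentiation assay uses 0.3 uM GABA,
#' P_open 0.05-0.1). A ratio near 1 indicates absence of potentiation.
#'
#' @param peak_agonist_nA peak with agonist alone, > 0.
#' @param peak_agonist_plus_modulator_nA peak with agonist + modulator.
#' @return Dimensionless ratio.
#' @export
potentiation_ratio <- function(peak_agonist_nA, peak_agonist_plus_modulator_nA) {
  if (any(peak_agonist_nA <= 0)) stop("agonist-alone peak must be > 0")
  peak_agonist_plus_modulator_nA / peak_agonist_nA
}
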