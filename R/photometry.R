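# Fibre-photometry preprocessing: isosbestic correction, decimation,
# peri-event alignment with baseline Z-scoring, heatmap normalization and
# window-mean quantification.

#' Isosbestic artifact correction
#'
#' Corrects the calcium-dependent 465 nm channel with the calcium-independent
#' 405 nm channel: corrected = (ch465 - ch405) / ch405. Any artifact or
#' bleaching that multiplies both channels equally cancels exactly.
#'
#' @param rec A [TwoChannelRecording-class].
#' @return A [Trace-class] of the corrected signal on the same time grid.
#' @examples
#' rec <- twoChannelRecording(trace(0:1, c(2, 4)), trace(0:1, c(1, 2)))
#' traceValues(correctIsosbestic(rec))  # 1, 1
#' @export
correctIsosbestic <- function(rec) {
  v405 <- rec@ch405@values
  if (any(v405 <= 0))
    pcStop("signalError",
           "405 nm channel has samples <= 0; correction undefined")
  trace(rec@ch465@times, (rec@ch465@values - v405) / v405,
        rate = rec@ch465@rate)
}

#' Decimate a trace to approximately 25 samples per second
#'
#' Mean-bins consecutive samples with bin width `round(rate/targetRate)`.
#' Binning both smooths (anti-alias) and subsamples; when the computed bin
#' width is 1 the trace is returned unchanged.
#'
#' @param trc A [Trace-class].
#' @param targetRate Target sampling rate (default 25 samples/s).
#' @return The decimated [Trace-class].
#' @export
decimateToRate <- function(trc, targetRate = 25) {
  if (trc@rate < targetRate)
    pcStop("rateError",
           sprintf("input rate %.3g < target %.3g; upsampling not supported",
                   trc@rate, targetRate))
  width <- round(trc@rate / targetRate)
  if (width <= 1) return(trc)
  n <- length(trc@times)
  grp <- (seq_len(n) - 1) %/% width
  times <- as.numeric(tapply(trc@times, grp, mean))
  values <- as.numeric(tapply(trc@values, grp, mean))
  trace(times, values, rate = trc@rate / width)
}

#' Align a trace into a peri-event trial tensor
#'
#' Cuts the corrected trace into per-trial windows around `alignLabel`
#' (t = 0 at the event), Z-scores each trial against its own baseline
#' window (default -10 to -5 s; Z = (x - m) / sigma), and flags — never
#' drops — trials that violate the exclusion rules:
#' \itemize{
#'   \item `trial_too_long`: total trial length (first to last event of the
#'     trial) exceeds the session-kind limit (15 s multi-phase, 10 s other,
#'     25 s endoscope);
#'   \item `degenerate_baseline`: baseline SD is zero;
#'   \item `out_of_support`: the window extends beyond the recording.
#' }
#'
#' @param trc Corrected [Trace-class] (absolute time).
#' @param events An [EventTable-class]; every trial must contain
#'   `alignLabel`.
#' @param alignLabel Event label to align to (t = 0).
#' @param window Length-2 window in seconds relative to the event; must
#'   contain the baseline window.
#' @param cfg An [AnalysisConfig-class].
#' @return A [PeriEventTensor-class].
#' @export
alignTrials <- function(trc, events, alignLabel = "food_contact",
                        window = c(-10, 10), cfg = analysisConfig()) {
  ev <- eventData(events)
  bw <- cfg@baselineWindow
  if (window[1] > bw[1] || window[2] < bw[2])
    pcStop("rangeError", "window must contain the baseline window")
  anchors <- ev[ev$event_label == alignLabel, ]
  if (!nrow(anchors))
    pcStop("inputError", sprintf("no '%s' events found", alignLabel))
  axis <- seq(window[1], window[2], by = 1 / trc@rate)
  nTr <- nrow(anchors)
  Z <- matrix(NA_real_, nTr, length(axis))
  m <- sigma <- rep(NA_real_, nTr)
  exc <- data.frame(trial_id = anchors$trial_id, excluded = FALSE,
                    reason = "", stringsAsFactors = FALSE)
  baseIdx <- axis >= bw[1] & axis <= bw[2]
  for (i in seq_len(nTr)) {
    t0 <- anchors$time[i]
    tr <- ev[ev$trial_id == anchors$trial_id[i], ]
    limit <- cfg@trialLengthLimits[tr$session_kind[1]]
    if (!is.na(limit) && diff(range(tr$time)) > limit) {
      exc$excluded[i] <- TRUE
      exc$reason[i] <- "trial_too_long"
    }
    y <- stats::approx(trc@times, trc@values, xout = t0 + axis,
                       rule = 1)$y
    if (anyNA(y)) {
      exc$excluded[i] <- TRUE
      if (exc$reason[i] == "") exc$reason[i] <- "out_of_support"
      next
    }
    m[i] <- mean(y[baseIdx])
    sigma[i] <- stats::sd(y[baseIdx])
    if (sigma[i] == 0) {
      exc$excluded[i] <- TRUE
      if (exc$reason[i] == "") exc$reason[i] <- "degenerate_baseline"
      next
    }
    Z[i, ] <- (y - m[i]) / sigma[i]
  }
  new("PeriEventTensor", Z = Z, timeAxis = axis,
      baselineStats = data.frame(trial_id = anchors$trial_id, m = m,
                                 sigma = sigma),
      excluded = exc)
}

#' Per-trial min-max normalization for heatmaps
#'
#' Rescales each included trial to normalised Z = (Z - min Z) /
#' (max Z - min Z), so rows span exactly \[0, 1\]. Constant rows map to
#' zeros with a warning; excluded trials stay `NA`.
#'
#' @param tensor A [PeriEventTensor-class] with at least one included trial.
#' @return Trials x time numeric matrix in \[0, 1\].
#' @export
normalizeHeatmap <- function(tensor) {
  inc <- !tensor@excluded$excluded
  if (!any(inc)) pcStop("inputError", "no included trials to normalize")
  out <- matrix(NA_real_, nrow(tensor@Z), ncol(tensor@Z))
  for (i in which(inc)) {
    z <- tensor@Z[i, ]
    rng <- range(z)
    if (diff(rng) == 0) {
      pcWarn("degenerateTrialWarning",
             sprintf("trial %d is constant; heatmap row set to zeros", i))
      out[i, ] <- 0
    } else {
      out[i, ] <- (z - rng[1]) / diff(rng)
    }
  }
  out
}

#' Compare window means per trial
#'
#' Arithmetic mean of Z over two windows per included trial, for a paired
#' downstream comparison (e.g. baseline -8..-7 s vs after contact 9..10 s).
#'
#' @param tensor A [PeriEventTensor-class].
#' @param winA,winB Length-2 windows in seconds; must lie within the time
#'   axis.
#' @return data.frame with `trial_id`, `mean_a`, `mean_b` (included trials
#'   only).
#' @export
windowMeanCompare <- function(tensor, winA, winB) {
  ax <- tensor@timeAxis
  for (w in list(winA, winB)) {
    if (w[1] < min(ax) || w[2] > max(ax))
      pcStop("rangeError",
             sprintf("window [%g, %g] outside time axis [%g, %g]",
                     w[1], w[2], min(ax), max(ax)))
  }
  inc <- which(!tensor@excluded$excluded)
  ia <- ax >= winA[1] & ax <= winA[2]
  ib <- ax >= winB[1] & ax <= winB[2]
  data.frame(trial_id = tensor@excluded$trial_id[inc],
             mean_a = rowMeans(tensor@Z[inc, ia, drop = FALSE]),
             mean_b = rowMeans(tensor@Z[inc, ib, drop = FALSE]))
}
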