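# Brain-slice calcium imaging corrections and responder calling, plus
# sIPSC percent-change metrics and inclusion filters for whole-cell
# recordings.

#' Preprocess a slice recording
#'
#' Drops the first 2 min of the recording (camera photobleaching), Z-scores
#' every cell against the -480..0 s window before drug delivery, fits a
#' straight line to the slice-mean Z trace over that baseline and subtracts
#' the line (extrapolated over the whole recording) from every cell, which
#' removes common photobleaching/slice-drift trends.
#'
#' @param mat A [CellTraceMatrix-class] in absolute time.
#' @param drugOnset Drug-delivery time (s) on the recording clock.
#' @return A [CellTraceMatrix-class] holding adjusted Z traces
#'   (`sourceTag = "adjusted_z"`).
#' @export
preprocessSlice <- function(mat, drugOnset) {
  t <- mat@times
  keep <- t >= t[1] + 120
  if (!any(keep))
    pcStop("inputError", "recording shorter than the 2-min trim")
  t <- t[keep]
  x <- mat@craw[, keep, drop = FALSE]
  if (min(t) > drugOnset - 480 + 1e-9)
    pcStop("inputError",
           "recording does not cover the -480..0 s baseline after the 2-min trim")
  base <- t >= drugOnset - 480 & t <= drugOnset
  m <- rowMeans(x[, base, drop = FALSE])
  s <- apply(x[, base, drop = FALSE], 1, stats::sd)
  z <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    if (s[i] == 0) {
      dev <- x[i, ] - m[i]
      z[i, dev > 0] <- Inf
      z[i, dev < 0] <- -Inf
    } else {
      z[i, ] <- (x[i, ] - m[i]) / s[i]
    }
  }
  sliceMean <- colMeans(z)
  fit <- stats::lm(y ~ t, data = data.frame(t = t[base], y = sliceMean[base]))
  line <- stats::predict(fit, newdata = data.frame(t = t))
  z <- sweep(z, 2, line)
  cellTraceMatrix(mat@cellIds, z, t, sourceTag = "adjusted_z")
}

#' Call drug-excited cells
#'
#' A cell is excited iff its maximum adjusted Z after drug onset strictly
#' exceeds the sigma threshold (default 4). Decreases in activity are not
#' called.
#'
#' @param adjusted Adjusted Z [CellTraceMatrix-class] from
#'   [preprocessSlice()].
#' @param drugOnset Drug-delivery time (s).
#' @param cfg An [AnalysisConfig-class].
#' @return List with `excited` (named logical), `percent_active`,
#'   `max_z` (named numeric).
#' @export
callExcited <- function(adjusted, drugOnset, cfg = analysisConfig()) {
  post <- adjusted@times > drugOnset
  if (!any(post)) pcStop("rangeError", "no samples after drug onset")
  maxZ <- apply(adjusted@craw[, post, drop = FALSE], 1, max)
  excited <- maxZ > cfg@sigmaThreshold
  names(excited) <- names(maxZ) <- adjusted@cellIds
  list(excited = excited,
       percent_active = 100 * mean(excited),
       max_z = maxZ)
}

#' sIPSC frequency and amplitude metrics
#'
#' Event frequency (events/duration, Hz) and mean amplitude (pA) over the
#' baseline and analysis windows, plus each as a percentage of its baseline
#' value (100 = no change).
#'
#' @param rec A [SipscRecord-class].
#' @return List with `baseline_freq`, `baseline_amp`, `window_freq`,
#'   `window_amp`, `norm_freq_pct`, `norm_amp_pct`.
#' @export
sipscMetrics <- function(rec) {
  inWin <- function(w) rec@eventTimes >= w[1] & rec@eventTimes <= w[2]
  b <- inWin(rec@baselineWindow)
  a <- inWin(rec@analysisWindow)
  bF <- sum(b) / diff(rec@baselineWindow)
  aF <- sum(a) / diff(rec@analysisWindow)
  bA <- if (any(b)) mean(rec@amplitudes[b]) else NA_real_
  aA <- if (any(a)) mean(rec@amplitudes[a]) else NA_real_
  if (bF == 0)
    pcStop("metricError",
           "baseline frequency is 0; percent-of-baseline undefined")
  list(baseline_freq = bF, baseline_amp = bA,
       window_freq = aF, window_amp = aA,
       norm_freq_pct = 100 * aF / bF,
       norm_amp_pct = if (is.na(bA) || bA == 0) NA_real_ else 100 * aA / bA)
}

#' sIPSC inclusion filter
#'
#' A neuron is included iff its baseline sIPSC frequency exceeds 5 Hz and
#' the control-period change is at most 20% in magnitude. Which change the
#' stability criterion is measured on is supplied by the caller as
#' `controlChange` (percent, 0 = no change).
#'
#' @param rec A [SipscRecord-class].
#' @param controlChange Percent change over the control period.
#' @param minRate Minimum baseline frequency (Hz, default 5).
#' @param maxChange Maximum tolerated control change (percent, default 20).
#' @return List with `include` (logical) and `reason` (`"ok"`,
#'   `"low_rate"`, `"unstable"`, or both comma-separated).
#' @export
sipscInclusion <- function(rec, controlChange, minRate = 5, maxChange = 20) {
  bF <- sum(rec@eventTimes >= rec@baselineWindow[1] &
              rec@eventTimes <= rec@baselineWindow[2]) /
    diff(rec@baselineWindow)
  reasons <- character(0)
  if (bF <= minRate) reasons <- c(reasons, "low_rate")
  if (abs(controlChange) > maxChange) reasons <- c(reasons, "unstable")
  list(include = !length(reasons),
       reason = if (length(reasons)) paste(reasons, collapse = ",") else "ok")
}
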