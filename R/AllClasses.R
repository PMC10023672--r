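# Closed vocabularies shared across the package.
kEventLabels <- c("accessibility", "seeking_onset", "food_contact",
                  "consumption_end", "food_zone_exit", "drug_onset",
                  "cue_onset")
kSessionKinds <- c("multi_phase", "other", "endoscope", "slice")
kBodyparts <- c("snout", "upper_jaw", "oral_commissure", "lower_jaw",
                "front_paw_L", "front_paw_R", "hind_paw_L", "hind_paw_R",
                "tail_base", "food")

#' Single-channel fluorescence trace
#'
#' A time-stamped fluorescence (or Z-unit) signal with a nominal sampling
#' rate. Times are in seconds and must be strictly increasing.
#'
#' @slot times Numeric vector of sample times (seconds, strictly increasing).
#' @slot values Numeric vector of samples, same length as `times`.
#' @slot rate Nominal sampling rate in samples per second.
#' @export
setClass("Trace", representation(
  times = "numeric", values = "numeric", rate = "numeric"
))

setValidity("Trace", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (length(object@rate) != 1 || !is.finite(object@rate) || object@rate <= 0)
    return("rate must be a single positive number")
  TRUE
})

#' Construct a Trace
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param values Signal values, same length as `times`.
#' @param rate Sampling rate (samples/s); inferred from the median time step
#'   when omitted.
#' @return A [Trace-class] object.
#' @export
trace <- function(times, values, rate = NULL) {
  if (is.null(rate)) {
    rate <- if (length(times) > 1) 1 / stats::median(diff(times)) else 1
  }
  new("Trace", times = as.numeric(times), values = as.numeric(values),
      rate = rate)
}

#' @describeIn trace Sample times of a trace.
#' @param x A `Trace`.
#' @export
traceTimes <- function(x) x@times

#' @describeIn trace Signal values of a trace.
#' @export
traceValues <- function(x) x@values

#' @describeIn trace Sampling rate of a trace.
#' @export
traceRate <- function(x) x@rate

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace: %d samples @ %.3g Hz, t in [%.3g, %.3g] s\n",
              length(object@times), object@rate,
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA))
})

setMethod("length", "Trace", function(x) length(x@times))

#' Two-channel fibre-photometry recording
#'
#' Holds the 465 nm calcium-dependent channel and the 405 nm isosbestic
#' (calcium-independent) channel of one session on a shared time grid.
#'
#' @slot ch465 [Trace-class]: calcium-dependent signal.
#' @slot ch405 [Trace-class]: isosbestic control signal.
#' @slot sessionId Character session identifier.
#' @export
setClass("TwoChannelRecording", representation(
  ch465 = "Trace", ch405 = "Trace", sessionId = "character"
))

setValidity("TwoChannelRecording", function(object) {
  if (length(object@ch465@times) != length(object@ch405@times) ||
      (length(object@ch465@times) &&
       !isTRUE(all.equal(object@ch465@times, object@ch405@times,
                         tolerance = 1e-12))))
    return("ch465 and ch405 must share an identical time grid")
  TRUE
})

#' Construct a TwoChannelRecording
#' @param ch465,ch405 [Trace-class] objects on the same time grid.
#' @param sessionId Session identifier string.
#' @return A [TwoChannelRecording-class].
#' @export
twoChannelRecording <- function(ch465, ch405, sessionId = "session") {
  new("TwoChannelRecording", ch465 = ch465, ch405 = ch405,
      sessionId = sessionId)
}

setMethod("show", "TwoChannelRecording", function(object) {
  cat(sprintf("TwoChannelRecording '%s': %d samples @ %.3g Hz\n",
              object@sessionId, length(object@ch465@times),
              object@ch465@rate))
})

#' Behavioural event table
#'
#' Time-stamped behavioural landmarks per trial, from a closed label
#' vocabulary (accessibility, seeking_onset, food_contact, consumption_end,
#' food_zone_exit, drug_onset, cue_onset). Within a trial, event times must
#' be non-decreasing in that canonical order.
#'
#' @slot events A data.frame with columns `trial_id`, `event_label`, `time`,
#'   `session_kind`.
#' @export
setClass("EventTable", representation(events = "data.frame"))

setValidity("EventTable", function(object) {
  ev <- object@events
  need <- c("trial_id", "event_label", "time", "session_kind")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(ev)) {
    bad <- setdiff(unique(ev$event_label), kEventLabels)
    if (length(bad))
      return(paste("unknown event label(s):", paste(bad, collapse = ", ")))
    badk <- setdiff(unique(ev$session_kind), kSessionKinds)
    if (length(badk))
      return(paste("unknown session kind(s):", paste(badk, collapse = ", ")))
    for (id in unique(ev$trial_id)) {
      tr <- ev[ev$trial_id == id, ]
      ord <- order(match(tr$event_label, kEventLabels))
      if (is.unsorted(tr$time[ord]))
        return(sprintf("trial %s: event times decrease in canonical order",
                       as.character(id)))
    }
  }
  TRUE
})

#' Construct an EventTable
#' @param events data.frame with columns `trial_id`, `event_label`, `time`
#'   (seconds), `session_kind`.
#' @return An [EventTable-class].
#' @export
eventTable <- function(events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  obj <- new("EventTable", events = events)
  obj
}

#' @describeIn eventTable Extract the underlying data.frame.
#' @param x An `EventTable`.
#' @export
eventData <- function(x) x@events

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d events, %d trial(s)\n", nrow(object@events),
              length(unique(object@events$trial_id))))
})

#' Cells-by-time raw calcium trace matrix
#'
#' Raw per-cell calcium traces (the "Craw" output of constrained source
#' extraction) on a shared time axis.
#'
#' @slot cellIds Character cell identifiers (one per row of `craw`).
#' @slot craw Numeric matrix, cells x time.
#' @slot times Numeric time axis in seconds, strictly increasing.
#' @slot sourceTag Free-text provenance tag.
#' @export
setClass("CellTraceMatrix", representation(
  cellIds = "character", craw = "matrix", times = "numeric",
  sourceTag = "character"
))

setValidity("CellTraceMatrix", function(object) {
  if (nrow(object@craw) != length(object@cellIds))
    return("craw row count must equal number of cellIds")
  if (ncol(object@craw) != length(object@times))
    return("craw column count must equal number of time points")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (anyNA(object@craw))
    return("craw must not contain missing samples")
  TRUE
})

#' Construct a CellTraceMatrix
#' @param cellIds Cell identifiers.
#' @param craw Cells x time numeric matrix of raw traces.
#' @param times Time axis in seconds.
#' @param sourceTag Provenance string (e.g. `"cnmfe"`).
#' @return A [CellTraceMatrix-class].
#' @export
cellTraceMatrix <- function(cellIds, craw, times, sourceTag = "unknown") {
  craw <- as.matrix(craw)
  rownames(craw) <- cellIds
  new("CellTraceMatrix", cellIds = as.character(cellIds), craw = craw,
      times = as.numeric(times), sourceTag = sourceTag)
}

#' @describeIn cellTraceMatrix Cell identifiers.
#' @param x A `CellTraceMatrix`.
#' @export
cellIds <- function(x) x@cellIds

#' @describeIn cellTraceMatrix Raw trace matrix (cells x time).
#' @export
craw <- function(x) x@craw

#' @describeIn cellTraceMatrix Time axis in seconds.
#' @export
cellTimes <- function(x) x@times

setMethod("show", "CellTraceMatrix", function(object) {
  cat(sprintf("CellTraceMatrix [%s]: %d cells x %d samples, t in [%.3g, %.3g] s\n",
              object@sourceTag, nrow(object@craw), ncol(object@craw),
              min(object@times), max(object@times)))
})

setMethod("dim", "CellTraceMatrix", function(x) dim(x@craw))

#' Analysis configuration
#'
#' Holds the study constants: the baseline window used for Z-scoring
#' (default -10 to -5 s before behavioural initiation), the response window
#' over which responsiveness is evaluated, the 4-sigma activation threshold,
#' the NF0 0.4 seeking-score-2 cut, per-session-kind trial-length exclusion
#' limits (15 s multi-phase, 10 s other, 25 s endoscope), and the 0.9
#' keypoint-likelihood cutoff.
#'
#' @slot baselineWindow Numeric length-2, seconds relative to the aligned
#'   event (start < end).
#' @slot responseWindow Numeric length-2, seconds relative to the event.
#' @slot sigmaThreshold Activation threshold in baseline SD units.
#' @slot nf0Threshold Seeking-score-2 cut in NF0 units.
#' @slot trialLengthLimits Named numeric: maximum trial length (s) per
#'   session kind.
#' @slot likelihoodCutoff Keypoint likelihood cutoff (probability).
#' @slot seed Integer seed for stochastic steps.
#' @export
setClass("AnalysisConfig", representation(
  baselineWindow = "numeric", responseWindow = "numeric",
  sigmaThreshold = "numeric", nf0Threshold = "numeric",
  trialLengthLimits = "numeric", likelihoodCutoff = "numeric",
  seed = "integer"
))

setValidity("AnalysisConfig", function(object) {
  if (length(object@baselineWindow) != 2 ||
      object@baselineWindow[1] >= object@baselineWindow[2])
    return("baselineWindow must be (start, end) with start < end")
  if (length(object@responseWindow) != 2 ||
      object@responseWindow[1] >= object@responseWindow[2])
    return("responseWindow must be (start, end) with start < end")
  if (object@sigmaThreshold <= 0) return("sigmaThreshold must be > 0")
  if (object@nf0Threshold <= 0) return("nf0Threshold must be > 0")
  if (any(object@trialLengthLimits <= 0))
    return("trialLengthLimits must be > 0")
  if (object@likelihoodCutoff <= 0 || object@likelihoodCutoff >= 1)
    return("likelihoodCutoff must be in (0, 1)")
  TRUE
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n",
      sprintf("  baseline window : [%g, %g] s\n", object@baselineWindow[1],
              object@baselineWindow[2]),
      sprintf("  response window : [%g, %g] s\n", object@responseWindow[1],
              object@responseWindow[2]),
      sprintf("  sigma threshold : %g\n", object@sigmaThreshold),
      sprintf("  NF0 threshold   : %g\n", object@nf0Threshold),
      sprintf("  trial limits (s): %s\n",
              paste(names(object@trialLengthLimits),
                    object@trialLengthLimits, sep = "=", collapse = ", ")),
      sprintf("  likelihood cut  : %g\n", object@likelihoodCutoff), sep = "")
})

#' Peri-event Z-scored tensor
#'
#' Trials x time matrix of Z-scored activity aligned to a behavioural event
#' at t = 0, with per-trial baseline statistics and exclusion flags. Trials
#' are flagged, never silently dropped.
#'
#' @slot Z Trials x time numeric matrix (Z units; NA rows for trials whose
#'   window fell outside the recording).
#' @slot timeAxis Seconds relative to the aligned event.
#' @slot baselineStats data.frame with per-trial `m` and `sigma`.
#' @slot excluded data.frame with `trial_id`, `excluded`, `reason`.
#' @export
setClass("PeriEventTensor", representation(
  Z = "matrix", timeAxis = "numeric", baselineStats = "data.frame",
  excluded = "data.frame"
))

setValidity("PeriEventTensor", function(object) {
  if (ncol(object@Z) != length(object@timeAxis))
    return("Z columns must match timeAxis length")
  if (nrow(object@Z) != nrow(object@excluded))
    return("Z rows must match exclusion table rows")
  TRUE
})

#' @describeIn alignTrials Z matrix (trials x time) of a tensor.
#' @param x A `PeriEventTensor`.
#' @export
zMatrix <- function(x) x@Z

#' @describeIn alignTrials Relative time axis of a tensor.
#' @export
timeAxis <- function(x) x@timeAxis

#' @describeIn alignTrials Per-trial exclusion flags and reasons.
#' @export
excludedTrials <- function(x) x@excluded

#' @describeIn alignTrials Per-trial baseline mean and SD.
#' @export
baselineStats <- function(x) x@baselineStats

setMethod("show", "PeriEventTensor", function(object) {
  cat(sprintf("PeriEventTensor: %d trial(s) x %d samples, t in [%.3g, %.3g] s (%d excluded)\n",
              nrow(object@Z), ncol(object@Z), min(object@timeAxis),
              max(object@timeAxis), sum(object@excluded$excluded)))
})

#' Neural-onset detection result
#'
#' @slot onsetTime Onset (argmax of the third derivative) in seconds
#'   relative to behavioural onset; `NA` when the jolt is flat.
#' @slot degreeUsed Polynomial degree of the fit.
#' @slot fitResidual RMS residual of the fit (Z units).
#' @slot searchWindow The (start, end) window searched.
#' @slot confidenceFlag One of `"ok"`, `"flat"`, `"edge"`.
#' @export
setClass("OnsetResult", representation(
  onsetTime = "numeric", degreeUsed = "integer", fitResidual = "numeric",
  searchWindow = "numeric", confidenceFlag = "character"
))

setMethod("show", "OnsetResult", function(object) {
  cat(sprintf("OnsetResult: onset %s s (degree %d, rms %.3g, flag %s)\n",
              format(object@onsetTime), object@degreeUsed,
              object@fitResidual, object@confidenceFlag))
})

#' Pose keypoint track for one camera view
#'
#' Per-frame bodypart coordinates and tracking likelihoods, plus the food
#' zone polygon for this view. Image coordinates: y increases downward.
#'
#' @slot view `"bottom"` or `"side"`.
#' @slot fps Frames per second (default 24).
#' @slot coords Array frames x bodyparts x (x, y, likelihood).
#' @slot foodZone Matrix of polygon vertices (columns x, y) in pixels.
#' @slot interpolated Logical frames x bodyparts matrix flagging points that
#'   were replaced by interpolation.
#' @export
setClass("KeypointTrack", representation(
  view = "character", fps = "numeric", coords = "array",
  foodZone = "matrix", interpolated = "matrix"
))

setValidity("KeypointTrack", function(object) {
  if (!object@view %in% c("bottom", "side"))
    return("view must be 'bottom' or 'side'")
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    return("coords must be frames x bodyparts x (x, y, likelihood)")
  if (d[1] < 1) return("frame count must be > 0")
  lik <- object@coords[, , 3]
  if (any(lik < 0 | lik > 1, na.rm = TRUE))
    return("likelihood must be in [0, 1]")
  if (object@fps <= 0) return("fps must be > 0")
  TRUE
})

#' Construct a KeypointTrack
#' @param view Camera view, `"bottom"` or `"side"`.
#' @param coords Array frames x bodyparts x 3 (x, y, likelihood); bodypart
#'   dimnames must name the tracked parts.
#' @param foodZone Polygon vertex matrix (columns x, y) in pixels.
#' @param fps Frames per second.
#' @return A [KeypointTrack-class].
#' @export
keypointTrack <- function(view, coords, foodZone, fps = 24) {
  interp <- matrix(FALSE, dim(coords)[1], dim(coords)[2],
                   dimnames = list(NULL, dimnames(coords)[[2]]))
  new("KeypointTrack", view = view, fps = fps, coords = coords,
      foodZone = as.matrix(foodZone), interpolated = interp)
}

#' @describeIn keypointTrack Number of frames in a track.
#' @param x A `KeypointTrack`.
#' @export
nFrames <- function(x) dim(x@coords)[1]

setMethod("show", "KeypointTrack", function(object) {
  cat(sprintf("KeypointTrack (%s view): %d frames @ %g fps, %d bodyparts\n",
              object@view, dim(object@coords)[1], object@fps,
              dim(object@coords)[2]))
})

#' Spontaneous IPSC event record for one neuron
#'
#' @slot cellId Cell identifier.
#' @slot condition `"ACSF"` or `"NPY"`.
#' @slot eventTimes Detected sIPSC event times (s), increasing.
#' @slot amplitudes Event amplitudes (pA), same length as `eventTimes`.
#' @slot baselineWindow (start, end) seconds of the baseline period.
#' @slot analysisWindow (start, end) seconds of the analysis period
#'   (the last minute after drug application).
#' @export
setClass("SipscRecord", representation(
  cellId = "character", condition = "character", eventTimes = "numeric",
  amplitudes = "numeric", baselineWindow = "numeric",
  analysisWindow = "numeric"
))

setValidity("SipscRecord", function(object) {
  if (length(object@eventTimes) != length(object@amplitudes))
    return("eventTimes and amplitudes must have equal length")
  if (!object@condition %in% c("ACSF", "NPY"))
    return("condition must be 'ACSF' or 'NPY'")
  if (length(object@baselineWindow) != 2 ||
      object@baselineWindow[1] >= object@baselineWindow[2])
    return("baselineWindow must be (start, end) with start < end")
  if (length(object@analysisWindow) != 2 ||
      object@analysisWindow[1] >= object@analysisWindow[2])
    return("analysisWindow must be (start, end) with start < end")
  TRUE
})

#' Construct a SipscRecord
#' @param cellId Cell identifier.
#' @param condition `"ACSF"` or `"NPY"`.
#' @param eventTimes Event times in seconds (sorted internally).
#' @param amplitudes Event amplitudes in pA.
#' @param baselineWindow,analysisWindow (start, end) windows in seconds.
#' @return A [SipscRecord-class].
#' @export
sipscRecord <- function(cellId, condition, eventTimes, amplitudes,
                        baselineWindow, analysisWindow) {
  ord <- order(eventTimes)
  new("SipscRecord", cellId = as.character(cellId), condition = condition,
      eventTimes = as.numeric(eventTimes[ord]),
      amplitudes = as.numeric(amplitudes[ord]),
      baselineWindow = as.numeric(baselineWindow),
      analysisWindow = as.numeric(analysisWindow))
}

setMethod("show", "SipscRecord", function(object) {
  cat(sprintf("SipscRecord %s (%s): %d events\n", object@cellId,
              object@condition, length(object@eventTimes)))
})

#' Synthetic-data generation parameters
#'
#' Defines the simulated study conditions: the mean latency by which neural
#' onset precedes behavioural onset (6 s), GCaMP-like kernel time constants,
#' shared artifact/bleaching levels, and the population class proportions
#' (25% seeking, 39% consummatory).
#'
#' @slot seed Integer RNG seed.
#' @slot nTrials Number of trials per session.
#' @slot onsetLead Mean neural-onset lead before behavioural onset (s).
#' @slot latencySd SD of the per-trial onset lead (s).
#' @slot transientRise GCaMP kernel rise time constant (s).
#' @slot transientDecay GCaMP kernel decay time constant (s).
#' @slot noiseSd Additive noise SD (signal units).
#' @slot bleachSlope Bleaching slope per second (<= 0 for decay).
#' @slot artifactGain Amplitude of the shared multiplicative artifact.
#' @slot amplitude Peak transient amplitude relative to baseline
#'   fluorescence.
#' @slot classProportions Named fractions for seeking, consummatory,
#'   ambiguous and non_responsive cells (sum to 1).
#' @export
setClass("SynthParams", representation(
  seed = "integer", nTrials = "numeric", onsetLead = "numeric",
  latencySd = "numeric", transientRise = "numeric",
  transientDecay = "numeric", noiseSd = "numeric", bleachSlope = "numeric",
  artifactGain = "numeric", amplitude = "numeric",
  classProportions = "numeric"
))

setValidity("SynthParams", function(object) {
  if (object@transientRise <= 0 || object@transientDecay <= 0 ||
      object@onsetLead <= 0 || object@latencySd < 0)
    return("time constants must be positive")
  p <- object@classProportions
  need <- c("seeking", "consummatory", "ambiguous", "non_responsive")
  if (!all(need %in% names(p)))
    return("classProportions must name seeking, consummatory, ambiguous, non_responsive")
  if (abs(sum(p) - 1) > 1e-9) return("classProportions must sum to 1")
  if (any(p < 0)) return("classProportions must be non-negative")
  TRUE
})

#' Construct synthetic-data parameters
#'
#' Defaults are the simulated study conditions: onset lead 6 s, GCaMP-like
#' rise 0.2 s / decay 1.5 s, class proportions 25% seeking / 39%
#' consummatory with the remainder non-responsive (exact-tie "ambiguous"
#' cells are measure-zero in real data and default to 0; set
#' `classProportions` explicitly to generate them).
#'
#' @param seed Integer RNG seed.
#' @param nTrials Trials per session.
#' @param onsetLead Mean neural lead before behavioural onset (s).
#' @param latencySd Per-trial SD of the lead (s).
#' @param transientRise,transientDecay Kernel time constants (s).
#' @param noiseSd Additive noise SD.
#' @param bleachSlope Bleaching slope per second.
#' @param artifactGain Shared multiplicative artifact amplitude.
#' @param amplitude Peak transient amplitude.
#' @param classProportions Named class fractions summing to 1.
#' @return A [SynthParams-class].
#' @export
synthParams <- function(seed = 1L, nTrials = 20, onsetLead = 6,
                        latencySd = 0.5, transientRise = 0.2,
                        transientDecay = 1.5, noiseSd = 0.1,
                        bleachSlope = -0.0002, artifactGain = 0.05,
                        amplitude = 5,
                        classProportions = c(seeking = 0.25,
                                             consummatory = 0.39,
                                             ambiguous = 0,
                                             non_responsive = 0.36)) {
  new("SynthParams", seed = as.integer(seed), nTrials = nTrials,
      onsetLead = onsetLead, latencySd = latencySd,
      transientRise = transientRise, transientDecay = transientDecay,
      noiseSd = noiseSd, bleachSlope = bleachSlope,
      artifactGain = artifactGain, amplitude = amplitude,
      classProportions = classProportions)
}

setMethod("show", "SynthParams", function(object) {
  cat(sprintf("SynthParams: seed %d, %g trials, onset lead %g s, noise SD %g\n",
              object@seed, object@nTrials, object@onsetLead, object@noiseSd))
})

#' Venn simulation parameters
#'
#' Population composition assumptions for the food-specific LepR / GABA
#' overlap simulation: 1000 GABA neurons, 10% of them LepR, 8% food-specific
#' overall, 63% of LepR neurons food-specific.
#'
#' @slot nGaba Number of GABAergic neurons simulated.
#' @slot pLepr Fraction of GABA neurons that are LepR.
#' @slot pFoodGaba Fraction of GABA neurons that are food-specific.
#' @slot pFoodLepr Fraction of LepR neurons that are food-specific.
#' @export
setClass("VennParams", representation(
  nGaba = "numeric", pLepr = "numeric", pFoodGaba = "numeric",
  pFoodLepr = "numeric"
))

setValidity("VennParams", function(object) {
  p <- c(object@pLepr, object@pFoodGaba, object@pFoodLepr)
  if (any(p < 0 | p > 1)) return("fractions must be in [0, 1]")
  if (object@nGaba < 1) return("nGaba must be >= 1")
  TRUE
})

#' Construct Venn simulation parameters
#' @param nGaba Number of GABA neurons (default 1000).
#' @param pLepr Fraction of GABA neurons that are LepR (default 0.10).
#' @param pFoodGaba Fraction of GABA neurons food-specific (default 0.08).
#' @param pFoodLepr Fraction of LepR neurons food-specific (default 0.63).
#' @return A [VennParams-class].
#' @export
vennParams <- function(nGaba = 1000, pLepr = 0.10, pFoodGaba = 0.08,
                       pFoodLepr = 0.63) {
  new("VennParams", nGaba = nGaba, pLepr = pLepr, pFoodGaba = pFoodGaba,
      pFoodLepr = pFoodLepr)
}

setMethod("show", "VennParams", function(object) {
  cat(sprintf("VennParams: %g GABA, pLepr %g, pFoodGaba %g, pFoodLepr %g\n",
              object@nGaba, object@pLepr, object@pFoodGaba,
              object@pFoodLepr))
})
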