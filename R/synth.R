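# Seeded synthetic-data generators. Every generator reseeds the RNG from
# its SynthParams, emits the same containers the readers produce, and
# returns ground truth sufficient to score its downstream stage.

# Activity of one trial: firing rate ramps linearly from the neural onset
# to the behavioural onset, holds through the consummatory period, ramps
# off after it; the calcium signal is this rate convolved with the
# difference-of-exponentials GCaMP kernel (closed form via the ramp
# response). The third derivative of the noiseless signal peaks exactly at
# the ramp onset, which is the stored "true neural onset".
rampActivity <- function(t, onset, peakAt, offAt, offEnd, rise, decay) {
  up <- (kernelRampResponse(t - onset, rise, decay) -
           kernelRampResponse(t - peakAt, rise, decay)) / (peakAt - onset)
  down <- (kernelRampResponse(t - offAt, rise, decay) -
             kernelRampResponse(t - offEnd, rise, decay)) / (offEnd - offAt)
  up - down
}

#' Generate a synthetic two-channel photometry session
#'
#' Builds a seeded session of `nTrials` seeking trials: per trial the
#' neural activity ramps up from `onsetLead` (+- `latencySd`) seconds
#' before the seeking onset, is convolved with the GCaMP kernel, and enters
#' the 465 nm channel multiplicatively on top of a shared
#' artifact-and-bleaching envelope; the 405 nm isosbestic channel carries
#' the identical envelope but no activity, so the correction formula
#' cancels it exactly. Gaussian sensor noise is added per channel and
#' sample.
#'
#' @param params A [SynthParams-class].
#' @param rate Native sampling rate (samples/s, default 1000 as typical
#'   for photometry acquisition before decimation).
#' @param trialSpacing Seconds between seeking onsets.
#' @return List with `recording` ([TwoChannelRecording-class]), `events`
#'   ([EventTable-class], session kind `multi_phase`), and `truth`
#'   (data.frame `trial_id`, `seek_onset`, `neural_onset`, `latency`).
#' @export
genPhotometrySession <- function(params = synthParams(), rate = 1000,
                                 trialSpacing = 40) {
  set.seed(params@seed)
  n <- params@nTrials
  pad <- 20
  dur <- pad + max(n, 0.5) * trialSpacing
  t <- seq(0, dur, by = 1 / rate)
  act <- numeric(length(t))
  if (n > 0) {
    seek <- pad + (seq_len(n) - 1) * trialSpacing
    latency <- pmin(pmax(stats::rnorm(n, params@onsetLead, params@latencySd),
                         2), 9)
    for (i in seq_len(n)) {
      idx <- t >= seek[i] - latency[i] - 1 & t <= seek[i] + 25
      act[idx] <- act[idx] + params@amplitude *
        rampActivity(t[idx], seek[i] - latency[i], seek[i], seek[i] + 8,
                     seek[i] + 10, params@transientRise,
                     params@transientDecay)
    }
    events <- do.call(rbind, lapply(seq_len(n), function(i) data.frame(
      trial_id = i,
      event_label = c("accessibility", "seeking_onset", "food_contact",
                      "consumption_end"),
      time = seek[i] + c(-3, 0, 4, 8),
      session_kind = "multi_phase", stringsAsFactors = FALSE)))
    truth <- data.frame(trial_id = seq_len(n), seek_onset = seek,
                        neural_onset = seek - latency, latency = latency)
  } else {
    events <- data.frame(trial_id = integer(0), event_label = character(0),
                         time = numeric(0), session_kind = character(0),
                         stringsAsFactors = FALSE)
    truth <- data.frame(trial_id = integer(0), seek_onset = numeric(0),
                        neural_onset = numeric(0), latency = numeric(0))
  }
  phi <- stats::runif(2, 0, 2 * pi)
  envelope <- (1 + params@artifactGain *
                 (0.6 * sin(2 * pi * 0.017 * t + phi[1]) +
                    0.4 * sin(2 * pi * 0.31 * t + phi[2]))) *
    exp(params@bleachSlope * t)
  f0 <- 10  # baseline fluorescence; corrected trace = act / f0
  ch465 <- envelope * (f0 + act) +
    stats::rnorm(length(t), 0, params@noiseSd)
  ch405 <- envelope * f0 + stats::rnorm(length(t), 0, params@noiseSd)
  list(recording = twoChannelRecording(trace(t, ch465, rate),
                                       trace(t, ch405, rate),
                                       sessionId = sprintf("synth%d",
                                                           params@seed)),
       events = eventTable(events), truth = truth)
}

assignClasses <- function(nCells, proportions) {
  # largest-remainder apportionment so counts sum to nCells
  raw <- proportions * nCells
  counts <- floor(raw)
  left <- nCells - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  rep(names(proportions), counts)
}

endoscopeSessionEvents <- function(nTrials, spacing, pad, food) {
  do.call(rbind, lapply(seq_len(nTrials), function(i) {
    t0 <- pad + (i - 1) * spacing
    data.frame(
      trial_id = i,
      event_label = c("seeking_onset", "food_contact",
                      if (food) "consumption_end" else "food_zone_exit"),
      time = t0 + c(0, 5, 10),
      session_kind = "endoscope", stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic micro-endoscope cell population
#'
#' Generates paired food and no-food sessions for a population with known
#' class composition: seeking-class cells are active only between seeking
#' onset and food contact (or zone arrival); consummatory-class cells only
#' from food contact to consumption end and not at all in the no-food
#' session; ambiguous-class cells ramp linearly across both phases so that
#' seeking-score-1 exactly ties the consummatory score; non-responsive
#' cells are silent. In both sessions the `food_contact` timestamp marks
#' the zone-arrival moment of no-food trials.
#'
#' @param params A [SynthParams-class] (`classProportions` sets the
#'   composition).
#' @param nCells Number of cells.
#' @param nTrials Trials per session.
#' @param rate Sampling rate of the trace matrix (samples/s).
#' @return List with `food`, `nofood` (each `list(mat, events)`), and
#'   `truth` (data.frame `cell_id`, `class`).
#' @export
genEndoscopePopulation <- function(params = synthParams(), nCells = 100,
                                   nTrials = 6, rate = 10) {
  set.seed(params@seed)
  spacing <- 40
  pad <- 20
  classes <- assignClasses(nCells, params@classProportions)
  dur <- pad + nTrials * spacing
  t <- seq(0, dur, by = 1 / rate)
  evF <- endoscopeSessionEvents(nTrials, spacing, pad, food = TRUE)
  evN <- endoscopeSessionEvents(nTrials, spacing, pad, food = FALSE)
  f0 <- 5
  cellAct <- function(class, food) {
    act <- numeric(length(t))
    for (i in seq_len(nTrials)) {
      t0 <- pad + (i - 1) * spacing
      seg <- switch(class,
        seeking = rampActivity(t, t0, t0 + 1, t0 + 5, t0 + 6,
                               params@transientRise, params@transientDecay),
        consummatory = if (food)
          rampActivity(t, t0 + 5, t0 + 6, t0 + 10, t0 + 11,
                       params@transientRise, params@transientDecay)
          else 0,
        ambiguous = pmax(0, pmin((t - t0) / 10, 1)) *
          (t <= t0 + 10),  # linear ramp over the trial, off at the end
        non_responsive = 0)
      act <- act + seg
    }
    act
  }
  makeMat <- function(food) {
    m <- matrix(0, nCells, length(t))
    for (c_i in seq_len(nCells)) {
      m[c_i, ] <- f0 + params@amplitude * cellAct(classes[c_i], food) +
        stats::rnorm(length(t), 0, params@noiseSd)
    }
    cellTraceMatrix(sprintf("cell%03d", seq_len(nCells)), m, t,
                    sourceTag = if (food) "synth_food" else "synth_nofood")
  }
  list(food = list(mat = makeMat(TRUE), events = eventTable(evF)),
       nofood = list(mat = makeMat(FALSE), events = eventTable(evN)),
       truth = data.frame(cell_id = sprintf("cell%03d", seq_len(nCells)),
                          class = classes, stringsAsFactors = FALSE))
}

posePosture <- function(view, consummatory) {
  # x, y per bodypart; image coordinates, y down
  if (view == "bottom") {
    if (consummatory)
      rbind(snout = c(240, 100), upper_jaw = c(235, 110),
            oral_commissure = c(240, 112), lower_jaw = c(245, 114),
            front_paw_L = c(230, 200), front_paw_R = c(250, 200),
            hind_paw_L = c(200, 260), hind_paw_R = c(280, 260),
            tail_base = c(240, 320), food = c(240, 95))
    else
      rbind(snout = c(240, 300), upper_jaw = c(235, 310),
            oral_commissure = c(240, 312), lower_jaw = c(245, 314),
            front_paw_L = c(150, 200), front_paw_R = c(330, 200),
            hind_paw_L = c(200, 260), hind_paw_R = c(280, 260),
            tail_base = c(240, 180), food = c(240, 95))
  } else {
    if (consummatory)
      rbind(snout = c(320, 250), upper_jaw = c(315, 255),
            oral_commissure = c(320, 257), lower_jaw = c(325, 259),
            front_paw_L = c(300, 330), front_paw_R = c(340, 330),
            hind_paw_L = c(280, 340), hind_paw_R = c(360, 340),
            tail_base = c(420, 330), food = c(320, 260))
    else
      rbind(snout = c(100, 100), upper_jaw = c(95, 105),
            oral_commissure = c(100, 107), lower_jaw = c(105, 109),
            front_paw_L = c(80, 330), front_paw_R = c(120, 330),
            hind_paw_L = c(60, 340), hind_paw_R = c(140, 340),
            tail_base = c(200, 330), food = c(320, 260))
  }
}

poseZone <- function(view) {
  if (view == "bottom")
    cbind(x = c(200, 280, 280, 200), y = c(60, 60, 140, 140))
  else
    cbind(x = c(250, 390, 390, 250), y = c(200, 200, 300, 300))
}

#' Generate a synthetic two-view pose session
#'
#' Scripts `nBouts` consummatory bouts during which all three posture
#' criteria hold in every frame; outside bouts all three are violated.
#' Optionally degrades a fraction of keypoints below the likelihood cutoff
#' (displacing their coordinates), emulating tracking dropouts that the
#' likelihood filter must repair.
#'
#' @param params A [SynthParams-class] (`noiseSd` adds pixel jitter; keep 0
#'   for exact-truth checks).
#' @param nBouts Number of scripted bouts.
#' @param durationS Session length in seconds.
#' @param boutFrames Frames per bout (default 36, 1.5 s at 24 fps).
#' @param degradeFrac Fraction of (frame, bodypart) points degraded below
#'   the likelihood cutoff.
#' @param fps Frames per second.
#' @return List with `bottom`, `side` ([KeypointTrack-class]), `labels`
#'   (true per-frame logical), `bouts` (true bout table).
#' @export
genPoseSession <- function(params = synthParams(), nBouts = 3,
                           durationS = 60, boutFrames = 36,
                           degradeFrac = 0, fps = 24) {
  set.seed(params@seed)
  n <- round(durationS * fps)
  labels <- rep(FALSE, n)
  bouts <- data.frame(bout_id = integer(0), onset_frame = integer(0),
                      offset_frame = integer(0), duration = numeric(0))
  if (nBouts > 0) {
    gap <- floor((n - nBouts * boutFrames) / (nBouts + 1))
    if (gap < 2 * fps)
      pcStop("parameterError", "session too short for the requested bouts")
    starts <- gap + (seq_len(nBouts) - 1) * (boutFrames + gap) + 1
    for (b in seq_len(nBouts)) {
      labels[starts[b]:(starts[b] + boutFrames - 1)] <- TRUE
    }
    bouts <- data.frame(bout_id = seq_len(nBouts), onset_frame = starts,
                        offset_frame = starts + boutFrames - 1,
                        duration = boutFrames / fps)
  }
  makeTrack <- function(view) {
    pc <- posePosture(view, TRUE)
    pn <- posePosture(view, FALSE)
    coords <- array(NA_real_, c(n, length(kBodyparts), 3),
                    dimnames = list(NULL, kBodyparts,
                                    c("x", "y", "likelihood")))
    for (p in seq_along(kBodyparts)) {
      coords[, p, 1] <- ifelse(labels, pc[p, 1], pn[p, 1]) +
        stats::rnorm(n, 0, params@noiseSd)
      coords[, p, 2] <- ifelse(labels, pc[p, 2], pn[p, 2]) +
        stats::rnorm(n, 0, params@noiseSd)
      coords[, p, 3] <- stats::runif(n, 0.95, 1)
    }
    if (degradeFrac > 0) {
      cells <- which(stats::runif(n * length(kBodyparts)) < degradeFrac)
      for (cell in cells) {
        fr <- ((cell - 1) %% n) + 1
        p <- ((cell - 1) %/% n) + 1
        coords[fr, p, 1] <- coords[fr, p, 1] + stats::runif(1, -120, 120)
        coords[fr, p, 2] <- coords[fr, p, 2] + stats::runif(1, -120, 120)
        coords[fr, p, 3] <- stats::runif(1, 0.2, 0.85)
      }
    }
    keypointTrack(view, coords, poseZone(view), fps = fps)
  }
  list(bottom = makeTrack("bottom"), side = makeTrack("side"),
       labels = labels, bouts = bouts)
}

#' Generate a synthetic brain-slice recording
#'
#' One slice of `nCells` cells sharing a common linear bleaching trend;
#' a fraction of cells ramp up after drug delivery. The recording starts
#' 720 s before the drug (so the 2-min camera trim and the -480..0 s
#' baseline both fit) and continues 300 s after it.
#'
#' @param params A [SynthParams-class] (`bleachSlope` in signal units per
#'   second).
#' @param nCells Number of cells.
#' @param fracResponders Fraction of cells that respond to the drug.
#' @param rate Sampling rate (samples/s).
#' @return List with `mat` ([CellTraceMatrix-class]), `drug_onset`
#'   (seconds), `truth` (data.frame `cell_id`, `responder`).
#' @export
genSliceRecording <- function(params = synthParams(), nCells = 40,
                              fracResponders = 0.5, rate = 10) {
  set.seed(params@seed)
  drug <- 720
  t <- seq(0, drug + 300, by = 1 / rate)
  nResp <- round(nCells * fracResponders)
  responder <- c(rep(TRUE, nResp), rep(FALSE, nCells - nResp))
  f0 <- 5
  post <- pmin(pmax((t - drug) / 60, 0), 1)   # ramp to plateau over 60 s
  m <- matrix(0, nCells, length(t))
  for (i in seq_len(nCells)) {
    m[i, ] <- f0 + params@bleachSlope * t +
      (if (responder[i]) params@amplitude * post else 0) +
      stats::rnorm(length(t), 0, params@noiseSd)
  }
  list(mat = cellTraceMatrix(sprintf("cell%03d", seq_len(nCells)), m, t,
                             sourceTag = "synth_slice"),
       drug_onset = drug,
       truth = data.frame(cell_id = sprintf("cell%03d", seq_len(nCells)),
                          responder = responder, stringsAsFactors = FALSE))
}

#' Generate a synthetic gene-by-cell count matrix
#'
#' Clean cells carry ~3000 UMIs with a low mitochondrial fraction;
#' designated cells are generated below the 500-UMI floor or above the 40%
#' mitochondrial ceiling. Cells split into a GABAergic cluster (Slc32a1
#' high) and a glutamatergic cluster (Slc17a6 high), so the
#' median-expression labelling rule has a known answer.
#'
#' @param params A [SynthParams-class].
#' @param nCells Total cells.
#' @param nLowUmi Cells designated low-UMI (< 500).
#' @param nHighMito Cells designated high-mitochondrial (> 40%); disjoint
#'   from the low-UMI set.
#' @param nGenes Total genes (includes Slc32a1, Slc17a6 and three `mt-`
#'   genes).
#' @return List with `counts` (gene x cell matrix), `truth` (data.frame
#'   `cell_id`, `status`, `cluster`).
#' @export
genCountMatrix <- function(params = synthParams(), nCells = 100,
                           nLowUmi = 5, nHighMito = 5, nGenes = 60) {
  if (nLowUmi + nHighMito > nCells)
    pcStop("parameterError",
           "nLowUmi + nHighMito must not exceed nCells")
  if (nGenes < 10) pcStop("parameterError", "need at least 10 genes")
  set.seed(params@seed)
  genes <- c("Slc32a1", "Slc17a6", "mt-Nd1", "mt-Co1", "mt-Cytb",
             sprintf("Gene%03d", seq_len(nGenes - 5)))
  status <- rep("clean", nCells)
  status[seq_len(nLowUmi)] <- "low_umi"
  status[nLowUmi + seq_len(nHighMito)] <- "high_mito"
  cluster <- rep(c("c1", "c2"), length.out = nCells)  # c1 GABA, c2 glut
  counts <- matrix(0L, nGenes, nCells,
                   dimnames = list(genes, sprintf("cell%03d",
                                                  seq_len(nCells))))
  filler <- genes[6:nGenes]
  for (j in seq_len(nCells)) {
    total <- switch(status[j],
      clean = stats::rpois(1, 3000),
      low_umi = sample(100:450, 1),
      high_mito = stats::rpois(1, 3000))
    mitoFrac <- switch(status[j],
      clean = stats::runif(1, 0.02, 0.10),
      low_umi = stats::runif(1, 0.02, 0.10),
      high_mito = stats::runif(1, 0.45, 0.70))
    nMito <- round(total * mitoFrac)
    counts[3:5, j] <- stats::rmultinom(1, nMito, rep(1 / 3, 3))
    rest <- total - nMito
    marker <- round(rest * 0.03) + 1L
    if (cluster[j] == "c1") counts["Slc32a1", j] <- marker
    else counts["Slc17a6", j] <- marker
    counts[filler, j] <- stats::rmultinom(1, rest - marker,
                                          rep(1, length(filler)))
  }
  list(counts = counts,
       truth = data.frame(cell_id = colnames(counts), status = status,
                          cluster = cluster, stringsAsFactors = FALSE))
}
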