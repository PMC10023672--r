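# Micro-endoscope single-cell phenotyping: per-trial Z-scoring of Craw,
# 4-sigma responsiveness, food-specificity classes, NF0 normalization,
# phase scores and seeking/consummatory classification.

#' Per-cell peri-event Z array
#'
#' Cells x trials x time array of baseline Z-scored activity, with trial
#' exclusion flags and per-cell-trial degenerate-baseline flags.
#'
#' @slot z Numeric array cells x trials x time.
#' @slot timeAxis Seconds relative to the aligned event.
#' @slot excluded data.frame `trial_id`, `excluded`, `reason`.
#' @slot degenerate Logical cells x trials matrix (baseline SD was zero).
#' @slot cellIds Character cell identifiers.
#' @export
setClass("CellZArray", representation(
  z = "array", timeAxis = "numeric", excluded = "data.frame",
  degenerate = "matrix", cellIds = "character"
))

setMethod("show", "CellZArray", function(object) {
  d <- dim(object@z)
  cat(sprintf("CellZArray: %d cells x %d trials x %d samples (%d trials excluded)\n",
              d[1], d[2], d[3], sum(object@excluded$excluded)))
})

#' Z-score cell traces around a behavioural event
#'
#' For every cell and trial, Z = (Craw - m) / sigma with m and sigma from
#' the baseline window (default -10..-5 s before behavioural initiation).
#' Trials whose total length (first to last event) exceeds the endoscope
#' limit (25 s) are flagged excluded. Cell-trials with a constant baseline
#' are flagged degenerate; their Z is the noise-free limit (signed Inf
#' where the trace departs the baseline mean, 0 where it equals it), which
#' keeps noiseless synthetic data analysable.
#'
#' @param mat A [CellTraceMatrix-class] (absolute time).
#' @param events An [EventTable-class] with one `alignLabel` event per
#'   trial.
#' @param cfg An [AnalysisConfig-class].
#' @param alignLabel Event marking behavioural initiation (t = 0).
#' @param window Peri-event window (s); must contain the baseline window.
#' @return A [CellZArray-class].
#' @export
zscoreCells <- function(mat, events, cfg = analysisConfig(),
                        alignLabel = "seeking_onset", window = c(-10, 15)) {
  ev <- eventData(events)
  bw <- cfg@baselineWindow
  if (window[1] > bw[1] || window[2] < bw[2])
    pcStop("rangeError", "window must contain the baseline window")
  anchors <- ev[ev$event_label == alignLabel, ]
  if (!nrow(anchors))
    pcStop("inputError", sprintf("no '%s' events found", alignLabel))
  rate <- 1 / stats::median(diff(mat@times))
  axis <- seq(window[1], window[2], by = 1 / rate)
  nC <- nrow(mat@craw); nT <- nrow(anchors)
  z <- array(NA_real_, c(nC, nT, length(axis)))
  degen <- matrix(FALSE, nC, nT)
  exc <- data.frame(trial_id = anchors$trial_id, excluded = FALSE,
                    reason = "", stringsAsFactors = FALSE)
  baseIdx <- axis >= bw[1] & axis <= bw[2]
  for (j in seq_len(nT)) {
    t0 <- anchors$time[j]
    tr <- ev[ev$trial_id == anchors$trial_id[j], ]
    limit <- cfg@trialLengthLimits[tr$session_kind[1]]
    if (!is.na(limit) && diff(range(tr$time)) > limit) {
      exc$excluded[j] <- TRUE
      exc$reason[j] <- "trial_too_long"
    }
    for (i in seq_len(nC)) {
      y <- stats::approx(mat@times, mat@craw[i, ], xout = t0 + axis,
                         rule = 1)$y
      if (anyNA(y)) {
        if (!exc$excluded[j]) {
          exc$excluded[j] <- TRUE
          exc$reason[j] <- "out_of_support"
        }
        next
      }
      m <- mean(y[baseIdx]); s <- stats::sd(y[baseIdx])
      if (s == 0) {
        degen[i, j] <- TRUE
        dev <- y - m
        zi <- numeric(length(y))
        zi[dev > 0] <- Inf
        zi[dev < 0] <- -Inf
        z[i, j, ] <- zi
      } else {
        z[i, j, ] <- (y - m) / s
      }
    }
  }
  new("CellZArray", z = z, timeAxis = axis, excluded = exc,
      degenerate = degen, cellIds = mat@cellIds)
}

#' Call responsive cells at the sigma threshold
#'
#' Averages each cell's Z trace across included trials, takes the maximum
#' over the response window, and calls the cell responsive iff that maximum
#' strictly exceeds the sigma threshold (default 4). A cell with no usable
#' trials, or one that is constant throughout, is not responsive.
#'
#' @param zarr A [CellZArray-class].
#' @param cfg An [AnalysisConfig-class].
#' @param testId Label of the behavioural test (e.g. `"food_1"`,
#'   `"nonfood"`).
#' @param responseWindow Window (s) over which the maximum is taken;
#'   defaults to the config's response window.
#' @return data.frame `cell_id`, `test_id`, `max_z`, `responsive`.
#' @export
callResponsive <- function(zarr, cfg = analysisConfig(), testId = "food_1",
                           responseWindow = cfg@responseWindow) {
  ax <- zarr@timeAxis
  if (responseWindow[1] < min(ax) || responseWindow[2] > max(ax))
    pcStop("rangeError", "response window outside trace support")
  win <- ax >= responseWindow[1] & ax <= responseWindow[2]
  inc <- which(!zarr@excluded$excluded)
  nC <- dim(zarr@z)[1]
  maxZ <- rep(NA_real_, nC)
  for (i in seq_len(nC)) {
    if (!length(inc)) next
    avg <- colMeans(matrix(zarr@z[i, inc, ], nrow = length(inc)))
    if (all(is.na(avg[win]))) next
    maxZ[i] <- max(avg[win], na.rm = TRUE)
  }
  responsive <- !is.na(maxZ) & maxZ > cfg@sigmaThreshold
  data.frame(cell_id = zarr@cellIds, test_id = testId, max_z = maxZ,
             responsive = responsive, stringsAsFactors = FALSE)
}

#' Four-way food-specificity classification
#'
#' Combines responsiveness calls from three food tests and one non-food
#' test per cell: responsive in all three food tests and not in the
#' non-food test is `food_specific`; responsive in all four is
#' `non_specific`; responsive only in the non-food test is
#' `non_food_specific`; responsive in none is `non_responsive`. Cells
#' responsive in some but not all food tests fall outside the four printed
#' definitions and are reported as `unclassified`.
#'
#' @param calls data.frame of [callResponsive()] rows covering test ids
#'   `food_1`, `food_2`, `food_3`, `nonfood` for every cell.
#' @return data.frame `cell_id`, `label`.
#' @export
classifyFoodSpecificity <- function(calls) {
  need <- c("food_1", "food_2", "food_3", "nonfood")
  cells <- unique(calls$cell_id)
  out <- data.frame(cell_id = cells, label = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(cells)) {
    sub <- calls[calls$cell_id == cells[k], ]
    if (!all(need %in% sub$test_id))
      pcStop("inputError",
             sprintf("cell %s: missing test(s): %s", cells[k],
                     paste(setdiff(need, sub$test_id), collapse = ", ")))
    r <- vapply(need, function(tid) sub$responsive[sub$test_id == tid][1],
                logical(1))
    food <- r[1:3]; nonfood <- r[4]
    out$label[k] <-
      if (all(food) && !nonfood) "food_specific"
      else if (all(food) && nonfood) "non_specific"
      else if (!any(food) && nonfood) "non_food_specific"
      else if (!any(food) && !nonfood) "non_responsive"
      else "unclassified"
  }
  out
}

#' NF0 min-max normalization of raw traces
#'
#' Per-cell normalization NF0 = (Craw - min Craw) / (max Craw - min Craw).
#' The range may be supplied explicitly (e.g. computed jointly over the
#' food and no-food sessions of one recording) so that a cell silent in one
#' session still gets a defined NF0 there. Cells with zero range are
#' flagged degenerate and their NF0 set to `NA`.
#'
#' @param mat A [CellTraceMatrix-class].
#' @param range Optional 2-column matrix (min, max) per cell.
#' @return List with `nf0` (cells x time matrix in \[0, 1\]), `degenerate`
#'   (named logical), `range` (the per-cell range used).
#' @export
nf0Normalize <- function(mat, range = NULL) {
  if (is.null(range))
    range <- cbind(apply(mat@craw, 1, min), apply(mat@craw, 1, max))
  degenerate <- range[, 2] - range[, 1] <= 0
  nf0 <- (mat@craw - range[, 1]) / (range[, 2] - range[, 1])
  nf0[degenerate, ] <- NA_real_
  names(degenerate) <- mat@cellIds
  list(nf0 = nf0, degenerate = degenerate, range = range)
}

#' Joint per-cell range across two sessions
#'
#' Min and max of each cell's raw trace over the union of two sessions of
#' the same recording, for use as the `range` argument of
#' [nf0Normalize()].
#'
#' @param matFood,matNoFood [CellTraceMatrix-class] objects with matching
#'   cells.
#' @return 2-column matrix (min, max) per cell.
#' @export
nf0Range <- function(matFood, matNoFood) {
  if (!identical(matFood@cellIds, matNoFood@cellIds))
    pcStop("inputError", "sessions have different cells")
  cbind(pmin(apply(matFood@craw, 1, min), apply(matNoFood@craw, 1, min)),
        pmax(apply(matFood@craw, 1, max), apply(matNoFood@craw, 1, max)))
}

#' Phase scores per cell
#'
#' Computes, averaged over included trials:
#' \itemize{
#'   \item seeking-score-1 (`s1`): NF0 at the food-contact moment of food
#'     trials;
#'   \item seeking-score-2 (`s2`): NF0 at the food-zone-arrival moment of
#'     no-food trials (the contact-equivalent moment; no food exists to
#'     contact);
#'   \item consummatory score (`c`): NF0 at the end of food trials
#'     (consumption end) minus `s1`.
#' }
#' Trials longer than the endoscope limit are excluded. A cell with a
#' degenerate NF0 range, or with no included trials in a session, gets `NA`
#' scores and a non-`"ok"` status instead of aborting the batch.
#'
#' @param nf0Food,nf0NoFood NF0 matrices from [nf0Normalize()] (use a joint
#'   [nf0Range()] so both sessions share the per-cell scale).
#' @param timesFood,timesNoFood Time axes of the two sessions.
#' @param eventsFood,eventsNoFood [EventTable-class] objects. Food trials
#'   need `food_contact` and `consumption_end`; no-food trials need
#'   `food_contact` (zone arrival).
#' @param cellIds Cell identifiers.
#' @param cfg An [AnalysisConfig-class].
#' @return data.frame `cell_id`, `s1`, `s2`, `c`, `status`.
#' @export
phaseScores <- function(nf0Food, timesFood, eventsFood,
                        nf0NoFood, timesNoFood, eventsNoFood,
                        cellIds, cfg = analysisConfig()) {
  evF <- eventData(eventsFood)
  evN <- eventData(eventsNoFood)
  inclTrials <- function(ev) {
    ids <- unique(ev$trial_id)
    keep <- vapply(ids, function(id) {
      tr <- ev[ev$trial_id == id, ]
      limit <- cfg@trialLengthLimits[tr$session_kind[1]]
      is.na(limit) || diff(range(tr$time)) <= limit
    }, logical(1))
    ids[keep]
  }
  idsF <- inclTrials(evF)
  idsN <- inclTrials(evN)
  nC <- nrow(nf0Food)
  out <- data.frame(cell_id = cellIds, s1 = NA_real_, s2 = NA_real_,
                    c = NA_real_, status = "ok", stringsAsFactors = FALSE)
  if (!length(idsF) || !length(idsN)) {
    out$status <- "no_included_trials"
    return(out)
  }
  contactF <- vapply(idsF, function(id)
    evF$time[evF$trial_id == id & evF$event_label == "food_contact"][1],
    numeric(1))
  endF <- vapply(idsF, function(id)
    evF$time[evF$trial_id == id & evF$event_label == "consumption_end"][1],
    numeric(1))
  contactN <- vapply(idsN, function(id)
    evN$time[evN$trial_id == id & evN$event_label == "food_contact"][1],
    numeric(1))
  if (anyNA(contactF) || anyNA(endF) || anyNA(contactN))
    pcStop("inputError", "trials missing food_contact/consumption_end events")
  for (i in seq_len(nC)) {
    if (anyNA(nf0Food[i, ]) || anyNA(nf0NoFood[i, ])) {
      out$status[i] <- "degenerate"
      next
    }
    s1 <- mean(stats::approx(timesFood, nf0Food[i, ], xout = contactF)$y)
    endv <- mean(stats::approx(timesFood, nf0Food[i, ], xout = endF)$y)
    s2 <- mean(stats::approx(timesNoFood, nf0NoFood[i, ], xout = contactN)$y)
    out$s1[i] <- s1
    out$s2[i] <- s2
    out$c[i] <- endv - s1
  }
  out
}

#' Classify cells into seeking / consummatory / ambiguous
#'
#' Applies the phase rule to each cell's scores: a responsive cell is
#' `seeking` iff s1 > c and s2 > 0.4 (NF0 threshold); `consummatory` iff
#' c > s1 or s2 < 0.4; otherwise (exact ties) `ambiguous`. Non-responsive
#' cells are labelled `non_responsive` regardless of scores.
#'
#' @param scores data.frame from [phaseScores()].
#' @param responsive Logical vector, one per cell (from
#'   [callResponsive()]).
#' @param cfg An [AnalysisConfig-class] (`nf0Threshold` is the s2 cut).
#' @return `scores` with a `label` column added.
#' @export
classifyPhase <- function(scores, responsive, cfg = analysisConfig()) {
  thr <- cfg@nf0Threshold
  lab <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    if (!isTRUE(responsive[i])) {
      lab[i] <- "non_responsive"
    } else if (is.na(scores$s1[i]) || is.na(scores$s2[i]) ||
               is.na(scores$c[i])) {
      lab[i] <- "non_responsive"
    } else if (scores$s1[i] > scores$c[i] && scores$s2[i] > thr) {
      lab[i] <- "seeking"
    } else if (scores$c[i] > scores$s1[i] || scores$s2[i] < thr) {
      lab[i] <- "consummatory"
    } else {
      lab[i] <- "ambiguous"
    }
  }
  scores$label <- lab
  scores
}

#' Population label proportions
#'
#' @param labels Character vector of per-cell labels.
#' @return data.frame `label`, `n`, `fraction` (fractions sum to 1).
#' @export
populationProportions <- function(labels) {
  if (!length(labels)) pcStop("inputError", "no cells")
  tab <- table(labels)
  data.frame(label = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / length(labels),
             stringsAsFactors = FALSE)
}
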