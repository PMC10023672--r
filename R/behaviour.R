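# Pose-based consummatory-behaviour extraction: likelihood filtering,
# the three geometric criteria, frame labelling, bout segmentation, and
# the seeking-test success-rate formula.

#' Filter low-likelihood keypoints
#'
#' Points tracked with likelihood below the cutoff (default 0.9) are
#' replaced by linear interpolation between the nearest confident frames of
#' the same bodypart; leading/trailing gaps are held at the nearest
#' confident value. Replaced frames are flagged in the track's
#' `interpolated` matrix.
#'
#' @param track A [KeypointTrack-class].
#' @param cfg An [AnalysisConfig-class] (`likelihoodCutoff`).
#' @return The filtered [KeypointTrack-class].
#' @export
filterLikelihood <- function(track, cfg = analysisConfig()) {
  cut <- cfg@likelihoodCutoff
  coords <- track@coords
  interp <- track@interpolated
  parts <- dimnames(coords)[[2]]
  n <- dim(coords)[1]
  for (p in seq_len(dim(coords)[2])) {
    conf <- coords[, p, 3] >= cut
    if (!any(conf))
      pcStop("trackError",
             sprintf("bodypart '%s' has no frames at or above the likelihood cutoff",
                     parts[p]))
    if (all(conf)) next
    idx <- which(conf)
    for (d in 1:2) {
      coords[, p, d] <- stats::approx(idx, coords[idx, p, d],
                                      xout = seq_len(n), rule = 2)$y
    }
    interp[!conf, p] <- TRUE
  }
  track@coords <- coords
  track@interpolated <- interp
  track
}

pointInPolygon <- function(x, y, poly) {
  # boundary counts as inside
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

checkZone <- function(poly, view) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3 || abs(pracma::polyarea(poly[, 1], poly[, 2])) == 0)
    pcStop("geometryError",
           sprintf("degenerate food-zone polygon for %s view", view))
  poly
}

#' Evaluate the three consummatory-posture criteria per frame
#'
#' For every frame:
#' \itemize{
#'   \item c1: the distance between the left and right front paws is less
#'     than that between the left and right hind paws (bottom view);
#'   \item c2: the y-coordinates decrease strictly from tail base to the
#'     midpoint of the hind paws to the midpoint of the front paws (bottom
#'     view; image coordinates, y down — the tail is lowest in the image);
#'   \item c3: the snout lies inside the food-zone polygon in both views
#'     (boundary counts as inside).
#' }
#'
#' @param bottom,side Filtered [KeypointTrack-class] objects of the two
#'   synchronized views.
#' @return Logical matrix frames x c(c1, c2, c3).
#' @export
evaluateCriteria <- function(bottom, side) {
  zb <- checkZone(bottom@foodZone, "bottom")
  zs <- checkZone(side@foodZone, "side")
  cb <- bottom@coords
  d2 <- function(a, b) sqrt((cb[, a, 1] - cb[, b, 1])^2 +
                              (cb[, a, 2] - cb[, b, 2])^2)
  c1 <- d2("front_paw_L", "front_paw_R") < d2("hind_paw_L", "hind_paw_R")
  midHindY <- (cb[, "hind_paw_L", 2] + cb[, "hind_paw_R", 2]) / 2
  midFrontY <- (cb[, "front_paw_L", 2] + cb[, "front_paw_R", 2]) / 2
  c2 <- cb[, "tail_base", 2] > midHindY & midHindY > midFrontY
  c3 <- pointInPolygon(cb[, "snout", 1], cb[, "snout", 2], zb) &
    pointInPolygon(side@coords[, "snout", 1], side@coords[, "snout", 2], zs)
  cbind(c1 = c1, c2 = c2, c3 = c3)
}

#' Label consummatory frames
#'
#' A frame is consummatory iff all three posture criteria hold
#' simultaneously.
#'
#' @param bottom,side Filtered, frame-synchronized
#'   [KeypointTrack-class] objects.
#' @return Logical vector, one element per frame.
#' @export
labelConsummatoryFrames <- function(bottom, side) {
  if (nFrames(bottom) != nFrames(side))
    pcStop("syncError", "bottom and side tracks have different frame counts")
  crit <- evaluateCriteria(bottom, side)
  unname(crit[, 1] & crit[, 2] & crit[, 3])
}

#' Segment labelled frames into bouts
#'
#' Maximal runs of consummatory frames; runs separated by at most `maxGap`
#' non-consummatory frames are merged, and merged runs shorter than
#' `minDuration` frames are dropped.
#'
#' @param labels Logical per-frame labels.
#' @param fps Frames per second (default 24).
#' @param minDuration Minimum bout length in frames (default 12, i.e.
#'   0.5 s at 24 fps).
#' @param maxGap Maximum merged gap in frames (default 6, i.e. 0.25 s).
#' @return data.frame `bout_id`, `onset_frame`, `offset_frame`,
#'   `duration` (s); zero rows when nothing qualifies.
#' @export
extractBouts <- function(labels, fps = 24, minDuration = 12, maxGap = 6) {
  if (minDuration < 1 || maxGap < 0)
    pcStop("parameterError", "minDuration >= 1 and maxGap >= 0 required")
  empty <- data.frame(bout_id = integer(0), onset_frame = integer(0),
                      offset_frame = integer(0), duration = numeric(0))
  r <- rle(as.logical(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  if (!length(on)) return(empty)
  runs <- data.frame(start = starts[on], end = ends[on])
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1
      if (gap <= maxGap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1 >= minDuration, ,
                   drop = FALSE]
  if (!nrow(merged)) return(empty)
  data.frame(bout_id = seq_len(nrow(merged)),
             onset_frame = merged$start,
             offset_frame = merged$end,
             duration = (merged$end - merged$start + 1) / fps)
}

#' Seeking-test success rate
#'
#' Success rate S2 / W with W = S1 + S2, where S1 is the number of seeking
#' terminations and S2 the number of consumptions after the food cue.
#'
#' @param s1 Count of seeking terminations.
#' @param s2 Count of consumptions after food cue.
#' @return The success fraction in \[0, 1\].
#' @examples
#' successRate(2, 8)  # 0.8
#' @export
successRate <- function(s1, s2) {
  if (s1 < 0 || s2 < 0)
    pcStop("parameterError", "counts must be non-negative")
  if (s1 + s2 == 0)
    pcStop("parameterError", "success rate undefined for S1 + S2 = 0")
  s2 / (s1 + s2)
}
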