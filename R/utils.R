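# Internal condition helpers and polynomial utilities.

# Signal a classed error so callers can distinguish failure modes
# (schemaError, dataError, configError, signalError, rateError, rangeError,
# parameterError, inputError, scoringError, metricError, geometryError,
# syncError, trackError, summaryError).
pcStop <- function(class, msg) {
  cond <- structure(
    class = c(class, "phasecalcError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

pcWarn <- function(class, msg) {
  cond <- structure(
    class = c(class, "phasecalcWarning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cond)
}

# ---- polynomial helpers (coefficients always ascending: a0, a1, ...) ----

polyEvalAsc <- function(coef, x) {
  # Horner on ascending coefficients
  r <- rep(0, length(x))
  for (k in rev(seq_along(coef))) r <- r * x + coef[k]
  r
}

polyDerivAsc <- function(coef) {
  n <- length(coef)
  if (n <= 1) return(0)
  coef[-1] * seq_len(n - 1)
}

polyMulAsc <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Convert p(s) with s = (t - center)/half into coefficients in t.
polyUnscaleAsc <- function(coefS, center, half) {
  out <- c(coefS[1])
  base <- c(-center / half, 1 / half)   # s as a polynomial in t
  pw <- 1
  for (k in seq_along(coefS)[-1]) {
    pw <- polyMulAsc(pw, base)
    padded <- rep(0, max(length(out), length(pw)))
    padded[seq_along(out)] <- out
    padded[seq_along(pw)] <- padded[seq_along(pw)] + coefS[k] * pw
    out <- padded
  }
  out
}

# Least-squares polynomial fit on a scaled abscissa for conditioning.
# Returns ascending t-space coefficients, fitted values and RMS residual.
polyFitRaw <- function(t, y, degree) {
  center <- mean(range(t))
  half <- max(diff(range(t)) / 2, .Machine$double.eps)
  s <- (t - center) / half
  X <- outer(s, 0:degree, `^`)
  coefS <- qr.coef(qr(X), y)
  coefS[is.na(coefS)] <- 0
  fitted <- as.vector(X %*% coefS)
  list(
    coef = polyUnscaleAsc(coefS, center, half),
    fitted = fitted,
    rms = sqrt(mean((y - fitted)^2)),
    center = center,
    half = half
  )
}

# Real roots of an ascending-coefficient polynomial within [lo, hi].
polyRealRoots <- function(coef, lo, hi) {
  nz <- which(abs(coef) > 0)
  if (!length(nz) || max(nz) == 1) return(numeric(0))
  coef <- coef[seq_len(max(nz))]
  r <- polyroot(coef)
  re <- Re(r)[abs(Im(r)) < 1e-7 * (1 + abs(Re(r)))]
  re[re >= lo & re <= hi]
}

# argmax of polynomial over [lo, hi] via critical points + endpoints
polyArgmax <- function(coef, lo, hi) {
  cand <- c(lo, hi, polyRealRoots(polyDerivAsc(coef), lo, hi))
  vals <- polyEvalAsc(coef, cand)
  cand[which.max(vals)]
}

# GCaMP-like step response of a difference-of-exponentials kernel,
# normalized to approach 1: integral of (exp(-u/decay) - exp(-u/rise)).
kernelStepResponse <- function(t, rise, decay) {
  out <- numeric(length(t))
  p <- t > 0
  tp <- t[p]
  out[p] <- (decay * (1 - exp(-tp / decay)) - rise * (1 - exp(-tp / rise))) /
    (decay - rise)
  out
}

# Integral of the step response: response to a unit-slope ramp starting at
# 0. A linear firing-rate ramp convolved with the kernel is a difference of
# these, and its third time-derivative peaks exactly at the ramp onset.
kernelRampResponse <- function(t, rise, decay) {
  out <- numeric(length(t))
  p <- t > 0
  tp <- t[p]
  out[p] <- (decay * (tp + decay * (exp(-tp / decay) - 1)) -
               rise * (tp + rise * (exp(-tp / rise) - 1))) / (decay - rise)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
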