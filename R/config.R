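#' Build an analysis configuration
#'
#' All arguments default to the study constants: baseline window -10..-5 s
#' before behavioural initiation, response window 0..10 s after it,
#' activation threshold 4 sigma, NF0 threshold 0.4, trial-length limits of
#' 15 s (multi-phase), 10 s (other) and 25 s (endoscope), keypoint
#' likelihood cutoff 0.9.
#'
#' @param baseline_window Length-2 numeric, seconds relative to the event.
#' @param response_window Length-2 numeric, seconds relative to the event.
#' @param sigma_threshold Activation threshold in baseline-SD units.
#' @param nf0_threshold Seeking-score-2 cut in NF0 units.
#' @param trial_length_limits Named numeric of maximum trial lengths (s).
#' @param likelihood_cutoff Keypoint likelihood cutoff in (0, 1).
#' @param seed Integer seed.
#' @return An [AnalysisConfig-class].
#' @examples
#' cfg <- analysisConfig()
#' cfg
#' @export
analysisConfig <- function(baseline_window = c(-10, -5),
                           response_window = c(0, 10),
                           sigma_threshold = 4,
                           nf0_threshold = 0.4,
                           trial_length_limits = c(multi_phase = 15,
                                                   other = 10,
                                                   endoscope = 25),
                           likelihood_cutoff = 0.9,
                           seed = 1L) {
  if (length(baseline_window) != 2 || baseline_window[1] >= baseline_window[2])
    pcStop("configError", "baseline_window must satisfy start < end")
  if (length(response_window) != 2 || response_window[1] >= response_window[2])
    pcStop("configError", "response_window must satisfy start < end")
  if (sigma_threshold <= 0)
    pcStop("configError", "sigma_threshold must be > 0")
  if (nf0_threshold <= 0)
    pcStop("configError", "nf0_threshold must be > 0")
  new("AnalysisConfig",
      baselineWindow = as.numeric(baseline_window),
      responseWindow = as.numeric(response_window),
      sigmaThreshold = sigma_threshold, nf0Threshold = nf0_threshold,
      trialLengthLimits = trial_length_limits,
      likelihoodCutoff = likelihood_cutoff, seed = as.integer(seed))
}

#' Load an analysis configuration from YAML or JSON
#'
#' Keys absent from the file take the defaults of [analysisConfig()];
#' unknown keys are a configuration error (they usually signal a typo).
#'
#' @param path Path to a YAML or JSON document of configuration keys.
#' @return An [AnalysisConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) pcStop("configError", paste("no such file:", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- c("baseline_window", "response_window", "sigma_threshold",
             "nf0_threshold", "trial_length_limits", "likelihood_cutoff",
             "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    pcStop("configError",
           paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  if (!is.null(raw$trial_length_limits))
    raw$trial_length_limits <- unlist(raw$trial_length_limits)
  do.call(analysisConfig, raw)
}
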