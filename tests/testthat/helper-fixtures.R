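# Shared fixture builders (all fixtures are generated in code).

# a peri-event tensor built directly, bypassing alignment
mkTensor <- function(rows, axis, excluded = rep(FALSE, nrow(rows))) {
  new("PeriEventTensor", Z = rows, timeAxis = axis,
      baselineStats = data.frame(trial_id = seq_len(nrow(rows)),
                                 m = NA_real_, sigma = NA_real_),
      excluded = data.frame(trial_id = seq_len(nrow(rows)),
                            excluded = excluded,
                            reason = ifelse(excluded, "test", "")))
}

# a single-cell, single-trial Z array with a given peak value
mkZArray <- function(peak, axis = seq(-10, 15, by = 0.1)) {
  z <- array(0, c(1, 1, length(axis)))
  z[1, 1, which.min(abs(axis - 5))] <- peak
  new("CellZArray", z = z, timeAxis = axis,
      excluded = data.frame(trial_id = 1, excluded = FALSE, reason = ""),
      degenerate = matrix(FALSE, 1, 1), cellIds = "cellA")
}

mkEvents <- function(trial_id, labels, times, kind) {
  eventTable(data.frame(trial_id = trial_id, event_label = labels,
                        time = times, session_kind = kind,
                        stringsAsFactors = FALSE))
}

# responsiveness-call table for one cell from a TTTF-style pattern
mkCalls <- function(pattern, cell = "c1") {
  data.frame(cell_id = cell,
             test_id = c("food_1", "food_2", "food_3", "nonfood"),
             max_z = ifelse(pattern, 5, 1), responsive = pattern,
             stringsAsFactors = FALSE)
}
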