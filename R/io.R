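# CSV readers/writers for the pipeline's domain objects.
#
# All tables are plain CSV with one header row. Writers append a
# `# rows=N` footer; readers verify it when present, so silently
# truncated files are rejected.

readCsvChecked <- function(path) {
  if (!file.exists(path)) pcStop("dataError", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  footer <- grep("^#\\s*rows=", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1) pcStop("schemaError", paste("empty file:", path))
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (length(footer)) {
    n <- as.integer(sub("^#\\s*rows=\\s*", "", footer[length(footer)]))
    if (!is.na(n) && n != nrow(df))
      pcStop("dataError",
             sprintf("%s: row-count footer says %d rows, found %d (truncated file?)",
                     path, n, nrow(df)))
  }
  df
}

requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    pcStop("schemaError",
           sprintf("%s: missing column(s): %s", path,
                   paste(miss, collapse = ", ")))
}

#' Read a pipeline input table
#'
#' Parses one of the pipeline's CSV dialects into its validated domain
#' object. Time units are seconds throughout.
#'
#' Schemas:
#' \describe{
#'   \item{two_channel}{columns `time`, `ch465`, `ch405` (optional
#'     `session_id`) -> [TwoChannelRecording-class]}
#'   \item{cell_matrix}{column `time` plus one column per cell ->
#'     [CellTraceMatrix-class]}
#'   \item{events}{columns `trial_id`, `event_label`, `time`,
#'     `session_kind` -> [EventTable-class]}
#'   \item{sipsc_events}{columns `cell_id`, `condition`, `time`,
#'     `amplitude` -> validated data.frame (see [sipscRecord()])}
#'   \item{counts}{column `gene` plus one column per cell -> gene x cell
#'     integer matrix}
#' }
#'
#' @param path CSV file path.
#' @param schema One of `"two_channel"`, `"cell_matrix"`, `"events"`,
#'   `"sipsc_events"`, `"counts"`.
#' @return The schema's domain object (see Details).
#' @export
readTraceTable <- function(path,
                           schema = c("two_channel", "cell_matrix", "events",
                                      "sipsc_events", "counts")) {
  schema <- match.arg(schema)
  df <- readCsvChecked(path)
  switch(schema,
    two_channel = {
      requireColumns(df, c("time", "ch465", "ch405"), path)
      if (is.unsorted(df$time, strictly = TRUE))
        pcStop("dataError", paste(path, ": time must be strictly increasing"))
      sid <- if ("session_id" %in% names(df)) as.character(df$session_id[1])
             else "session"
      twoChannelRecording(trace(df$time, df$ch465),
                          trace(df$time, df$ch405), sessionId = sid)
    },
    cell_matrix = {
      requireColumns(df, "time", path)
      if (is.unsorted(df$time, strictly = TRUE))
        pcStop("dataError", paste(path, ": time must be strictly increasing"))
      cells <- setdiff(names(df), "time")
      if (!length(cells))
        pcStop("schemaError", paste(path, ": no cell columns found"))
      mat <- t(as.matrix(df[cells]))
      if (anyNA(mat))
        pcStop("dataError", paste(path, ": missing samples in cell matrix"))
      cellTraceMatrix(cells, mat, df$time, sourceTag = "csv")
    },
    events = {
      requireColumns(df, c("trial_id", "event_label", "time", "session_kind"),
                     path)
      obj <- try(eventTable(df), silent = TRUE)
      if (inherits(obj, "try-error")) {
        msg <- conditionMessage(attr(obj, "condition"))
        if (grepl("label", msg)) pcStop("schemaError", paste0(path, ": ", msg))
        pcStop("dataError", paste0(path, ": ", msg))
      }
      obj
    },
    sipsc_events = {
      requireColumns(df, c("cell_id", "condition", "time", "amplitude"), path)
      bad <- setdiff(unique(df$condition), c("ACSF", "NPY"))
      if (length(bad))
        pcStop("schemaError",
               sprintf("%s: unknown condition(s): %s", path,
                       paste(bad, collapse = ", ")))
      df
    },
    counts = {
      requireColumns(df, "gene", path)
      cells <- setdiff(names(df), "gene")
      if (!length(cells))
        pcStop("schemaError", paste(path, ": no cell columns found"))
      mat <- as.matrix(df[cells])
      rownames(mat) <- df$gene
      if (anyNA(mat) || any(mat < 0))
        pcStop("dataError", paste(path, ": counts must be non-negative and complete"))
      mat
    })
}

#' Write a pipeline table
#'
#' Writes the CSV dialect that [readTraceTable()] reads back, including the
#' row-count footer used to detect truncation. Dispatch follows the object
#' class; matrices are written under the `counts` schema.
#'
#' @param object A [TwoChannelRecording-class], [CellTraceMatrix-class],
#'   [EventTable-class], sIPSC event data.frame, or gene x cell matrix.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
setGeneric("writeTraceTable", function(object, path)
  standardGeneric("writeTraceTable"))

writeWithFooter <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cat(sprintf("# rows=%d\n", nrow(df)), file = path, append = TRUE)
  invisible(path)
}

#' @rdname writeTraceTable
setMethod("writeTraceTable", "TwoChannelRecording", function(object, path) {
  writeWithFooter(data.frame(time = object@ch465@times,
                             ch465 = object@ch465@values,
                             ch405 = object@ch405@values,
                             session_id = object@sessionId), path)
})

#' @rdname writeTraceTable
setMethod("writeTraceTable", "CellTraceMatrix", function(object, path) {
  df <- data.frame(time = object@times)
  for (i in seq_along(object@cellIds)) df[[object@cellIds[i]]] <- object@craw[i, ]
  writeWithFooter(df, path)
})

#' @rdname writeTraceTable
setMethod("writeTraceTable", "EventTable", function(object, path) {
  writeWithFooter(object@events, path)
})

#' @rdname writeTraceTable
setMethod("writeTraceTable", "data.frame", function(object, path) {
  writeWithFooter(object, path)
})

#' @rdname writeTraceTable
setMethod("writeTraceTable", "matrix", function(object, path) {
  df <- data.frame(gene = rownames(object), check.names = FALSE)
  for (j in seq_len(ncol(object))) df[[colnames(object)[j]]] <- object[, j]
  writeWithFooter(df, path)
})
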