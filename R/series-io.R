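# CSV I/O and validation for MIMIC-numerics-style vital-sign tables.
# Dialect: comma separator, '.' decimal, UTF-8, mandatory header row,
# optional leading time column 't'. Non-numeric cells become NA (explicit
# missing markers); zeros are genuine readings (a monitor can report SpO2=0)
# and are never treated as missing.

#' Read a vital-sign series from CSV
#'
#' Expects a header row; a column named \code{t} (case-sensitive) is taken as
#' the sample time, otherwise the 1-based row index is used. All remaining
#' columns are parsed as numeric parameters; non-numeric cells become
#' explicit \code{NA} markers. When all five canonical parameters are present
#' the columns are reordered to (ABPmean, HR, Pulse, Respiration, SpO2);
#' extra columns are passed through after them.
#'
#' @param path Path to a CSV file.
#' @return A \linkS4class{VitalSeries}.
#' @seealso [writeSeries()], [validateSeries()]
#' @export
readSeries <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stopf("empty file: %s", path)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  ncols <- length(header)
  body <- lines[-1L]
  cells <- strsplit(body, ",", fixed = TRUE)
  ragged <- which(lengths(cells) != ncols)
  if (length(ragged))
    stopf("ragged row at line %d: expected %d fields, found %d",
          ragged[1L] + 1L, ncols, lengths(cells)[ragged[1L]])
  mat <- if (length(body)) {
    m <- suppressWarnings(
      matrix(as.numeric(trimws(unlist(cells))), nrow = length(body),
             ncol = ncols, byrow = TRUE))
    colnames(m) <- header
    m
  } else {
    matrix(numeric(0), nrow = 0L, ncol = ncols, dimnames = list(NULL, header))
  }
  if ("t" %in% header) {
    times <- mat[, "t"]
    mat <- mat[, setdiff(header, "t"), drop = FALSE]
  } else {
    times <- seq_len(nrow(mat))
  }
  if (all(CANONICAL_PARAMETERS %in% colnames(mat))) {
    ord <- c(CANONICAL_PARAMETERS,
             setdiff(colnames(mat), CANONICAL_PARAMETERS))
    mat <- mat[, ord, drop = FALSE]
  }
  VitalSeries(mat, times = times)
}

#' Write a vital-sign series to CSV
#'
#' Emits a header \code{t,<param1>,...} and the values with enough digits
#' (15 significant) that a write/read round trip is lossless for finite
#' values. \code{NA} readings are written as empty cells.
#'
#' @param series A \linkS4class{VitalSeries}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeSeries <- function(series, path) {
  stopifnot(is(series, "VitalSeries"))
  v <- vitalValues(series)
  df <- data.frame(t = seriesTimes(series), v, check.names = FALSE)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
  out <- c(paste(colnames(df), collapse = ","),
           if (nrow(df)) apply(df, 1L, function(r)
             paste(fmt(as.numeric(r)), collapse = ",")))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Write ground-truth labels as a sidecar CSV
#'
#' Columns \code{index,label,event_id}: 1-based instant index, its label, and
#' the id (list position) of the covering event or empty for normal instants.
#'
#' @param labeled A \linkS4class{LabeledSeries}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeLabels <- function(labeled, path) {
  stopifnot(is(labeled, "LabeledSeries"))
  ids <- rep(NA_integer_, length(labeled))
  evs <- seriesEvents(labeled)
  for (i in seq_along(evs)) ids[eventWindow(evs[[i]])] <- i
  df <- data.frame(index = seq_len(length(labeled)),
                   label = seriesLabels(labeled),
                   event_id = ifelse(is.na(ids), "", ids))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sidecar label CSV back into labels and event windows
#'
#' @param path Path written by [writeLabels()].
#' @return A list with \code{labels} (character vector) and \code{events}
#'   (list of \linkS4class{EventSpec}s reconstructed with the labeled kind,
#'   window, and unknown magnitude 1 on parameter \code{"?"} when the original
#'   specs are unavailable). Intended for evaluation alignment, not re-injection.
#' @keywords internal
readLabels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- df$label
  events <- list()
  eid <- as.character(df$event_id)
  eid[is.na(eid)] <- ""
  ids <- unique(eid[nzchar(eid)])
  for (id in ids) {
    idx <- df$index[eid == id]
    kind <- unique(labels[idx])
    events[[length(events) + 1L]] <-
      eventSpec(kind, start = min(idx), duration = length(idx),
                parameters = "?", magnitude = 1, direction = 1)
  }
  list(labels = labels, events = events)
}

#' Validate a vital-sign series
#'
#' Pure reporting: never mutates the data. Findings cover runs of missing
#' values, non-monotone times, and out-of-physical-range readings (SpO2
#' outside \[0, 100\], negative vitals).
#'
#' @param series A \linkS4class{VitalSeries}.
#' @return A data.frame with columns \code{type}, \code{parameter},
#'   \code{index}, \code{message}; zero rows for a clean series.
#' @export
validateSeries <- function(series) {
  stopifnot(is(series, "VitalSeries"))
  findings <- list()
  add <- function(type, parameter, index, message)
    findings[[length(findings) + 1L]] <<-
      data.frame(type = type, parameter = parameter, index = index,
                 message = message)
  tm <- seriesTimes(series)
  if (length(tm) > 1L) {
    bad <- which(diff(tm) <= 0)
    for (i in bad)
      add("non_monotone_time", "", i + 1L,
          sprintf("time does not increase between rows %d and %d", i, i + 1L))
  }
  v <- vitalValues(series)
  for (p in colnames(v)) {
    x <- v[, p]
    miss <- rle(is.na(x))
    ends <- cumsum(miss$lengths)
    starts <- ends - miss$lengths + 1L
    for (j in which(miss$values))
      add("missing_run", p, starts[j],
          sprintf("%d consecutive missing value(s) starting at row %d",
                  miss$lengths[j], starts[j]))
    if (identical(p, "SpO2")) {
      for (i in which(!is.na(x) & (x < 0 | x > 100)))
        add("out_of_range", p, i,
            sprintf("SpO2 %.6g outside [0, 100] at row %d", x[i], i))
    } else {
      for (i in which(!is.na(x) & x < 0))
        add("out_of_range", p, i,
            sprintf("negative %s %.6g at row %d", p, x[i], i))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(type = character(0), parameter = character(0),
                  index = integer(0), message = character(0))
}
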