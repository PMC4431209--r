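# Scoring decisions against ground truth: confusion counts, detection rate,
# false positive rate, ROC sweep over the number of voting parameters, and
# the fixed-vs-dynamic threshold comparison.

#' Score alarm decisions against ground truth
#'
#' Positive class = true alarm (true medical condition); negative class =
#' false alarm (sensor fault). Event-level scoring (default, matching how
#' alarms are counted in practice) gives each ground-truth event one
#' outcome: a medical event is a TP if any decision inside its window is
#' \code{"true_alarm"} (else FN); a sensor fault is an FP if its window is
#' ever declared \code{"true_alarm"} (else TN). Instant-level scoring scores
#' every decision instant covered by an event the same way, one count per
#' instant; normal instants are not scored (they belong to neither alarm
#' class).
#'
#' @param decisions Decision data.frame from [runPipeline()].
#' @param truth A \linkS4class{LabeledSeries}, or a list with elements
#'   \code{labels} (per-instant) and \code{events} (list of
#'   \linkS4class{EventSpec}s).
#' @param mode \code{"event"} (default) or \code{"instant"}.
#' @return A \linkS4class{ConfusionCounts}.
#' @seealso [detectionRate()], [falsePositiveRate()], [rocSweep()]
#' @export
scoreDecisions <- function(decisions, truth, mode = c("event", "instant")) {
  mode <- match.arg(mode)
  if (is(truth, "LabeledSeries"))
    truth <- list(labels = seriesLabels(truth), events = seriesEvents(truth))
  labels <- truth$labels
  events <- truth$events
  if (nrow(decisions) && max(decisions$t) > length(labels))
    stopf("decisions extend to instant %d but truth has only %d labels",
          max(decisions$t), length(labels))
  TP <- FP <- TN <- FN <- 0L
  if (identical(mode, "event")) {
    for (ev in events) {
      w <- eventWindow(ev)
      declared <- any(decisions$verdict[decisions$t %in% w] == "true_alarm")
      if (identical(ev@kind, "medical_event")) {
        if (declared) TP <- TP + 1L else FN <- FN + 1L
      } else {
        if (declared) FP <- FP + 1L else TN <- TN + 1L
      }
    }
  } else {
    lab <- labels[decisions$t]
    alarm <- decisions$verdict == "true_alarm"
    TP <- sum(lab == "medical_event" & alarm)
    FN <- sum(lab == "medical_event" & !alarm)
    FP <- sum(lab == "sensor_fault" & alarm)
    TN <- sum(lab == "sensor_fault" & !alarm)
  }
  confusionCounts(TP = TP, FP = FP, TN = TN, FN = FN)
}

#' @rdname detectionRate
#' @export
setMethod("detectionRate", "ConfusionCounts", function(x) {
  if (x@TP + x@FN == 0L) {
    warning("detection rate undefined: TP + FN = 0 (no positive events scored)")
    return(NA_real_)
  }
  x@TP / (x@TP + x@FN)
})

#' @rdname falsePositiveRate
#' @export
setMethod("falsePositiveRate", "ConfusionCounts", function(x) {
  if (x@FP + x@TN == 0L) {
    warning("false positive rate undefined: FP + TN = 0 (no negative events scored)")
    return(NA_real_)
  }
  x@FP / (x@FP + x@TN)
})

# Restrict a labeled series to its first k parameters (canonical order);
# labels and event windows are kept so that events on hidden parameters are
# still scored (an undetectable fault should count as a true negative).
firstKParameters <- function(labeled, k) {
  stopifnot(is(labeled, "LabeledSeries"))
  if (k < 1L || k > nParameters(labeled))
    stopf("k = %d outside 1..%d", k, nParameters(labeled))
  params <- parameterNames(labeled)[seq_len(k)]
  new("LabeledSeries",
      values = labeled@values[, params, drop = FALSE],
      times = labeled@times, units = labeled@units[params],
      labels = labeled@labels, events = labeled@events)
}

#' ROC sweep over the number of voting parameters
#'
#' Reruns detection using only the first k parameters (canonical column
#' order) for each requested k, scores each run event-level against the same
#' ground truth, and reports one (k, DR, FPR) operating point per k. Varying
#' how many parameters vote moves the majority-voting operating point and
#' traces the ROC; the injected anomalies are held fixed so points are
#' comparable.
#'
#' @param labeled A \linkS4class{LabeledSeries} benchmark (e.g. from
#'   [makeBenchmark()]).
#' @param config A \linkS4class{PipelineConfig}.
#' @param kValues Integer vector, each in 1..n (default \code{1:n}).
#' @param mode Scoring mode passed to [scoreDecisions()].
#' @return A data.frame with columns \code{k}, \code{TP}, \code{FP},
#'   \code{TN}, \code{FN}, \code{DR}, \code{FPR}.
#' @export
rocSweep <- function(labeled, config = pipelineConfig(),
                     kValues = seq_len(nParameters(labeled)),
                     mode = "event") {
  rows <- lapply(kValues, function(k) {
    sub <- firstKParameters(labeled, k)
    cc <- scoreDecisions(runPipeline(sub, config), sub, mode = mode)
    data.frame(k = k, TP = cc@TP, FP = cc@FP, TN = cc@TN, FN = cc@FN,
               DR = suppressWarnings(detectionRate(cc)),
               FPR = suppressWarnings(falsePositiveRate(cc)))
  })
  do.call(rbind, rows)
}

#' Compare dynamic and fixed thresholding on one benchmark
#'
#' Runs the pipeline twice on the same labeled series — once with the sliding
#' dynamic threshold \eqn{T_d} and once with the fixed threshold \eqn{T_f}
#' (the SD of the initial window, never updated) — and reports both modes'
#' confusion counts, DR and FPR side by side.
#'
#' @param labeled A \linkS4class{LabeledSeries}.
#' @param config A \linkS4class{PipelineConfig}; its \code{thresholdMode} is
#'   overridden per run.
#' @param mode Scoring mode passed to [scoreDecisions()].
#' @return A data.frame with one row per mode: \code{mode}, \code{TP},
#'   \code{FP}, \code{TN}, \code{FN}, \code{DR}, \code{FPR},
#'   \code{nTrueAlarmInstants}.
#' @export
thresholdModeComparison <- function(labeled, config = pipelineConfig(),
                                    mode = "event") {
  stopifnot(is(labeled, "LabeledSeries"))
  rows <- lapply(c("dynamic", "fixed"), function(tm) {
    cfg <- config
    cfg@thresholdMode <- tm
    dec <- runPipeline(labeled, cfg)
    cc <- scoreDecisions(dec, labeled, mode = mode)
    data.frame(mode = tm, TP = cc@TP, FP = cc@FP, TN = cc@TN, FN = cc@FN,
               DR = suppressWarnings(detectionRate(cc)),
               FPR = suppressWarnings(falsePositiveRate(cc)),
               nTrueAlarmInstants = sum(dec$verdict == "true_alarm"))
  })
  do.call(rbind, rows)
}
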