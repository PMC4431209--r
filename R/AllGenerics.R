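#' Parameter names of a vital-sign series
#'
#' @param x A \linkS4class{VitalSeries} (or derived) object.
#' @return Character vector of physiological parameter names, in canonical
#'   column order.
#' @export
setGeneric("parameterNames", function(x) standardGeneric("parameterNames"))

#' Sample times of a series
#'
#' @param x A \linkS4class{VitalSeries} object.
#' @return Numeric vector of strictly increasing sample times (sample indices
#'   when no explicit clock is attached).
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' Value matrix of a series
#'
#' @param x A \linkS4class{VitalSeries} object.
#' @return Numeric matrix, one row per time instant, one column per parameter,
#'   in native units. Missing readings are \code{NA}.
#' @export
setGeneric("vitalValues", function(x) standardGeneric("vitalValues"))

#' Measurement units of a series
#'
#' @param x A \linkS4class{VitalSeries} object.
#' @return Named character vector mapping parameter name to unit string.
#' @export
setGeneric("vitalUnits", function(x) standardGeneric("vitalUnits"))

#' Number of physiological parameters
#'
#' @param x A \linkS4class{VitalSeries} object.
#' @return Integer count of monitored parameters.
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))

#' Per-instant ground-truth labels
#'
#' @param x A \linkS4class{LabeledSeries} object.
#' @return Character vector, one of \code{"normal"}, \code{"medical_event"},
#'   \code{"sensor_fault"} per instant.
#' @export
setGeneric("seriesLabels", function(x) standardGeneric("seriesLabels"))

#' Injected events of a labeled series
#'
#' @param x A \linkS4class{LabeledSeries} object.
#' @return List of \linkS4class{EventSpec} objects, in injection order.
#' @export
setGeneric("seriesEvents", function(x) standardGeneric("seriesEvents"))

#' One-step-ahead prediction from a fitted window model
#'
#' @param model A fitted \linkS4class{SVRModel}.
#' @param t Sample index immediately following the fitted window. The pipeline
#'   only ever forecasts one step ahead; any other index is a contract
#'   violation.
#' @return Predicted value, native units, finite.
#' @export
setGeneric("predictNext", function(model, t) standardGeneric("predictNext"))

#' Push a value into a sliding threshold buffer
#'
#' @param state A \linkS4class{ThresholdState}.
#' @param value New accepted reading (native units). Non-finite values are
#'   rejected and the state returned unchanged (with a warning).
#' @return Updated \linkS4class{ThresholdState}: oldest element evicted when
#'   the buffer is full, \code{value} appended, threshold recomputed.
#' @export
setGeneric("updateThreshold", function(state, value) standardGeneric("updateThreshold"))

#' Current standard deviation of a threshold buffer
#'
#' @param state A \linkS4class{ThresholdState}.
#' @return Sample standard deviation (n-1 denominator) of the buffer; 0 for a
#'   buffer with fewer than two values.
#' @export
setGeneric("thresholdSd", function(state) standardGeneric("thresholdSd"))

#' Current dynamic threshold value
#'
#' @param state A \linkS4class{ThresholdState}.
#' @return \code{kMult * thresholdSd(state)}, native units.
#' @export
setGeneric("thresholdValue", function(state) standardGeneric("thresholdValue"))

#' Detection rate (sensitivity) from confusion counts
#'
#' Detection rate is TP / (TP + FN): the fraction of true medical conditions
#' that were declared true alarms.
#'
#' @param x A \linkS4class{ConfusionCounts} object.
#' @return Fraction in \[0, 1\]; \code{NA} with a warning when TP + FN = 0
#'   (undefined, never silently 0/0).
#' @export
setGeneric("detectionRate", function(x) standardGeneric("detectionRate"))

#' False positive rate from confusion counts
#'
#' False positive rate is FP / (FP + TN): the fraction of sensor faults
#' (actual false alarms) wrongly declared true alarms.
#'
#' @param x A \linkS4class{ConfusionCounts} object.
#' @return Fraction in \[0, 1\]; \code{NA} with a warning when FP + TN = 0.
#' @export
setGeneric("falsePositiveRate", function(x) standardGeneric("falsePositiveRate"))
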