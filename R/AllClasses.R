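#' @import methods
NULL

CANONICAL_PARAMETERS <- c("ABPmean", "HR", "Pulse", "Respiration", "SpO2")

CANONICAL_UNITS <- c(
  ABPmean     = "mmHg",
  HR          = "bpm",
  Pulse       = "bpm",
  Respiration = "breaths/min",
  SpO2        = "%"
)

VALID_LABELS <- c("normal", "medical_event", "sensor_fault")

# ---------------------------------------------------------------------------
# VitalSeries
# ---------------------------------------------------------------------------

#' VitalSeries: an ordered multivariate vital-sign stream
#'
#' Holds one row per time instant and one column per physiological parameter
#' (native units). The instant-t observation is the vector
#' \eqn{A_t = (a_{t,1}, \dots, a_{t,n})} of the n parameters collected by the
#' patient's N sensors (n >= N; two parameters may come from one device).
#' Missing readings are explicit \code{NA}, never dropped, so that downstream
#' stages can abstain rather than silently impute.
#'
#' @slot values Numeric matrix, rows = instants, columns = parameters; column
#'   names are the parameter names.
#' @slot times Strictly increasing numeric sample times. Defaults to the
#'   1-based row index when no clock is given.
#' @slot units Named character vector, one unit string per parameter.
#'
#' @seealso [VitalSeries()] constructor, [readSeries()], [generateVitals()]
#' @name VitalSeries-class
#' @aliases VitalSeries-class
#' @export
setClass("VitalSeries",
  representation(
    values = "matrix",
    times  = "numeric",
    units  = "character"
  )
)

setValidity("VitalSeries", function(object) {
  v <- object@values
  msgs <- character(0)
  if (!is.numeric(v)) msgs <- c(msgs, "'values' must be a numeric matrix")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)) || any(!nzchar(colnames(v))))
    msgs <- c(msgs, "'values' must have unique, non-empty column names")
  if (ncol(v) < 1L) msgs <- c(msgs, "at least one parameter is required")
  if (length(object@times) != nrow(v))
    msgs <- c(msgs, "'times' length must equal the number of rows")
  # monotonicity is a data-quality finding reported by validateSeries(), not
  # a hard invariant: files with duplicated clock stamps must stay readable
  if (anyNA(object@times) || any(!is.finite(object@times)))
    msgs <- c(msgs, "'times' must be finite and non-missing")
  if (!identical(sort(names(object@units)), sort(colnames(v))))
    msgs <- c(msgs, "'units' must be named by the parameter names")
  if (length(msgs)) msgs else TRUE
})

#' Construct a VitalSeries
#'
#' @param values Numeric matrix (instants x parameters) or data.frame of
#'   numeric columns; column names are parameter names.
#' @param times Optional strictly increasing sample times; defaults to the
#'   1-based row index.
#' @param units Optional named character vector of units; canonical units are
#'   filled in for the standard parameters (ABPmean mmHg, HR/Pulse bpm,
#'   Respiration breaths/min, SpO2 %), others default to \code{""}.
#' @return A \linkS4class{VitalSeries}.
#' @examples
#' vs <- VitalSeries(cbind(HR = c(72, 74, 73), SpO2 = c(98, 97, 98)))
#' parameterNames(vs)
#' @export
VitalSeries <- function(values, times = NULL, units = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(times)) times <- seq_len(nrow(values))
  params <- colnames(values)
  u <- ifelse(params %in% names(CANONICAL_UNITS), CANONICAL_UNITS[params], "")
  names(u) <- params
  if (!is.null(units)) u[names(units)] <- units
  new("VitalSeries", values = values, times = as.numeric(times), units = u)
}

#' @rdname parameterNames
#' @export
setMethod("parameterNames", "VitalSeries", function(x) colnames(x@values))

#' @rdname seriesTimes
#' @export
setMethod("seriesTimes", "VitalSeries", function(x) x@times)

#' @rdname vitalValues
#' @export
setMethod("vitalValues", "VitalSeries", function(x) x@values)

#' @rdname vitalUnits
#' @export
setMethod("vitalUnits", "VitalSeries", function(x) x@units)

#' @rdname nParameters
#' @export
setMethod("nParameters", "VitalSeries", function(x) ncol(x@values))

#' @describeIn VitalSeries-class number of time instants
#' @param x A VitalSeries.
#' @export
setMethod("length", "VitalSeries", function(x) nrow(x@values))

setMethod("show", "VitalSeries", function(object) {
  cat(sprintf("%s with %d instants x %d parameters\n",
              class(object), nrow(object@values), ncol(object@values)))
  u <- object@units[colnames(object@values)]
  cat("  parameters:",
      paste(sprintf("%s [%s]", names(u), ifelse(nzchar(u), u, "?")),
            collapse = ", "), "\n")
  if (anyNA(object@values))
    cat(sprintf("  missing readings: %d\n", sum(is.na(object@values))))
})

# ---------------------------------------------------------------------------
# EventSpec
# ---------------------------------------------------------------------------

#' EventSpec: one injectable anomaly
#'
#' Describes a window of perturbed readings. A \code{sensor_fault} perturbs
#' exactly one parameter (uncorrelated, device-caused); a
#' \code{medical_event} co-perturbs a strict majority of the parameters
#' (correlated physiological change). Affected values x are replaced by
#' \code{x * (1 + direction * magnitude)}.
#'
#' @slot kind \code{"medical_event"} or \code{"sensor_fault"}.
#' @slot start 1-based index of the first perturbed instant.
#' @slot duration Number of perturbed instants.
#' @slot parameters Affected parameter names.
#' @slot magnitude Positive perturbation fraction (0.20, 0.30 and 0.50 are the
#'   conventional levels).
#' @slot direction Named numeric vector of +1/-1 per affected parameter.
#'
#' @seealso [eventSpec()], [injectEvent()]
#' @name EventSpec-class
#' @export
setClass("EventSpec",
  representation(
    kind       = "character",
    start      = "integer",
    duration   = "integer",
    parameters = "character",
    magnitude  = "numeric",
    direction  = "numeric"
  )
)

setValidity("EventSpec", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("medical_event", "sensor_fault"))
    msgs <- c(msgs, "kind must be 'medical_event' or 'sensor_fault'")
  if (object@start < 1L) msgs <- c(msgs, "start must be >= 1")
  if (object@duration < 1L) msgs <- c(msgs, "duration must be >= 1")
  if (length(object@parameters) < 1L)
    msgs <- c(msgs, "at least one affected parameter is required")
  if (identical(object@kind, "sensor_fault") && length(object@parameters) != 1L)
    msgs <- c(msgs, "a sensor_fault affects exactly one parameter")
  if (!is.finite(object@magnitude) || object@magnitude <= 0)
    msgs <- c(msgs, "magnitude must be a positive fraction")
  if (!identical(sort(names(object@direction)), sort(object@parameters)))
    msgs <- c(msgs, "direction must be named by the affected parameters")
  if (!all(object@direction %in% c(-1, 1)))
    msgs <- c(msgs, "direction entries must be +1 or -1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EventSpec
#'
#' @param kind \code{"medical_event"} or \code{"sensor_fault"}.
#' @param start 1-based first perturbed instant.
#' @param duration Number of perturbed instants.
#' @param parameters Affected parameter names (exactly one for a fault).
#' @param magnitude Positive perturbation fraction, e.g. 0.50.
#' @param direction +1/-1 per affected parameter; a scalar is recycled, a
#'   named vector is matched by parameter.
#' @return An \linkS4class{EventSpec}.
#' @examples
#' eventSpec("sensor_fault", start = 40, duration = 5,
#'           parameters = "HR", magnitude = 0.5, direction = +1)
#' @export
eventSpec <- function(kind, start, duration, parameters, magnitude,
                      direction = 1) {
  if (is.null(names(direction))) {
    direction <- rep_len(direction, length(parameters))
    names(direction) <- parameters
  }
  new("EventSpec", kind = kind, start = as.integer(start),
      duration = as.integer(duration), parameters = parameters,
      magnitude = magnitude, direction = direction[parameters])
}

setMethod("show", "EventSpec", function(object) {
  cat(sprintf("EventSpec %s @ [%d, %d] magnitude %.2f on %s\n",
              object@kind, object@start, object@start + object@duration - 1L,
              object@magnitude,
              paste(sprintf("%s%+d", object@parameters,
                            as.integer(object@direction)), collapse = ", ")))
})

eventWindow <- function(event) seq(event@start, length.out = event@duration)

# ---------------------------------------------------------------------------
# LabeledSeries
# ---------------------------------------------------------------------------

#' LabeledSeries: a VitalSeries with per-instant ground truth
#'
#' Extends \linkS4class{VitalSeries} with a label per instant
#' (\code{"normal"}, \code{"medical_event"} or \code{"sensor_fault"}) and the
#' list of injected \linkS4class{EventSpec}s. Every non-normal instant is
#' covered by exactly one event.
#'
#' @slot labels Character vector, one label per instant.
#' @slot events List of \linkS4class{EventSpec} objects.
#'
#' @seealso [LabeledSeries()], [injectEvent()], [makeBenchmark()]
#' @name LabeledSeries-class
#' @export
setClass("LabeledSeries",
  contains = "VitalSeries",
  representation(labels = "character", events = "list")
)

setValidity("LabeledSeries", function(object) {
  msgs <- character(0)
  if (length(object@labels) != nrow(object@values))
    msgs <- c(msgs, "labels length must equal series length")
  if (!all(object@labels %in% VALID_LABELS))
    msgs <- c(msgs, sprintf("labels must be one of %s",
                            paste(VALID_LABELS, collapse = ", ")))
  if (!all(vapply(object@events, is, logical(1), "EventSpec")))
    msgs <- c(msgs, "events must be a list of EventSpec objects")
  covered <- integer(nrow(object@values))
  for (ev in object@events) {
    w <- eventWindow(ev)
    if (any(w < 1L) || any(w > nrow(object@values))) {
      msgs <- c(msgs, "an event window lies outside the series")
    } else {
      covered[w] <- covered[w] + 1L
    }
  }
  if (any(covered > 1L)) msgs <- c(msgs, "event windows must not overlap")
  if (length(msgs) == 0L) {
    bad <- (covered == 0L & object@labels != "normal") |
           (covered == 1L & object@labels == "normal")
    if (any(bad))
      msgs <- c(msgs, "every non-normal instant must be covered by exactly one event")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledSeries
#'
#' @param series A \linkS4class{VitalSeries}.
#' @param labels Optional per-instant labels; defaults to all \code{"normal"}.
#' @param events Optional list of \linkS4class{EventSpec}s consistent with the
#'   labels.
#' @return A \linkS4class{LabeledSeries}.
#' @export
LabeledSeries <- function(series, labels = NULL, events = list()) {
  if (is.null(labels)) labels <- rep("normal", length(series))
  new("LabeledSeries", values = series@values, times = series@times,
      units = series@units, labels = labels, events = events)
}

#' @rdname seriesLabels
#' @export
setMethod("seriesLabels", "LabeledSeries", function(x) x@labels)

#' @rdname seriesEvents
#' @export
setMethod("seriesEvents", "LabeledSeries", function(x) x@events)

setMethod("show", "LabeledSeries", function(object) {
  callNextMethod()
  tab <- table(factor(object@labels, levels = VALID_LABELS))
  cat(sprintf("  labels: %s; %d events\n",
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", "),
              length(object@events)))
})

# ---------------------------------------------------------------------------
# GeneratorConfig
# ---------------------------------------------------------------------------

#' GeneratorConfig: synthetic vital-sign generator settings
#'
#' The generator emulates numerics-rate monitor data: each parameter is its
#' baseline mean plus a slowly wandering drift plus small autocorrelated
#' sensor noise,
#' \deqn{x_{t,p} = \mu_p + s_p D_{t,p} + n_{t,p},}
#' where the drift \eqn{D_{t,p} = \rho Z_t + \sqrt{1-\rho^2} U_{t,p}} blends a
#' latent drift \eqn{Z} shared by all parameters (source of cross-parameter
#' correlation \eqn{\rho}) with a parameter-own drift \eqn{U_p}. Each drift is
#' a unit-variance smooth process (AR(1) level with persistent AR(1) velocity
#' innovations), and \eqn{n_{t,p}} is mean-reverting AR(1) observation noise.
#' SpO2 is clipped to \[0, 100\] and all vitals to >= 0.
#'
#' @slot nSamples Number of instants to generate.
#' @slot seed Integer RNG seed; generation is fully deterministic given the
#'   config.
#' @slot samplePeriod Nominal seconds between samples (metadata only; all
#'   windows are in samples).
#' @slot baselineMeans Named numeric, baseline mean per parameter (native
#'   units).
#' @slot driftSds Named numeric, stationary SD of the slow drift per parameter
#'   (native units).
#' @slot arCoefficient AR(1) coefficient of the observation noise, in \[0, 1).
#' @slot noiseSds Named numeric, stationary SD of the observation noise per
#'   parameter (native units).
#' @slot crossCorrelation Drift blending weight \eqn{\rho} in \[-1, 1\].
#' @slot driftVelocityPhi AR(1) coefficient of the drift velocity (smoothness
#'   of trends).
#' @slot driftDecay Mean-reversion coefficient of the drift level (keeps
#'   excursions bounded).
#'
#' @seealso [generatorConfig()], [generateVitals()]
#' @name GeneratorConfig-class
#' @export
setClass("GeneratorConfig",
  representation(
    nSamples         = "integer",
    seed             = "integer",
    samplePeriod     = "numeric",
    baselineMeans    = "numeric",
    driftSds         = "numeric",
    arCoefficient    = "numeric",
    noiseSds         = "numeric",
    crossCorrelation = "numeric",
    driftVelocityPhi = "numeric",
    driftDecay       = "numeric"
  )
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character(0)
  if (object@nSamples < 1L) msgs <- c(msgs, "nSamples must be > 0")
  p <- names(object@baselineMeans)
  if (is.null(p) || anyDuplicated(p))
    msgs <- c(msgs, "baselineMeans must be uniquely named by parameter")
  for (s in c("driftSds", "noiseSds")) {
    v <- slot(object, s)
    if (!identical(sort(names(v)), sort(p)))
      msgs <- c(msgs, sprintf("'%s' must be named by the same parameters", s))
    if (any(!is.finite(v)) || any(v < 0))
      msgs <- c(msgs, sprintf("'%s' must be finite and >= 0", s))
  }
  if (any(!is.finite(object@baselineMeans)))
    msgs <- c(msgs, "baseline means must be finite")
  if (object@arCoefficient < 0 || object@arCoefficient >= 1)
    msgs <- c(msgs, "arCoefficient must be in [0, 1)")
  if (abs(object@crossCorrelation) > 1)
    msgs <- c(msgs, "crossCorrelation must be in [-1, 1]")
  if (object@driftVelocityPhi < 0 || object@driftVelocityPhi >= 1)
    msgs <- c(msgs, "driftVelocityPhi must be in [0, 1)")
  if (object@driftDecay < 0 || object@driftDecay >= 1)
    msgs <- c(msgs, "driftDecay must be in [0, 1)")
  # default normal adult ranges when the canonical parameters are present
  rng <- list(HR = c(60, 100), Respiration = c(12, 20), SpO2 = c(95, 100))
  for (nm in intersect(names(rng), p)) {
    m <- object@baselineMeans[[nm]]
    if (m < rng[[nm]][1] || m > rng[[nm]][2])
      msgs <- c(msgs, sprintf("%s baseline mean %.1f outside normal range [%g, %g]",
                              nm, m, rng[[nm]][1], rng[[nm]][2]))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig: %d samples, seed %d, %d parameters\n",
              object@nSamples, object@seed, length(object@baselineMeans)))
  cat(sprintf("  drift: rho=%.2f phi_v=%.2f decay=%.3f; noise AR %.2f\n",
              object@crossCorrelation, object@driftVelocityPhi,
              object@driftDecay, object@arCoefficient))
})

# ---------------------------------------------------------------------------
# SVRConfig / SVRModel
# ---------------------------------------------------------------------------

#' SVRConfig: epsilon-insensitive SVR forecasting settings
#'
#' Configures the one-step-ahead per-parameter forecaster: an epsilon-SVR
#' \eqn{f(x) = \langle w, x\rangle + b} minimizing
#' \eqn{\tfrac12\|w\|^2 + C\sum_i(\xi_i + \xi_i^*)} subject to residuals
#' within the \eqn{\varepsilon} tube.
#'
#' @slot cost Positive regularization constant C.
#' @slot epsilon Epsilon tube half-width in native units of the target, or
#'   \code{NA} (default) to use \code{epsilonFraction * sd(window targets)}
#'   so the tube is meaningful across parameters with different units.
#' @slot epsilonFraction Fraction of the window SD used when \code{epsilon}
#'   is \code{NA}.
#' @slot kernel \code{"linear"} (default) or \code{"rbf"}.
#' @slot featureMode \code{"lags"} (default): regress each value on its
#'   \code{lagOrder} predecessors; \code{"time_index"}: regress on the
#'   window-local index rescaled to \[0, 1\].
#' @slot lagOrder Number of lagged regressors in \code{"lags"} mode.
#' @slot windowSize Sliding training window length in samples (default 30).
#'
#' @seealso [svrConfig()], [fitWindow()], [rollingPredict()]
#' @name SVRConfig-class
#' @export
setClass("SVRConfig",
  representation(
    cost            = "numeric",
    epsilon         = "numeric",
    epsilonFraction = "numeric",
    kernel          = "character",
    featureMode     = "character",
    lagOrder        = "integer",
    windowSize      = "integer"
  )
)

setValidity("SVRConfig", function(object) {
  msgs <- character(0)
  if (!is.finite(object@cost) || object@cost <= 0)
    msgs <- c(msgs, "cost (C) must be > 0")
  if (!is.na(object@epsilon) && object@epsilon < 0)
    msgs <- c(msgs, "epsilon must be >= 0")
  if (!is.finite(object@epsilonFraction) || object@epsilonFraction < 0)
    msgs <- c(msgs, "epsilonFraction must be >= 0")
  if (!object@kernel %in% c("linear", "rbf"))
    msgs <- c(msgs, "kernel must be 'linear' or 'rbf'")
  if (!object@featureMode %in% c("lags", "time_index"))
    msgs <- c(msgs, "featureMode must be 'lags' or 'time_index'")
  if (object@lagOrder < 1L) msgs <- c(msgs, "lagOrder must be >= 1")
  if (object@windowSize < 2L) msgs <- c(msgs, "windowSize must be >= 2")
  if (object@windowSize < object@lagOrder + 1L)
    msgs <- c(msgs, "windowSize must be >= lagOrder + 1")
  if (length(msgs)) msgs else TRUE
})

#' SVRModel: a fitted one-step window forecaster
#'
#' Returned by [fitWindow()]. For the linear kernel the prediction is affine
#' in the features; degenerate (constant-target) windows are represented by a
#' constant model predicting that value.
#'
#' @slot fit The underlying solver fit (\code{e1071::svm} object), or
#'   \code{NULL} for a constant model.
#' @slot constantValue Prediction of a constant model (\code{NA} otherwise).
#' @slot config The \linkS4class{SVRConfig} used.
#' @slot lastValues The trailing window values needed to build the next
#'   feature vector (lags mode).
#' @slot nextIndex The only sample index this model may forecast (the index
#'   immediately after the fitted window).
#' @slot epsilonUsed Resolved epsilon tube half-width (native units).
#'
#' @name SVRModel-class
#' @export
setClass("SVRModel",
  representation(
    fit           = "ANY",
    constantValue = "numeric",
    config        = "SVRConfig",
    lastValues    = "numeric",
    nextIndex     = "numeric",
    epsilonUsed   = "numeric"
  )
)

setMethod("show", "SVRModel", function(object) {
  kindtxt <- if (is.null(object@fit)) "constant" else
    sprintf("%s-kernel %s-feature eps-SVR", object@config@kernel,
            object@config@featureMode)
  cat(sprintf("SVRModel (%s), forecasts index %g, epsilon %.4g\n",
              kindtxt, object@nextIndex, object@epsilonUsed))
})

# ---------------------------------------------------------------------------
# ThresholdState
# ---------------------------------------------------------------------------

#' ThresholdState: per-parameter sliding buffer and dynamic threshold
#'
#' The dynamic threshold for a parameter is \eqn{T_d = k \cdot S_d}, where
#' \eqn{S_d} is the sample standard deviation of the last \code{capacity}
#' accepted readings. Updating the buffer each step keeps the threshold
#' tracking the patient's current variability; a fixed threshold
#' \eqn{T_f} is the never-updated special case.
#'
#' @slot parameter Parameter name.
#' @slot buffer Numeric vector of the most recent accepted values (FIFO,
#'   oldest first), length <= capacity.
#' @slot capacity Window size W (default 30).
#' @slot kMult Positive threshold multiplier k (default 1).
#'
#' @seealso [thresholdState()], [updateThreshold()], [thresholdValue()]
#' @name ThresholdState-class
#' @export
setClass("ThresholdState",
  representation(
    parameter = "character",
    buffer    = "numeric",
    capacity  = "integer",
    kMult     = "numeric"
  )
)

setValidity("ThresholdState", function(object) {
  msgs <- character(0)
  if (object@capacity < 2L) msgs <- c(msgs, "capacity must be >= 2")
  if (length(object@buffer) > object@capacity)
    msgs <- c(msgs, "buffer cannot exceed capacity")
  if (anyNA(object@buffer) || any(!is.finite(object@buffer)))
    msgs <- c(msgs, "buffer values must be finite")
  if (!is.finite(object@kMult) || object@kMult <= 0)
    msgs <- c(msgs, "kMult must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ThresholdState
#'
#' @param parameter Parameter name.
#' @param buffer Initial accepted values (most recent last); trimmed to the
#'   trailing \code{capacity} values if longer.
#' @param capacity Sliding window size W (default 30).
#' @param kMult Threshold multiplier k (default 1), so \eqn{T_d = k S_d}.
#' @return A \linkS4class{ThresholdState}.
#' @examples
#' st <- thresholdState("HR", buffer = c(2, 4, 4, 4, 5, 5, 7, 9), capacity = 8)
#' thresholdValue(st)
#' @export
thresholdState <- function(parameter, buffer = numeric(0), capacity = 30L,
                           kMult = 1) {
  capacity <- as.integer(capacity)
  if (length(buffer) > capacity)
    buffer <- buffer[(length(buffer) - capacity + 1L):length(buffer)]
  new("ThresholdState", parameter = parameter, buffer = as.numeric(buffer),
      capacity = capacity, kMult = kMult)
}

setMethod("show", "ThresholdState", function(object) {
  cat(sprintf("ThresholdState '%s': %d/%d values, S_d=%.4g, T_d=%.4g (k=%g)\n",
              object@parameter, length(object@buffer), object@capacity,
              thresholdSd(object), thresholdValue(object), object@kMult))
})

# ---------------------------------------------------------------------------
# PipelineConfig
# ---------------------------------------------------------------------------

#' PipelineConfig: end-to-end detection settings
#'
#' @slot thresholdWindow Sliding window W_t for the dynamic threshold
#'   (default 30 samples).
#' @slot predictionWindow Sliding window W_p for the forecaster (default 30
#'   samples).
#' @slot detectionWindow Reporting/evaluation batch size (default 80 samples);
#'   it does not affect per-instant decisions.
#' @slot kMult Threshold multiplier (default 1).
#' @slot svr The \linkS4class{SVRConfig} used per parameter.
#' @slot updatePolicy \code{"accept_all"} (default): windows always advance
#'   on the sensed value and the forecast is used for anomaly detection only;
#'   \code{"accept_normal_only"}: a flagged parameter's windows receive the
#'   predicted value instead of the suspect reading, shielding the model from
#'   faults at the risk of detaching it from a drifting patient.
#' @slot thresholdMode \code{"dynamic"} (default): threshold recomputed from
#'   the sliding buffer each step; \code{"fixed"}: frozen at the SD of the
#'   initial window.
#'
#' @seealso [pipelineConfig()], [runPipeline()]
#' @name PipelineConfig-class
#' @export
setClass("PipelineConfig",
  representation(
    thresholdWindow  = "integer",
    predictionWindow = "integer",
    detectionWindow  = "integer",
    kMult            = "numeric",
    svr              = "SVRConfig",
    updatePolicy     = "character",
    thresholdMode    = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msgs <- character(0)
  for (s in c("thresholdWindow", "predictionWindow", "detectionWindow"))
    if (slot(object, s) < 2L) msgs <- c(msgs, sprintf("%s must be >= 2", s))
  if (!is.finite(object@kMult) || object@kMult <= 0)
    msgs <- c(msgs, "kMult must be > 0")
  if (!object@updatePolicy %in% c("accept_normal_only", "accept_all"))
    msgs <- c(msgs, "updatePolicy must be 'accept_normal_only' or 'accept_all'")
  if (!object@thresholdMode %in% c("dynamic", "fixed"))
    msgs <- c(msgs, "thresholdMode must be 'dynamic' or 'fixed'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(paste0("PipelineConfig: W_t=%d W_p=%d W_detect=%d k=%g, ",
                     "policy=%s, threshold=%s\n"),
              object@thresholdWindow, object@predictionWindow,
              object@detectionWindow, object@kMult, object@updatePolicy,
              object@thresholdMode))
})

# ---------------------------------------------------------------------------
# ConfusionCounts
# ---------------------------------------------------------------------------

#' ConfusionCounts: binary alarm-triage outcomes
#'
#' Positive class = true alarm (true medical condition); negative class =
#' false alarm (sensor fault). TP: medical condition declared a true alarm;
#' FN: medical condition missed; FP: sensor fault wrongly declared a true
#' alarm; TN: sensor fault correctly left a false alarm.
#'
#' @slot TP,FP,TN,FN Non-negative integer counts.
#'
#' @seealso [confusionCounts()], [scoreDecisions()], [detectionRate()],
#'   [falsePositiveRate()]
#' @name ConfusionCounts-class
#' @export
setClass("ConfusionCounts",
  representation(TP = "integer", FP = "integer", TN = "integer", FN = "integer")
)

setValidity("ConfusionCounts", function(object) {
  v <- c(object@TP, object@FP, object@TN, object@FN)
  if (any(is.na(v)) || any(v < 0L)) "all counts must be non-negative integers"
  else TRUE
})

#' Construct ConfusionCounts
#'
#' @param TP,FP,TN,FN Non-negative counts.
#' @return A \linkS4class{ConfusionCounts}.
#' @examples
#' falsePositiveRate(confusionCounts(FP = 3, TN = 56))  # 3/59 = 0.0508
#' @export
confusionCounts <- function(TP = 0L, FP = 0L, TN = 0L, FN = 0L) {
  new("ConfusionCounts", TP = as.integer(TP), FP = as.integer(FP),
      TN = as.integer(TN), FN = as.integer(FN))
}

setMethod("show", "ConfusionCounts", function(object) {
  dr <- suppressWarnings(detectionRate(object))
  fpr <- suppressWarnings(falsePositiveRate(object))
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (DR=%s, FPR=%s)\n",
              object@TP, object@FP, object@TN, object@FN,
              ifelse(is.na(dr), "undefined", sprintf("%.4f", dr)),
              ifelse(is.na(fpr), "undefined", sprintf("%.4f", fpr))))
})
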