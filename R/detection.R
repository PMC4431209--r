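# Core pipeline: per-parameter sliding windows, dynamic standard-deviation
# threshold, predicted-vs-sensed error flags, and majority voting over the
# parameters to emit per-instant alarm decisions.

#' @rdname updateThreshold
#' @export
setMethod("updateThreshold", "ThresholdState", function(state, value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    warning("non-finite value rejected; threshold state unchanged")
    return(state)
  }
  buf <- c(state@buffer, as.numeric(value))
  if (length(buf) > state@capacity)
    buf <- buf[(length(buf) - state@capacity + 1L):length(buf)]
  initialize(state, buffer = buf)
})

#' @rdname thresholdSd
#' @export
setMethod("thresholdSd", "ThresholdState", function(state) sampleSd(state@buffer))

#' @rdname thresholdValue
#' @export
setMethod("thresholdValue", "ThresholdState",
          function(state) state@kMult * sampleSd(state@buffer))

#' Residual and percentage error between sensed and predicted values
#'
#' @param actual Sensed value \eqn{S_a(t)}, finite.
#' @param predicted Predicted value \eqn{S_p(t)}, finite.
#' @return List with \code{residual} = \eqn{|S_a - S_p|} (native units) and
#'   \code{percentError} = \eqn{100|S_a - S_p|/|S_a|}, or \code{NA} when
#'   \eqn{S_a = 0} (undefined, reported as missing rather than silently 0).
#' @examples
#' computeError(100, 90)  # residual 10, percentError 10
#' @export
computeError <- function(actual, predicted) {
  if (!is.finite(actual) || !is.finite(predicted))
    stopf("computeError requires finite actual and predicted values")
  residual <- abs(actual - predicted)
  list(residual = residual,
       percentError = if (actual == 0) NA_real_ else 100 * residual / abs(actual))
}

#' Flag a parameter whose forecast error exceeds its dynamic threshold
#'
#' The vote \eqn{v(i)} is 1 exactly when the native-unit residual strictly
#' exceeds the current threshold \eqn{T_d = k S_d}; ties are not flagged, and
#' a zero threshold (zero-variance window) flags any nonzero residual.
#'
#' @param err Result of [computeError()] (or a bare numeric residual).
#' @param state The parameter's current \linkS4class{ThresholdState}.
#' @return Logical flag.
#' @export
flagParameter <- function(err, state) {
  residual <- if (is.list(err)) err$residual else as.numeric(err)
  residual > thresholdValue(state)
}

#' Majority vote across per-parameter anomaly flags
#'
#' With Y flagged parameters out of n voting: Y = 0 is \code{"normal"};
#' Y > n/2 (a strict majority, i.e. a correlated change across most
#' parameters) is \code{"true_alarm"}; any minority of flags, including an
#' exact even-n tie, is \code{"false_alarm"} (sensor anomaly) — a split vote
#' is conservatively not treated as a medical emergency.
#'
#' @param flags Logical/0-1 vector of per-parameter votes.
#' @param n Number of parameters voting (default \code{length(flags)}).
#' @return One of \code{"normal"}, \code{"true_alarm"}, \code{"false_alarm"}.
#' @examples
#' majorityVote(c(1, 1, 1, 0, 0))  # "true_alarm": 3 > 5/2
#' majorityVote(c(1, 1, 0, 0))     # "false_alarm": 2 is not > 2
#' @export
majorityVote <- function(flags, n = length(flags)) {
  if (length(flags) == 0L) stopf("empty flag vector")
  if (length(flags) != n)
    stopf("flags length %d does not match n = %d", length(flags), n)
  if (anyNA(flags)) stopf("flags must not contain NA (abstainers are dropped before voting)")
  Y <- sum(flags != 0)
  if (Y == 0L) "normal"
  else if (Y > n / 2) "true_alarm"
  else "false_alarm"
}

#' Construct a PipelineConfig
#'
#' @param thresholdWindow Dynamic-threshold sliding window W_t in samples
#'   (default 30).
#' @param predictionWindow Forecaster sliding window W_p in samples
#'   (default 30).
#' @param detectionWindow Reporting batch size in samples (default 80).
#' @param kMult Threshold multiplier k, so \eqn{T_d = k S_d} (default 1).
#' @param svr An \linkS4class{SVRConfig}; its window size is forced to
#'   \code{predictionWindow}.
#' @param updatePolicy \code{"accept_all"} (default): sliding windows always
#'   receive the sensed value, so the predicted value is used for anomaly
#'   detection only; \code{"accept_normal_only"}: a flagged parameter's
#'   windows receive the predicted value instead of the suspect reading.
#'   See \linkS4class{PipelineConfig} for the trade-off.
#' @param thresholdMode \code{"dynamic"} (default) or \code{"fixed"}.
#' @return A validated \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(thresholdWindow = 30L, predictionWindow = 30L,
                           detectionWindow = 80L, kMult = 1,
                           svr = svrConfig(),
                           updatePolicy = c("accept_all", "accept_normal_only"),
                           thresholdMode = c("dynamic", "fixed")) {
  svr@windowSize <- as.integer(predictionWindow)
  validObject(svr)
  new("PipelineConfig",
      thresholdWindow = as.integer(thresholdWindow),
      predictionWindow = as.integer(predictionWindow),
      detectionWindow = as.integer(detectionWindow),
      kMult = as.numeric(kMult), svr = svr,
      updatePolicy = match.arg(updatePolicy),
      thresholdMode = match.arg(thresholdMode))
}

#' Run the full alarm-triage pipeline over a series
#'
#' For every instant t after the warm-up (the first \code{max(W_p, W_t)}
#' samples): each parameter is forecast one step ahead from its sliding
#' window of accepted values, the native-unit residual against the sensed
#' value is compared with the parameter's dynamic threshold
#' \eqn{T_d = k S_d}, and the per-parameter flags are majority-voted into a
#' verdict. Parameters without a usable forecast (missing reading, or a
#' window not yet full of accepted values) abstain; the vote is over the
#' non-abstaining parameters. Under the default
#' \code{"accept_all"} policy the windows always advance on the sensed
#' values and the forecast is used for comparison only; the alternative
#' \code{"accept_normal_only"} policy substitutes the forecast for flagged
#' readings, which shields the model from faults but can detach it from a
#' drifting patient after a spurious flag.
#'
#' @param series A \linkS4class{VitalSeries} (a \linkS4class{LabeledSeries}
#'   is accepted; labels are ignored here).
#' @param config A \linkS4class{PipelineConfig}.
#' @return A data.frame of alarm decisions with columns \code{t} (1-based
#'   instant), \code{verdict}, \code{voteCount} (Y), \code{nVoting} (n), and
#'   per-parameter \code{<p>_flag}, \code{<p>_residual},
#'   \code{<p>_threshold}, \code{<p>_predicted} (NA where the parameter
#'   abstained). Instants where every parameter abstained are skipped and
#'   listed in the \code{"skipped"} attribute. Deterministic given
#'   (series, config).
#' @seealso [scoreDecisions()], [runEndToEnd()]
#' @export
runPipeline <- function(series, config = pipelineConfig()) {
  stopifnot(is(series, "VitalSeries"), is(config, "PipelineConfig"))
  validObject(config)
  x <- vitalValues(series)
  params <- colnames(x)
  N <- nrow(x)
  Wp <- config@predictionWindow
  Wt <- config@thresholdWindow
  warmup <- max(Wp, Wt)
  if (N <= warmup)
    stopf("series length %d must exceed the warm-up %d", N, warmup)

  predBuf <- thrBuf <- vector("list", length(params))
  names(predBuf) <- names(thrBuf) <- params
  fixedT <- numeric(length(params))
  names(fixedT) <- params
  for (p in params) {
    acc <- x[seq_len(warmup), p]
    acc <- acc[is.finite(acc)]
    predBuf[[p]] <- if (length(acc) > Wp) acc[(length(acc) - Wp + 1L):length(acc)] else acc
    thrBuf[[p]] <- if (length(acc) > Wt) acc[(length(acc) - Wt + 1L):length(acc)] else acc
    fixedT[p] <- config@kMult * sampleSd(thrBuf[[p]])
  }

  nOut <- N - warmup
  verdict <- character(nOut)
  voteCount <- nVoting <- integer(nOut)
  flagM <- resM <- thrM <- predM <- matrix(NA_real_, nrow = nOut,
                                           ncol = length(params),
                                           dimnames = list(NULL, params))
  keep <- logical(nOut)
  skipped <- integer(0)

  for (t in (warmup + 1L):N) {
    i <- t - warmup
    flags <- logical(0)
    for (p in params) {
      actual <- x[t, p]
      win <- predBuf[[p]]
      usable <- is.finite(actual) && length(win) == Wp
      if (usable) {
        model <- fitWindow(win, config@svr, startIndex = t - Wp)
        pred <- predictNext(model, t)
        err <- computeError(actual, pred)
        thr <- if (identical(config@thresholdMode, "fixed")) fixedT[p]
               else config@kMult * sampleSd(thrBuf[[p]])
        fl <- err$residual > thr
        flags <- c(flags, fl)
        flagM[i, p] <- as.numeric(fl)
        resM[i, p] <- err$residual
        thrM[i, p] <- thr
        predM[i, p] <- pred
        push <- if (identical(config@updatePolicy, "accept_all") || !fl)
          actual else pred
        predBuf[[p]] <- c(win[-1L], push)
        thrBuf[[p]] <- c(thrBuf[[p]], push)
        if (length(thrBuf[[p]]) > Wt)
          thrBuf[[p]] <- thrBuf[[p]][(length(thrBuf[[p]]) - Wt + 1L):length(thrBuf[[p]])]
      } else if (is.finite(actual)) {
        # no forecast possible yet: the reading is accepted unflagged
        predBuf[[p]] <- c(predBuf[[p]], actual)
        if (length(predBuf[[p]]) > Wp)
          predBuf[[p]] <- predBuf[[p]][(length(predBuf[[p]]) - Wp + 1L):length(predBuf[[p]])]
        thrBuf[[p]] <- c(thrBuf[[p]], actual)
        if (length(thrBuf[[p]]) > Wt)
          thrBuf[[p]] <- thrBuf[[p]][(length(thrBuf[[p]]) - Wt + 1L):length(thrBuf[[p]])]
      }
    }
    if (length(flags) == 0L) {
      skipped <- c(skipped, t)
      next
    }
    keep[i] <- TRUE
    verdict[i] <- majorityVote(flags)
    voteCount[i] <- sum(flags)
    nVoting[i] <- length(flags)
  }

  out <- data.frame(t = (warmup + 1L):N, verdict = verdict,
                    voteCount = voteCount, nVoting = nVoting)[keep, ]
  for (p in params) {
    out[[paste0(p, "_flag")]] <- flagM[keep, p]
    out[[paste0(p, "_residual")]] <- resM[keep, p]
    out[[paste0(p, "_threshold")]] <- thrM[keep, p]
    out[[paste0(p, "_predicted")]] <- predM[keep, p]
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "warmup") <- warmup
  out
}
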