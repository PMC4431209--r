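# One-step-ahead per-parameter forecasting from a sliding window, by
# epsilon-insensitive support-vector regression, plus the comparison harness
# against linear-regression and Gaussian-process baselines.

#' Construct an SVRConfig
#'
#' @param cost Regularization constant C > 0 (default 1).
#' @param epsilon Fixed epsilon tube half-width in native units, or \code{NA}
#'   (default) for scale-adaptive \code{epsilonFraction * sd(window targets)}.
#' @param epsilonFraction Fraction of the window SD for the adaptive tube
#'   (default 0.1).
#' @param kernel \code{"linear"} (default) or \code{"rbf"}.
#' @param featureMode \code{"lags"} (default) or \code{"time_index"}. Lagged
#'   values track autocorrelated vitals at near the innovation floor;
#'   time-index regression extrapolates the within-window trend and is kept
#'   for comparison studies.
#' @param lagOrder Number of lagged regressors (default 3).
#' @param windowSize Training window length in samples (default 30).
#' @return A validated \linkS4class{SVRConfig}.
#' @examples
#' svrConfig(cost = 10, featureMode = "time_index")
#' @export
svrConfig <- function(cost = 1, epsilon = NA_real_, epsilonFraction = 0.1,
                      kernel = c("linear", "rbf"),
                      featureMode = c("lags", "time_index"),
                      lagOrder = 3L, windowSize = 30L) {
  new("SVRConfig", cost = as.numeric(cost), epsilon = as.numeric(epsilon),
      epsilonFraction = as.numeric(epsilonFraction), kernel = match.arg(kernel),
      featureMode = match.arg(featureMode), lagOrder = as.integer(lagOrder),
      windowSize = as.integer(windowSize))
}

# Training design for a window of values under a feature mode.
# time_index: single regressor, the window-local index rescaled to [0, 1];
# lags: the lagOrder previous values. Returns X (matrix), y, and the feature
# row for the one-step-ahead forecast.
windowDesign <- function(values, config) {
  W <- length(values)
  if (identical(config@featureMode, "time_index")) {
    x <- (seq_len(W) - 1) / (W - 1)
    keep <- is.finite(values)
    list(X = matrix(x[keep], ncol = 1L), y = values[keep],
         xNext = matrix(W / (W - 1), ncol = 1L))
  } else {
    if (anyNA(values))
      stopf("lags features require a complete window (missing values present)")
    k <- config@lagOrder
    emb <- stats::embed(values, k + 1L)
    list(X = emb[, -1L, drop = FALSE], y = emb[, 1L],
         xNext = matrix(values[W:(W - k + 1L)], nrow = 1L))
  }
}

#' Fit an epsilon-SVR forecaster on one sliding window
#'
#' Solves the epsilon-insensitive SVR problem
#' \deqn{\min \tfrac12\|w\|^2 + C\sum_i(\xi_i+\xi_i^*)}
#' subject to all training targets lying within \eqn{\varepsilon} of
#' \eqn{f(x_i)=\langle w,x_i\rangle+b} up to the slacks, via the libsvm SMO
#' solver (\code{e1071::svm}, \code{eps-regression}, unscaled so that
#' \eqn{\varepsilon} is in native units). A window whose usable targets are
#' all identical yields a constant model predicting that value (the constant
#' lies inside any positive tube).
#'
#' @param values Ordered window values (native units). \code{NA}s are
#'   excluded before fitting in \code{"time_index"} mode and are an error in
#'   \code{"lags"} mode.
#' @param config An \linkS4class{SVRConfig}.
#' @param startIndex Sample index of \code{values[1]} in the parent series
#'   (default 1); the model may only forecast
#'   \code{startIndex + length(values)}.
#' @return An \linkS4class{SVRModel}.
#' @seealso [predictNext()], [rollingPredict()]
#' @examples
#' m <- fitWindow(rep(70, 30), svrConfig())
#' predictNext(m, 31)
#' @export
fitWindow <- function(values, config = svrConfig(), startIndex = 1L) {
  stopifnot(is(config, "SVRConfig"))
  validObject(config)
  values <- as.numeric(values)
  usable <- sum(is.finite(values))
  if (usable < 2L)
    stopf("cannot fit: only %d usable point(s) in the window", usable)
  nextIndex <- startIndex + length(values)
  # center the window at its mean before solving: translation-equivariant for
  # the linear kernel and distance-preserving for the rbf kernel, so the
  # solution is unchanged, but the solver sees well-conditioned values
  # instead of raw vitals at magnitude ~100 with a tiny epsilon tube
  center <- mean(values[is.finite(values)])
  d <- windowDesign(values - center, config)
  eps <- if (is.na(config@epsilon)) config@epsilonFraction * sampleSd(d$y)
         else config@epsilon
  if (diff(range(d$y)) == 0) {
    return(new("SVRModel", fit = NULL, constantValue = d$y[1L] + center,
               config = config, lastValues = values,
               nextIndex = as.numeric(nextIndex), epsilonUsed = eps))
  }
  fit <- e1071::svm(x = d$X, y = d$y, type = "eps-regression",
                    kernel = if (identical(config@kernel, "rbf")) "radial"
                             else "linear",
                    cost = config@cost, epsilon = eps, scale = FALSE,
                    fitted = FALSE)
  if (fit$tot.nSV == 0L) {
    # every target already lies inside the tube at w = 0: the objective is
    # minimized by any b in [max(y) - eps, min(y) + eps]; take the midpoint
    return(new("SVRModel", fit = NULL,
               constantValue = (max(d$y) + min(d$y)) / 2 + center,
               config = config, lastValues = values,
               nextIndex = as.numeric(nextIndex), epsilonUsed = eps))
  }
  new("SVRModel", fit = fit, constantValue = NA_real_, config = config,
      lastValues = values, nextIndex = as.numeric(nextIndex),
      epsilonUsed = eps)
}

#' @rdname predictNext
#' @export
setMethod("predictNext", "SVRModel", function(model, t) {
  if (!missing(t) && !isTRUE(all.equal(as.numeric(t), model@nextIndex)))
    stopf("contract violation: model forecasts index %g, not %g (the pipeline only ever predicts one step ahead)",
          model@nextIndex, as.numeric(t))
  if (is.null(model@fit)) return(model@constantValue)
  center <- mean(model@lastValues[is.finite(model@lastValues)])
  d <- windowDesign(model@lastValues - center, model@config)
  out <- as.numeric(stats::predict(model@fit, d$xNext)) + center
  if (!is.finite(out)) stopf("non-finite prediction")
  out
})

#' Rolling one-step-ahead predictions over a series
#'
#' For each instant t after the first full window, fits on samples
#' \code{[t - windowSize, t - 1]} and forecasts t. Windows containing missing
#' values are skipped, never imputed (imputation would mask the very sensor
#' faults the pipeline is meant to expose); skipped instants are recorded in
#' the \code{"gaps"} attribute of the result.
#'
#' @param series A \linkS4class{VitalSeries}.
#' @param parameter Parameter name to forecast.
#' @param config An \linkS4class{SVRConfig}.
#' @return A data.frame with columns \code{parameter}, \code{t},
#'   \code{predicted}, \code{actual} (actual may be \code{NA});
#'   attribute \code{"gaps"} holds the skipped instants.
#' @export
rollingPredict <- function(series, parameter, config = svrConfig()) {
  stopifnot(is(series, "VitalSeries"))
  if (!parameter %in% parameterNames(series))
    stopf("parameter '%s' not in series (%s)", parameter,
          paste(parameterNames(series), collapse = ", "))
  x <- vitalValues(series)[, parameter]
  W <- config@windowSize
  if (length(x) <= W)
    stopf("series length %d must exceed the window size %d", length(x), W)
  recs <- vector("list", length(x) - W)
  gaps <- integer(0)
  for (t in (W + 1L):length(x)) {
    win <- x[(t - W):(t - 1L)]
    if (anyNA(win)) {
      gaps <- c(gaps, t)
      next
    }
    model <- fitWindow(win, config, startIndex = t - W)
    recs[[t - W]] <- data.frame(parameter = parameter, t = t,
                                predicted = predictNext(model, t),
                                actual = x[t])
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(parameter = character(0), t = integer(0),
                      predicted = numeric(0), actual = numeric(0))
  attr(out, "gaps") <- gaps
  out
}

# One-step forecast of a window by each comparison method, with the shared
# constant-window guard. Windows are centered at their mean (a no-op for the
# affine methods; it matches the Gaussian process's zero-mean prior).
forecastWindow <- function(values, method, config) {
  center <- mean(values[is.finite(values)])
  d <- windowDesign(values - center, config)
  if (diff(range(d$y)) == 0) return(d$y[1L] + center)
  switch(method,
    svr = {
      m <- fitWindow(values, config)   # fitWindow centers internally
      predictNext(m, as.numeric(length(values) + 1L))
    },
    linear_regression = {
      df <- data.frame(d$X)
      df$y <- d$y
      fit <- stats::lm(y ~ ., data = df)
      nd <- data.frame(d$xNext)
      names(nd) <- setdiff(names(df), "y")
      as.numeric(stats::predict(fit, nd)) + center
    },
    gaussian_process = {
      # fixed kernel width (median-heuristic-free) keeps the fit deterministic
      sigma <- 1 / max(ncol(d$X) * stats::var(as.vector(d$X)), 1e-8)
      fit <- kernlab::gausspr(x = d$X, y = d$y, kernel = "rbfdot",
                              kpar = list(sigma = sigma), scaled = FALSE)
      as.numeric(kernlab::predict(fit, d$xNext)) + center
    },
    stopf("unknown method '%s'", method))
}

#' Compare forecasting methods on rolling windows
#'
#' Reproduces the protocol shape of the predictor-selection study: for each
#' parameter, roll \code{nPredictions} one-step forecasts with each method
#' over the same windows and report the average percentage error
#' \eqn{\mathrm{mean}(100 |S_a - S_p| / |S_a|)} (instants with \eqn{S_a = 0}
#' excluded from the mean and counted) and the RMSE
#' \eqn{\sqrt{\mathrm{mean}((S_a - S_p)^2)}}.
#'
#' @param series A \linkS4class{VitalSeries}.
#' @param windowSize Sliding window length (default 30).
#' @param nPredictions Number of one-step forecasts per parameter
#'   (default 100).
#' @param methods Subset of \code{"svr"}, \code{"linear_regression"},
#'   \code{"gaussian_process"}.
#' @param config \linkS4class{SVRConfig} shared by all methods (feature
#'   construction and the SVR hyperparameters); its window size is overridden
#'   by \code{windowSize}.
#' @return A data.frame with one row per (method, parameter): columns
#'   \code{method}, \code{parameter}, \code{percentage_error}, \code{rmse},
#'   \code{n_predictions}, \code{n_zero_excluded}. The per-forecast
#'   \code{(t, predicted, actual)} pairs are attached as attribute
#'   \code{"pairs"} for independent recomputation.
#' @export
comparePredictors <- function(series, windowSize = 30L, nPredictions = 100L,
                              methods = c("svr", "linear_regression",
                                          "gaussian_process"),
                              config = svrConfig()) {
  stopifnot(is(series, "VitalSeries"))
  config@windowSize <- as.integer(windowSize)
  validObject(config)
  x <- vitalValues(series)
  if (nrow(x) < windowSize + nPredictions)
    stopf("series length %d too short for %d forecasts at window %d",
          nrow(x), nPredictions, windowSize)
  rows <- list()
  pairs <- list()
  for (p in colnames(x)) {
    usable <- 0L
    wins <- list()
    for (t in (windowSize + 1L):nrow(x)) {
      win <- x[(t - windowSize):(t - 1L), p]
      if (anyNA(win) || is.na(x[t, p])) next
      usable <- usable + 1L
      wins[[usable]] <- list(t = t, win = win, actual = x[t, p])
      if (usable >= nPredictions) break
    }
    if (usable < nPredictions)
      stopf("parameter %s: only %d usable windows (< %d)", p, usable,
            nPredictions)
    for (m in methods) {
      pred <- vapply(wins, function(w) forecastWindow(w$win, m, config),
                     numeric(1))
      act <- vapply(wins, `[[`, numeric(1), "actual")
      nz <- act != 0
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, parameter = p,
        percentage_error = mean(100 * abs(act[nz] - pred[nz]) / abs(act[nz])),
        rmse = sqrt(mean((act - pred)^2)),
        n_predictions = length(act),
        n_zero_excluded = sum(!nz))
      pairs[[length(pairs) + 1L]] <- data.frame(
        method = m, parameter = p,
        t = vapply(wins, `[[`, numeric(1), "t"),
        predicted = pred, actual = act)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pairs") <- do.call(rbind, pairs)
  out
}
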