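# Synthetic vital-sign generator: labeled multivariate streams with
# injectable correlated medical events and uncorrelated sensor faults.

#' Default generator configuration
#'
#' Builds a \linkS4class{GeneratorConfig} for the five canonical parameters
#' with baselines inside normal adult resting ranges (HR 60-100 bpm,
#' Respiration 12-20 breaths/min, SpO2 95-100%) and drift/noise amplitudes
#' chosen for numerics-rate realism: vitals wander smoothly by a few native
#' units over tens of samples while sample-to-sample sensor jitter stays
#' small. Pulse mirrors HR (same physiology read by a second device).
#'
#' @param nSamples Number of instants (default 600).
#' @param seed Integer seed (default 1); generation is deterministic given
#'   the config.
#' @param samplePeriod Nominal seconds per sample (default 60, i.e.
#'   per-minute numerics; metadata only).
#' @param baselineMeans,driftSds,noiseSds Named numeric vectors overriding
#'   the per-parameter defaults.
#' @param arCoefficient AR(1) coefficient of the short-term fluctuation
#'   (default 0.9): minute-scale physiological variation is persistent, and
#'   one-step prediction error then sits near the small innovation SD, as
#'   monitor numerics behave.
#' @param crossCorrelation Shared-drift blending weight in \[-1, 1\]
#'   (default 0.7): 1 = all parameters follow one latent physiological state,
#'   0 = independent drifts.
#' @param driftVelocityPhi Persistence of drift velocity (default 0.9).
#' @param driftDecay Mean reversion of the drift level (default 0.99).
#' @return A validated \linkS4class{GeneratorConfig}.
#' @examples
#' cfg <- generatorConfig(nSamples = 100, seed = 7)
#' series <- generateVitals(cfg)
#' @export
generatorConfig <- function(nSamples = 600L,
                            seed = 1L,
                            samplePeriod = 60,
                            baselineMeans = c(ABPmean = 90, HR = 80,
                                              Pulse = 80, Respiration = 16,
                                              SpO2 = 98),
                            driftSds = c(ABPmean = 5, HR = 4, Pulse = 4,
                                         Respiration = 1.5, SpO2 = 0.8),
                            noiseSds = c(ABPmean = 0.5, HR = 0.35, Pulse = 0.35,
                                         Respiration = 0.2, SpO2 = 0.12),
                            arCoefficient = 0.9,
                            crossCorrelation = 0.7,
                            driftVelocityPhi = 0.9,
                            driftDecay = 0.99) {
  new("GeneratorConfig",
      nSamples = as.integer(nSamples), seed = as.integer(seed),
      samplePeriod = samplePeriod, baselineMeans = baselineMeans,
      driftSds = driftSds[names(baselineMeans)],
      arCoefficient = arCoefficient,
      noiseSds = noiseSds[names(baselineMeans)],
      crossCorrelation = crossCorrelation,
      driftVelocityPhi = driftVelocityPhi, driftDecay = driftDecay)
}

# Stationary variance of the drift level z_k = d z_{k-1} + v_k,
# v_k = phi v_{k-1} + eta_k with unit-variance eta. The level is AR(2):
# z_k = (d+phi) z_{k-1} - d*phi z_{k-2} + eta_k, whose stationary variance is
# (1-a2) / ((1+a2)((1-a2)^2 - a1^2)) with a1 = d+phi, a2 = -d*phi.
driftStationaryVar <- function(phi, d) {
  a1 <- d + phi
  a2 <- -d * phi
  (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
}

# One unit-stationary-SD smooth drift path of length n (consumes 1 rnorm
# stream of length n).
driftPath <- function(n, phi, d) {
  eta <- stats::rnorm(n)
  v <- as.numeric(stats::filter(eta, phi, method = "recursive"))
  z <- as.numeric(stats::filter(v, d, method = "recursive"))
  sc <- driftStationaryVar(phi, d)
  if (sc > 0) z / sqrt(sc) else z
}

#' Generate a synthetic vital-sign stream
#'
#' Each parameter p follows
#' \deqn{x_{t,p} = \mu_p + s_p(\rho Z_t + \sqrt{1-\rho^2} U_{t,p}) + n_{t,p},}
#' with a shared smooth latent drift Z, parameter-own drifts U_p, and AR(1)
#' observation noise n_p at the configured stationary SD (see
#' \linkS4class{GeneratorConfig}). SpO2 is clipped to \[0, 100\] and all
#' vitals to >= 0. Output is byte-identical for identical configs.
#'
#' @param config A \linkS4class{GeneratorConfig}.
#' @return A \linkS4class{VitalSeries} of \code{nSamples} instants.
#' @export
generateVitals <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  params <- names(config@baselineMeans)
  n <- config@nSamples
  withLocalSeed(config@seed, {
    z <- driftPath(n, config@driftVelocityPhi, config@driftDecay)
    rho <- config@crossCorrelation
    vals <- matrix(NA_real_, nrow = n, ncol = length(params),
                   dimnames = list(NULL, params))
    for (p in params) {
      u <- driftPath(n, config@driftVelocityPhi, config@driftDecay)
      drift <- config@driftSds[[p]] * (rho * z + sqrt(1 - rho^2) * u)
      phi <- config@arCoefficient
      sigma <- config@noiseSds[[p]]
      eps <- stats::rnorm(n)
      if (sigma > 0) {
        innov <- sigma * sqrt(1 - phi^2) * eps
        innov[1L] <- sigma * eps[1L]  # start at the stationary distribution
        noise <- as.numeric(stats::filter(innov, phi, method = "recursive"))
      } else {
        noise <- numeric(n)
      }
      x <- config@baselineMeans[[p]] + drift + noise
      x <- pmax(x, 0)
      if (identical(p, "SpO2")) x <- pmin(x, 100)
      vals[, p] <- x
    }
    VitalSeries(vals, times = seq_len(n))
  })
}

#' Inject one anomaly into a labeled series
#'
#' Replaces the affected parameter values x over the event window by
#' \code{x * (1 + direction * magnitude)} and updates the labels. A
#' magnitude of 1 with direction -1 models a zero-dropout fault (the reading
#' collapses to 0). All untouched instants are bit-identical to the input.
#' Injected values are deliberately not clipped to physical ranges: the
#' aberrant reading is the point.
#'
#' @param x A \linkS4class{LabeledSeries}, or a \linkS4class{VitalSeries}
#'   (wrapped as all-normal).
#' @param event An \linkS4class{EventSpec}. The window must lie inside the
#'   series and not overlap an existing event; a medical event must affect a
#'   strict majority of the parameters.
#' @return A new \linkS4class{LabeledSeries} with the event applied.
#' @examples
#' cfg <- generatorConfig(nSamples = 60, seed = 3)
#' ls <- injectEvent(generateVitals(cfg),
#'                   eventSpec("sensor_fault", 45, 5, "HR", 0.5, +1))
#' table(seriesLabels(ls))
#' @export
injectEvent <- function(x, event) {
  if (is(x, "VitalSeries") && !is(x, "LabeledSeries")) x <- LabeledSeries(x)
  stopifnot(is(x, "LabeledSeries"), is(event, "EventSpec"))
  validObject(event)
  w <- eventWindow(event)
  if (min(w) < 1L || max(w) > length(x))
    stopf("event window [%d, %d] outside series of length %d",
          min(w), max(w), length(x))
  missing_p <- setdiff(event@parameters, parameterNames(x))
  if (length(missing_p))
    stopf("unknown parameter(s): %s", paste(missing_p, collapse = ", "))
  if (identical(event@kind, "medical_event") &&
      length(event@parameters) * 2L <= nParameters(x))
    stopf("a medical_event must affect a strict majority of the %d parameters",
          nParameters(x))
  for (ev in x@events) {
    if (length(intersect(w, eventWindow(ev))))
      stopf("event window [%d, %d] overlaps existing %s at [%d, %d]",
            min(w), max(w), ev@kind, ev@start, ev@start + ev@duration - 1L)
  }
  vals <- x@values
  for (p in event@parameters)
    vals[w, p] <- vals[w, p] * (1 + event@direction[[p]] * event@magnitude)
  labels <- x@labels
  labels[w] <- event@kind
  new("LabeledSeries", values = vals, times = x@times, units = x@units,
      labels = labels, events = c(x@events, event))
}

#' Build a labeled synthetic benchmark stream
#'
#' Generates a stream from \code{config} and injects the requested number of
#' correlated medical events and single-parameter sensor faults at seeded
#' uniform-random non-overlapping placements outside the warm-up region.
#' Medical events carry the correlated clinical signature: arterial pressure
#' rises while HR, Pulse, Respiration and SpO2 fall. Sensor faults perturb
#' one uniformly chosen parameter in a random direction.
#'
#' @param config A \linkS4class{GeneratorConfig} (its seed drives the base
#'   stream).
#' @param nMedical Number of medical events (default 5).
#' @param nFaults Number of sensor faults (default 10).
#' @param magnitudes Candidate perturbation fractions, sampled per event
#'   (default \code{c(0.20, 0.30, 0.50)}).
#' @param seed Seed for event placement and attributes (default
#'   \code{config@seed + 1000}).
#' @param warmup Instants at the start kept event-free so detection windows
#'   can fill (default 60).
#' @param medicalDuration,faultDuration Event lengths in samples (defaults 8
#'   and 5).
#' @param minGap Minimum normal samples between consecutive events
#'   (default 5).
#' @return A \linkS4class{LabeledSeries}.
#' @examples
#' bench <- makeBenchmark(generatorConfig(nSamples = 300, seed = 2),
#'                        nMedical = 2, nFaults = 3, magnitudes = 0.5)
#' length(seriesEvents(bench))
#' @export
makeBenchmark <- function(config, nMedical = 5L, nFaults = 10L,
                          magnitudes = c(0.20, 0.30, 0.50),
                          seed = config@seed + 1000L, warmup = 60L,
                          medicalDuration = 8L, faultDuration = 5L,
                          minGap = 5L) {
  stopifnot(is(config, "GeneratorConfig"))
  series <- LabeledSeries(generateVitals(config))
  params <- parameterNames(series)
  nEvents <- nMedical + nFaults
  if (nEvents == 0L) return(series)
  kinds <- c(rep("medical_event", nMedical), rep("sensor_fault", nFaults))
  durations <- ifelse(kinds == "medical_event", medicalDuration, faultDuration)
  N <- length(series)
  lastStart <- N - max(durations) + 1L
  if (lastStart <= warmup + 1L)
    stopf("series too short (%d) for events after warm-up %d", N, warmup)
  if (lastStart - warmup < nEvents)
    stopf("could not place %d events in %d candidate starts after warm-up %d",
          nEvents, lastStart - warmup, warmup)
  withLocalSeed(seed, {
    starts <- NULL
    for (try in seq_len(500L)) {
      cand <- sort(sample((warmup + 1L):lastStart, nEvents))
      perm <- sample.int(nEvents)  # which event occupies each time slot
      ends <- cand + durations[perm] - 1L
      if (all(ends <= N) &&
          (nEvents == 1L || all(cand[-1L] - ends[-nEvents] > minGap))) {
        starts <- integer(nEvents)
        starts[perm] <- cand
        break
      }
    }
    if (is.null(starts))
      stopf(paste0("could not place %d non-overlapping events with gap %d ",
                   "in %d samples after warm-up %d"),
            nEvents, minGap, N, warmup)
    medDirection <- ifelse(params == "ABPmean", 1, -1)
    names(medDirection) <- params
    for (i in seq_len(nEvents)) {
      mag <- if (length(magnitudes) == 1L) magnitudes
             else sample(magnitudes, 1L)
      ev <- if (kinds[i] == "medical_event") {
        eventSpec("medical_event", starts[i], durations[i], params, mag,
                  medDirection)
      } else {
        p <- if (length(params) == 1L) params else sample(params, 1L)
        eventSpec("sensor_fault", starts[i], durations[i], p, mag,
                  direction = sample(c(-1, 1), 1L))
      }
      series <- injectEvent(series, ev)
    }
    series
  })
}
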