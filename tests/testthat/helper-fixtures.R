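# Small in-code fixtures shared across the suite.

# A five-parameter series that is exactly constant: every threshold is zero
# and every forecast is exact, so all verdicts must be "normal".
constantSeries <- function(n = 45) {
  VitalSeries(cbind(ABPmean = rep(90, n), HR = rep(80, n), Pulse = rep(80, n),
                    Respiration = rep(16, n), SpO2 = rep(98, n)))
}

# A small low-noise generated stream (short, cheap) for pipeline fixtures.
quietConfig <- function(nSamples = 50, seed = 11) {
  generatorConfig(nSamples = nSamples, seed = seed,
                  driftSds = c(ABPmean = 0.5, HR = 0.4, Pulse = 0.4,
                               Respiration = 0.2, SpO2 = 0.1),
                  noiseSds = c(ABPmean = 0.05, HR = 0.04, Pulse = 0.04,
                               Respiration = 0.02, SpO2 = 0.01))
}

# Directions of a correlated medical deterioration: pressure up, the rest down.
medicalDirections <- function(params) {
  d <- ifelse(params == "ABPmean", 1, -1)
  names(d) <- params
  d
}

# Independent sample-SD oracle: direct formula, no call into the package.
oracleSd <- function(x) {
  if (length(x) < 2) return(0)
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
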