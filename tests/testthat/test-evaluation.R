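# Scoring uses hand-built decision tables so expectations are transparent.
fakeDecisions <- function(t, verdict) data.frame(t = t, verdict = verdict)

fakeTruth <- function(n, events) {
  labels <- rep("normal", n)
  for (ev in events) labels[seq(ev@start, length.out = ev@duration)] <- ev@kind
  list(labels = labels, events = events)
}

test_that("perfect triage of five medical and five fault events scores cleanly", {
  events <- c(lapply(seq(10, 50, 10), function(s)
                eventSpec("medical_event", s, 3, c("a", "b", "c"), 0.5,
                          c(a = 1, b = 1, c = 1))),
              lapply(seq(60, 100, 10), function(s)
                eventSpec("sensor_fault", s, 3, "a", 0.5)))
  truth <- fakeTruth(110, events)
  verdicts <- ifelse(truth$labels == "medical_event", "true_alarm",
                     ifelse(truth$labels == "sensor_fault", "false_alarm",
                            "normal"))
  cc <- scoreDecisions(fakeDecisions(1:110, verdicts), truth)
  expect_identical(c(cc@TP, cc@FP, cc@TN, cc@FN), c(5L, 0L, 5L, 0L))
  expect_identical(detectionRate(cc), 1)
  expect_identical(falsePositiveRate(cc), 0)
})

test_that("a degenerate always-alarm classifier scores all negatives as FP", {
  events <- c(lapply(c(10, 20, 30), function(s)
                eventSpec("medical_event", s, 2, c("a", "b"), 0.5,
                          c(a = 1, b = 1))),
              lapply(seq(40, 40 + 58 * 4, 4), function(s)
                eventSpec("sensor_fault", s, 2, "a", 0.5)))
  truth <- fakeTruth(300, events)
  cc <- scoreDecisions(fakeDecisions(1:300, rep("true_alarm", 300)), truth)
  expect_identical(c(cc@TP, cc@FP, cc@TN, cc@FN), c(3L, 59L, 0L, 0L))
})

test_that("event-level counts equal a brute-force per-event re-scan", {
  bench <- makeBenchmark(quietConfig(nSamples = 200, seed = 14), nMedical = 2,
                         nFaults = 3, magnitudes = 0.5, warmup = 35)
  dec <- runPipeline(bench)
  cc <- scoreDecisions(dec, bench)
  # oracle: rescan each event window independently
  tp <- fp <- tn <- fn <- 0L
  for (ev in seriesEvents(bench)) {
    w <- seq(ev@start, length.out = ev@duration)
    hit <- FALSE
    for (t in w) {
      v <- dec$verdict[dec$t == t]
      if (length(v) == 1 && v == "true_alarm") hit <- TRUE
    }
    if (ev@kind == "medical_event") {
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (hit) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  expect_identical(c(cc@TP, cc@FP, cc@TN, cc@FN), c(tp, fp, tn, fn))
  expect_identical(cc@TP + cc@FP + cc@TN + cc@FN,
                   length(seriesEvents(bench)))
})

test_that("scoring is invariant to event ordering and validates alignment", {
  events <- list(eventSpec("medical_event", 10, 2, c("a", "b"), 0.5,
                           c(a = 1, b = 1)),
                 eventSpec("sensor_fault", 20, 2, "a", 0.5),
                 eventSpec("sensor_fault", 30, 2, "b", 0.5))
  truth <- fakeTruth(40, events)
  dec <- fakeDecisions(1:40, c(rep("normal", 9), rep("true_alarm", 3),
                               rep("normal", 28)))
  cc1 <- scoreDecisions(dec, truth)
  truthRev <- truth
  truthRev$events <- rev(truth$events)
  cc2 <- scoreDecisions(dec, truthRev)
  expect_identical(c(cc1@TP, cc1@FP, cc1@TN, cc1@FN),
                   c(cc2@TP, cc2@FP, cc2@TN, cc2@FN))
  expect_error(scoreDecisions(fakeDecisions(50, "normal"), truth),
               "only 40 labels")
})

test_that("instant-level scoring counts each labeled decision instant", {
  events <- list(eventSpec("medical_event", 5, 4, c("a", "b"), 0.5,
                           c(a = 1, b = 1)),
                 eventSpec("sensor_fault", 15, 4, "a", 0.5))
  truth <- fakeTruth(25, events)
  verdicts <- rep("normal", 25)
  verdicts[5:6] <- "true_alarm"      # half the medical window caught
  verdicts[15] <- "true_alarm"       # one fault instant mis-declared
  verdicts[16:18] <- "false_alarm"
  cc <- scoreDecisions(fakeDecisions(1:25, verdicts), truth, mode = "instant")
  expect_identical(c(cc@TP, cc@FP, cc@TN, cc@FN), c(2L, 1L, 3L, 2L))
})

test_that("detection rate and false positive rate follow their defining ratios", {
  expect_identical(detectionRate(confusionCounts(TP = 5, FN = 0)), 1)
  expect_equal(detectionRate(confusionCounts(TP = 2, FN = 1)), 2 / 3,
               tolerance = 1e-12)
  expect_identical(detectionRate(confusionCounts(TP = 0, FN = 4)), 0)
  expect_identical(falsePositiveRate(confusionCounts(FP = 0, TN = 10)), 0)
  expect_identical(falsePositiveRate(confusionCounts(FP = 10, TN = 0)), 1)
  expect_warning(dr <- detectionRate(confusionCounts()), "undefined")
  expect_true(is.na(dr))
  expect_warning(fpr <- falsePositiveRate(confusionCounts(TP = 3)),
                 "undefined")
  expect_true(is.na(fpr))
})

test_that("ROC sweep at k = n matches a direct pipeline run and stays in range", {
  bench <- makeBenchmark(quietConfig(nSamples = 160, seed = 15), nMedical = 1,
                         nFaults = 2, magnitudes = 0.5, warmup = 35)
  tab <- rocSweep(bench, kValues = c(2, 5))
  expect_identical(tab$k, c(2, 5))
  expect_true(all(tab$DR >= 0 & tab$DR <= 1, na.rm = TRUE))
  expect_true(all(tab$FPR >= 0 & tab$FPR <= 1, na.rm = TRUE))
  direct <- scoreDecisions(runPipeline(bench), bench)
  expect_identical(tab$TP[tab$k == 5], direct@TP)
  expect_identical(tab$FP[tab$k == 5], direct@FP)
  expect_error(rocSweep(bench, kValues = 6), "outside")
})

test_that("voting over all five parameters dominates single-parameter voting", {
  bench <- makeBenchmark(generatorConfig(nSamples = 400, seed = 4),
                         nMedical = 3, nFaults = 6, magnitudes = 0.5)
  tab <- rocSweep(bench, kValues = c(1, 5))
  expect_gte(tab$DR[tab$k == 5], tab$DR[tab$k == 1])
  expect_lte(tab$FPR[tab$k == 5], tab$FPR[tab$k == 1])
})

test_that("threshold-mode comparison reports both modes and favors the dynamic threshold", {
  # an exactly stationary stream without events: both modes stay silent
  quiet <- LabeledSeries(constantSeries(90))
  tabQ <- thresholdModeComparison(quiet)
  expect_identical(tabQ$mode, c("dynamic", "fixed"))
  expect_identical(tabQ$nTrueAlarmInstants, c(0L, 0L))

  # quiet start then an accelerating baseline drift on every parameter: the
  # threshold frozen on the quiet initial window cannot follow the rising
  # local variability, so the fixed mode over-flags every parameter and
  # mis-declares the faults, while the dynamic threshold adapts
  base <- generateVitals(quietConfig(nSamples = 240, seed = 19))
  vals <- vitalValues(base)
  ramp <- pmax(seq_len(nrow(vals)) - 60, 0)
  for (p in colnames(vals)) vals[, p] <- vals[, p] + 0.02 * ramp * vals[1, p] / 90
  drift <- LabeledSeries(VitalSeries(vals, times = seriesTimes(base)))
  set.seed(3)
  for (s in c(100, 140, 180, 220))
    drift <- injectEvent(drift, eventSpec("sensor_fault", s, 4,
                                          sample(parameterNames(drift), 1),
                                          0.5, sample(c(-1, 1), 1)))
  tab <- thresholdModeComparison(drift)
  expect_identical(nrow(tab), 2L)
  expect_lte(tab$FPR[tab$mode == "dynamic"], tab$FPR[tab$mode == "fixed"])
})
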