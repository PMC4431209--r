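test_that("threshold buffer is FIFO and recomputes T_d after every update", {
  st <- thresholdState("HR", buffer = rep(80, 30), capacity = 30)
  expect_identical(thresholdSd(st), 0)
  expect_identical(thresholdValue(st), 0)

  st2 <- thresholdState("HR", buffer = c(2, 4, 4, 4, 5, 5, 7, 9), capacity = 8)
  expect_equal(thresholdSd(st2), oracleSd(c(2, 4, 4, 4, 5, 5, 7, 9)),
               tolerance = 1e-15)
  expect_equal(thresholdValue(st2), 2.13809, tolerance = 1e-5)

  st3 <- updateThreshold(st2, 11)
  expect_identical(length(st3@buffer), 8L)             # capacity kept
  expect_identical(st3@buffer, c(4, 4, 4, 5, 5, 7, 9, 11))  # oldest evicted
  expect_equal(thresholdValue(st3), oracleSd(st3@buffer), tolerance = 1e-12)

  expect_warning(st4 <- updateThreshold(st2, NaN), "non-finite")
  expect_identical(st4@buffer, st2@buffer)
  # kMult scales the threshold, not the SD
  stk <- thresholdState("HR", buffer = c(2, 4, 4, 4, 5, 5, 7, 9),
                        capacity = 8, kMult = 2.5)
  expect_equal(thresholdValue(stk), 2.5 * thresholdSd(stk), tolerance = 1e-15)
})

test_that("threshold SD equals the direct sample-SD formula over random buffers", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    buf <- rnorm(n, mean = runif(1, -50, 150), sd = runif(1, 0, 20))
    st <- thresholdState("x", buffer = buf, capacity = n)
    expect_equal(thresholdSd(st), oracleSd(buf), tolerance = 1e-12)
  }
})

test_that("error computation follows the residual and percentage definitions", {
  e <- computeError(100, 90)
  expect_identical(e$residual, 10)
  expect_identical(e$percentError, 10)
  e2 <- computeError(84.3, 84.3)
  expect_identical(e2$residual, 0)
  expect_identical(e2$percentError, 0)
  e3 <- computeError(0, 5)
  expect_identical(e3$residual, 5)
  expect_true(is.na(e3$percentError))   # undefined, never silently 0
  expect_error(computeError(NA, 5), "finite")
})

test_that("flagging is a strict comparison against the current threshold", {
  st <- thresholdState("HR", buffer = c(2, 4, 4, 4, 5, 5, 7, 9), capacity = 8)
  expect_true(flagParameter(computeError(90, 80), st))     # 10 > 2.138
  expect_false(flagParameter(computeError(80, 80), st))
  zero <- thresholdState("HR", buffer = rep(80, 10), capacity = 10)
  expect_false(flagParameter(0, zero))          # tie at 0 is not flagged
  expect_true(flagParameter(1e-9, zero))        # any nonzero residual is
  expect_false(flagParameter(thresholdValue(st), st))  # exact tie not flagged
})

test_that("majority voting applies the strict-majority rule with conservative ties", {
  expect_identical(majorityVote(c(1, 1, 1, 0, 0)), "true_alarm")    # 3 > 2.5
  expect_identical(majorityVote(c(1, 1, 0, 0, 0)), "false_alarm")
  expect_identical(majorityVote(c(0, 0, 0, 0, 0)), "normal")
  expect_identical(majorityVote(c(1, 1, 0, 0)), "false_alarm")      # tie
  expect_identical(majorityVote(TRUE), "true_alarm")
  expect_error(majorityVote(logical(0)), "empty")
  expect_error(majorityVote(c(1, 0), n = 3), "does not match")
})

test_that("majority voting equals the exhaustive count rule for all vectors up to n = 8", {
  for (n in 1:8) {
    grid <- as.matrix(expand.grid(rep(list(0:1), n)))
    for (i in seq_len(nrow(grid))) {
      flags <- grid[i, ]
      Y <- sum(flags)   # independent count comparison
      want <- if (Y == 0) "normal" else if (2 * Y > n) "true_alarm"
              else "false_alarm"
      expect_identical(majorityVote(flags), want)
    }
  }
})

test_that("a constant multivariate stream yields only normal verdicts", {
  dec <- runPipeline(constantSeries(45))
  expect_identical(unique(dec$verdict), "normal")
  expect_true(all(dec$voteCount == 0))
  expect_identical(nrow(dec), 15L)   # warm-up of 30 produces no decisions
})

test_that("a single-parameter fault is flagged alone and voted a false alarm", {
  base <- LabeledSeries(generateVitals(quietConfig(nSamples = 50, seed = 11)))
  fault <- injectEvent(base, eventSpec("sensor_fault", 40, 5, "HR", 0.5, +1))
  dec <- runPipeline(fault)
  win <- dec$t %in% 40:44
  # at the fault onset every window is still clean: HR (and only HR) must
  # exceed its threshold and the minority vote declares a false alarm
  onset <- dec[dec$t == 40, ]
  expect_identical(onset$verdict, "false_alarm")
  expect_identical(onset$HR_flag, 1)
  expect_identical(onset$voteCount, 1L)
  others <- paste0(setdiff(parameterNames(base), "HR"), "_flag")
  expect_true(all(dec[win, others] == 0))   # the fault never spreads
  expect_true(all(dec$verdict[win] %in% c("false_alarm", "normal")))
  # event-level: the fault is scored a true negative, not a medical alarm
  cc <- scoreDecisions(dec, fault)
  expect_identical(c(cc@TP, cc@FP, cc@TN, cc@FN), c(0L, 0L, 1L, 0L))
})

test_that("a correlated multi-parameter event is voted a true alarm", {
  base <- LabeledSeries(generateVitals(quietConfig(nSamples = 50, seed = 11)))
  params <- parameterNames(base)
  med <- injectEvent(base, eventSpec("medical_event", 40, 5, params, 0.5,
                                     medicalDirections(params)))
  dec <- runPipeline(med,
                     pipelineConfig(updatePolicy = "accept_normal_only"))
  win <- dec$t %in% 40:44
  expect_true(all(dec$verdict[win] == "true_alarm"))
  expect_true(all(dec$voteCount[win] == 5))
})

test_that("every decision carries exactly one verdict and the partition is complete", {
  bench <- makeBenchmark(quietConfig(nSamples = 160, seed = 2), nMedical = 1,
                         nFaults = 2, magnitudes = 0.5, warmup = 35)
  dec <- runPipeline(bench)
  expect_true(all(dec$verdict %in% c("normal", "true_alarm", "false_alarm")))
  expect_identical(nrow(dec) + length(attr(dec, "skipped")),
                   length(bench) - attr(dec, "warmup"))
  expect_true(all((dec$verdict == "normal") == (dec$voteCount == 0)))
  expect_true(all((dec$verdict == "true_alarm") ==
                    (dec$voteCount > dec$nVoting / 2)))
  expect_true(all(dec$voteCount >= 0 & dec$voteCount <= dec$nVoting))
})

test_that("raising the threshold multiplier never adds flags", {
  bench <- makeBenchmark(quietConfig(nSamples = 140, seed = 6), nMedical = 1,
                         nFaults = 1, magnitudes = 0.3, warmup = 35)
  d1 <- runPipeline(bench, pipelineConfig(kMult = 1))
  d2 <- runPipeline(bench, pipelineConfig(kMult = 2))
  f1 <- rowSums(as.matrix(d1[, grep("_flag$", names(d1))]), na.rm = TRUE)
  f2 <- rowSums(as.matrix(d2[, grep("_flag$", names(d2))]), na.rm = TRUE)
  expect_true(all(f2 <= f1))
})

test_that("the pipeline is deterministic end to end", {
  bench <- makeBenchmark(quietConfig(nSamples = 120, seed = 8), nMedical = 1,
                         nFaults = 1, magnitudes = 0.5, warmup = 35)
  expect_identical(runPipeline(bench), runPipeline(bench))
})

test_that("missing readings make a parameter abstain instead of voting", {
  vals <- vitalValues(generateVitals(quietConfig(nSamples = 50, seed = 13)))
  vals[40:42, "SpO2"] <- NA
  s <- VitalSeries(vals)
  dec <- runPipeline(s)
  rows <- dec$t %in% 40:42
  expect_true(all(is.na(dec$SpO2_flag[rows])))
  expect_true(all(dec$nVoting[rows] == 4))
  expect_true(all(dec$nVoting[dec$t > 75] == 5))  # window refilled, back to 5
})

test_that("update policies differ in what enters the windows", {
  base <- LabeledSeries(generateVitals(quietConfig(nSamples = 60, seed = 11)))
  fault <- injectEvent(base, eventSpec("sensor_fault", 40, 5, "HR", 0.5, +1))
  accAll <- runPipeline(fault, pipelineConfig(updatePolicy = "accept_all"))
  accNorm <- runPipeline(fault,
                         pipelineConfig(updatePolicy = "accept_normal_only"))
  # with accept_all the wild fault values enter the HR threshold buffer and
  # inflate the dynamic threshold after the fault; accept_normal_only keeps
  # the buffer clean so its threshold stays small
  after <- accAll$t %in% 46:55
  expect_gt(mean(accAll$HR_threshold[after]),
            mean(accNorm$HR_threshold[after]))
})

test_that("pipeline configs are validated before any computation", {
  expect_error(pipelineConfig(predictionWindow = 1), ">= 2")
  expect_error(pipelineConfig(kMult = 0), "kMult")
  s <- constantSeries(20)
  expect_error(runPipeline(s), "warm-up")
})
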