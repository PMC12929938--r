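# MSD and SE threshold classifiers, sweeps, dynamic range.

test_that("MSD rule agrees with the brute-force run-enumeration oracle", {
  cfg <- simConfig()
  cfgNoisy <- simConfig(noisyDelayProb = 0.6)
  set.seed(31)
  nDelayed <- 0L
  for (i in 1:150) {
    cls <- sample(c("delayed", "non_delayed"), 1)
    ev <- generateEvent(if (i %% 3 == 0) cfgNoisy else cfg, cls,
                        seed = 30000 + i)
    # vary the threshold so both outcomes and borderline cases occur
    thr <- sample(c(0.001, 0.003, 0.01, 0.05), 1)
    p <- msdParams(sigmaThreshold = thr)
    call <- classifyMsd(ev, p)
    want <- oracleMsdDelayed(normalizeTrace(ev), 75, thr, 10, 0.7)
    expect_identical(call$label == "delayed", want)
    if (want) nDelayed <- nDelayed + 1L
  }
  expect_gt(nDelayed, 10)  # both outcomes exercised
})

test_that("MSD rule reports a qualifying run with its location", {
  # constructed delay: zero-noise plateau, onset 0.72, length 20%
  cfg <- simConfig(delayNoiseSd = 0, delayOnsetFracRange = c(0.72, 0.72),
                   delayLenFracRange = c(0.20, 0.20))
  call <- classifyMsd(generateEvent(cfg, "delayed", seed = 41))
  expect_equal(call$label, "delayed")
  expect_gte(call$run_length, 11)
  expect_gte(call$delay_start_frac, 0.7)

  # white-noise trace: every bin far above threshold
  set.seed(5)
  noise <- eventTrace(450 + rnorm(3000, 0, 12))
  expect_equal(classifyMsd(noise)$label, "non_delayed")

  # quiet plateau at fractional position 0.3 only: gated out
  x <- 450 + rnorm(3000, 0, 12)
  x[900:1600] <- 300
  x[1] <- 200; x[2] <- 700   # pin the range
  expect_equal(classifyMsd(eventTrace(x))$label, "non_delayed")
})

test_that("raising the threshold never revokes a delayed call", {
  cfg <- simConfig()
  thresholds <- c(0.001, 0.002, 0.003, 0.005, 0.01, 0.03)
  for (i in 1:25) {
    ev <- generateEvent(cfg, sample(c("delayed", "non_delayed"), 1),
                        seed = 600 + i)
    msdCalls <- vapply(thresholds, function(t)
      classifyMsd(ev, msdParams(sigmaThreshold = t))$label == "delayed",
      logical(1))
    expect_true(all(diff(msdCalls) >= 0))
    seCalls <- vapply(c(0.05, 0.2, 0.495, 0.7, 0.9), function(t)
      classifySe(ev, seParams(seThreshold = t))$label == "delayed",
      logical(1))
    expect_true(all(diff(seCalls) >= 0))
  }
})

test_that("MSD hits high recall and low false-positive rate at defaults", {
  cfg <- simConfig()
  evD <- lapply(1:150, function(i) generateEvent(cfg, "delayed", 1e5 + i))
  evN <- lapply(1:150, function(i) generateEvent(cfg, "non_delayed", 2e5 + i))
  recall <- mean(classifyEvents(evD, "msd")$label == "delayed")
  fpr <- mean(classifyEvents(evN, "msd")$label == "delayed")
  expect_gte(recall, 0.95)
  expect_lte(fpr, 0.05)
})

test_that("SE rule flags plateaus and spares stationary noise", {
  cfg <- simConfig()
  ev <- generateEvent(cfg, "delayed", seed = 51)
  call <- classifySe(ev)
  expect_equal(call$label, "delayed")
  expect_lt(call$score, 0.495)
  expect_gt(call$delay_start_frac, 0.7)

  # stationary noise events stay above the calibrated threshold
  mins <- vapply(1:60, function(s) {
    set.seed(s)
    classifySe(eventTrace(450 + rnorm(2500, 0, 12)))$score
  }, numeric(1))
  expect_true(all(mins > 0.495))

  # threshold 0: nothing can fall strictly below
  expect_equal(classifySe(ev, seParams(seThreshold = 0))$label,
               "non_delayed")

  # too short for a frame beyond the gate: indeterminate error
  short <- eventTrace(450 + rnorm(140, 0, 12))
  expect_error(classifySe(short), class = "poreDelay_indeterminate")
  tab <- classifyEvents(list(short, ev), "se")
  expect_true(tab$indeterminate[1])
  expect_false(tab$indeterminate[2])
})

test_that("threshold sweeps saturate at the extremes and are monotone", {
  cfg <- simConfig()
  ev <- c(lapply(1:25, function(i) generateEvent(cfg, "delayed", 700 + i)),
          lapply(1:25, function(i) generateEvent(cfg, "non_delayed", 800 + i)))
  groups <- rep(c("100", "0"), each = 25)

  for (method in c("msd", "se")) {
    thr <- if (method == "msd") c(1e-6, 0.001, 0.003, 0.02, 2)
           else c(1e-6, 0.2, 0.495, 0.8, 1)
    sw <- sweepThreshold(ev, groups, method, thr)
    for (g in unique(sw$group)) {
      col <- sw$pct_delayed[sw$group == g][order(sw$threshold[sw$group == g])]
      expect_true(all(diff(col) >= 0))
      expect_equal(col[1], 0)            # below the global minimum score
      expect_equal(col[length(col)], 100)  # above the global maximum
    }
    # monotone columns checked against direct per-threshold classification
    p <- if (method == "msd") msdParams(sigmaThreshold = thr[3])
         else seParams(seThreshold = thr[3])
    direct <- classifyEvents(ev, method, p)
    swMid <- sw[sw$threshold == thr[3], ]
    for (g in unique(groups)) {
      expect_equal(
        swMid$pct_delayed[swMid$group == g],
        100 * mean(direct$label[groups == g] == "delayed", na.rm = TRUE))
    }
  }
})

test_that("dynamic range differences are computed per threshold", {
  sw <- data.frame(group = rep(c("hi", "lo"), each = 3),
                   threshold = rep(1:3, 2),
                   pct_delayed = c(80, 90, 100, 10, 20, 100))
  dr <- dynamicRange(sw, "hi", "lo")
  expect_equal(dr$dynamic_range, c(70, 70, 0))
  same <- dynamicRange(rbind(sw[1:3, ], transform(sw[1:3, ], group = "lo")),
                       "hi", "lo")
  expect_true(all(same$dynamic_range == 0))
  expect_error(dynamicRange(sw, "hi", "missing"), "missing")
})
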