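# Synthetic event, cohort and read generators.

test_that("event generation is deterministic and respects the clip band", {
  cfg <- simConfig()
  e1 <- generateEvent(cfg, "delayed", seed = 1)
  e2 <- generateEvent(cfg, "delayed", seed = 1)
  expect_identical(traceSamples(e1), traceSamples(e2))
  e3 <- generateEvent(cfg, "delayed", seed = 2)
  expect_false(identical(traceSamples(e1), traceSamples(e3)))
  for (ev in list(e1, e3, generateEvent(cfg, "non_delayed", 3))) {
    x <- traceSamples(ev)
    expect_gte(min(x), 200)
    expect_lte(max(x), 700)
    expect_gte(length(x), 1500)
    expect_lte(length(x), 4000)
  }
  expect_gte(eventMeta(e1)$onset_frac, 0.70)
  expect_error(generateEvent(cfg, "bogus", 1), "cls")
  expect_error(simConfig(eventLenRange = c(400, 100)), "ordered pair")
  expect_error(simConfig(delayNoiseSd = 20), "quieter")
})

test_that("non-delayed traces contain no long quiet window", {
  cfg <- simConfig()
  ev <- generateEvent(cfg, "non_delayed", seed = 1)
  x <- traceSamples(ev)
  n <- length(x)
  w <- ceiling(0.10 * n)
  step <- max(1L, w %/% 4L)
  sds <- vapply(seq(1L, n - w + 1L, by = step), function(s)
    sd(x[s:(s + w - 1L)]), numeric(1))
  expect_gt(min(sds), 3)  # pA
})

test_that("a zero-noise delay segment is exactly constant", {
  cfg <- simConfig(delayNoiseSd = 0)
  ev <- generateEvent(cfg, "delayed", seed = 5)
  x <- traceSamples(ev)
  n <- length(x)
  m <- eventMeta(ev)
  idx <- (round(m$onset_frac * n) + 1L):(round((m$onset_frac +
    m$delay_len_frac) * n) - 1L)
  expect_equal(sd(x[idx]), 0)
})

test_that("delayed and non-delayed classes separate in binned sd", {
  # delay-region bins of delayed events drop below 3 pA; no 75-bin sd of a
  # non-delayed event does
  cfg <- simConfig()
  nOk <- 0L
  nEv <- 120L
  for (i in seq_len(nEv)) {
    d <- generateEvent(cfg, "delayed", seed = 4000 + i)
    nd <- generateEvent(cfg, "non_delayed", seed = 8000 + i)
    sdD <- oracleBinSds(traceSamples(d), 75)
    m <- eventMeta(d)
    n <- length(traceSamples(d))
    reg <- which(oracleBinStarts(n, 75) / n >= m$onset_frac)
    sdN <- oracleBinSds(traceSamples(nd), 75)
    if (min(sdD[reg]) < 3 && min(sdN) > 3) nOk <- nOk + 1L
  }
  expect_gte(nOk / nEv, 0.99)
})

test_that("datasets have exact class counts and seed-dependent order", {
  cfg <- simConfig()
  ds <- generateDataset(cfg, 12, 8, seed = 7)
  expect_length(ds, 20)
  labs <- vapply(ds, eventLabel, character(1))
  expect_equal(sum(labs == "delayed"), 12)
  expect_equal(sum(labs == "non_delayed"), 8)
  ids1 <- vapply(ds, eventId, character(1))
  ids2 <- vapply(generateDataset(cfg, 12, 8, seed = 8), eventId, character(1))
  expect_setequal(ids1, ids2)
  expect_false(identical(ids1, ids2))  # different shuffle
  onlyN <- generateDataset(cfg, 0, 5, seed = 1)
  expect_true(all(vapply(onlyN, eventLabel, character(1)) == "non_delayed"))
})

test_that("dose-response cohorts realize the Hill expectation", {
  co <- cohortSpec(concentrations = c(0, 1.19, 100), nEventsPerConc = 400,
                   nReplicates = 1, baselinePct = 0)
  # midpoint identity: expected pct at C = Ke is baseline + Vmax/2
  expected <- poreDelay:::.hillExpectedPct(co, 1.19)
  expect_equal(expected, 36.59 / 2, tolerance = 1e-12)
  expect_equal(poreDelay:::.hillExpectedPct(co, 0), 0)

  cfg <- simConfig(eventLenRange = c(1500L, 1600L))
  sim <- generateDoseResponse(co, cfg, seed = 10)
  tr <- sim$truth
  for (r in seq_len(nrow(tr))) {
    p <- tr$expected_pct[r] / 100
    sdBin <- sqrt(p * (1 - p) / tr$n_events[r]) * 100
    expect_lte(abs(tr$realized_pct[r] - tr$expected_pct[r]),
               3 * sdBin + 1e-9)
  }
  labs <- vapply(sim$events[["conc100_rep1"]], eventLabel, character(1))
  expect_equal(sum(labs == "delayed"),
               tr$n_delayed[tr$conc_nM == 100])
  expect_error(cohortSpec(baselinePct = 80, hillVmax = 40), "100")
})

test_that("generated reads embed the barcode with the stated error profile", {
  g0 <- generateReads(30, 0, seed = 3)
  expect_true(all(grepl(referenceBarcode(), g0$reads, fixed = TRUE)))
  expect_true(all(g0$truth$n_sub == 0))

  g <- generateReads(500, 0.02, seed = 4)
  mu <- 38 * 0.02
  sdv <- sqrt(38 * 0.02 * 0.98)
  expect_lte(abs(mean(g$truth$n_sub) - mu), 3 * sdv / sqrt(500))

  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeReads(generateReads(20, 0.05, seed = 9)$reads, f1)
  writeReads(generateReads(20, 0.05, seed = 9)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generateReads(5, 0.7, seed = 1), "errorRate")
})
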