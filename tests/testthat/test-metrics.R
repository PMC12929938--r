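# Confusion metrics, AUC, radar scaling, MAD gate, baseline correction,
# SEM summaries, Hill fitting.

test_that("confusion counts tally exactly", {
  cc <- confusionCounts(rep(c("delayed", "non_delayed"), each = 10),
                        rep(c("delayed", "non_delayed"), each = 10))
  expect_equal(unname(cc), c(10, 0, 0, 10))
  allNeg <- confusionCounts(rep(c("delayed", "non_delayed"), 5),
                            rep("non_delayed", 10))
  expect_equal(allNeg[["tp"]], 0)
  expect_equal(allNeg[["fp"]], 0)

  set.seed(101)
  y <- sample(c("delayed", "non_delayed"), 100, replace = TRUE)
  p <- sample(c("delayed", "non_delayed"), 100, replace = TRUE)
  cc2 <- confusionCounts(y, p)
  # independent tally
  expect_equal(cc2[["tp"]], sum(y == "delayed" & p == "delayed"))
  expect_equal(cc2[["fn"]], sum(y == "delayed" & p == "non_delayed"))
  expect_equal(sum(cc2), 100)
  expect_error(confusionCounts(y, p[1:10]), "length")
})

test_that("metric suite agrees with the formula oracle incl. degenerates", {
  set.seed(102)
  worst <- 0
  nChecked <- 0L
  for (i in 1:10000) {
    cc <- c(tp = rpois(1, 20), fp = rpois(1, 5),
            fn = rpois(1, 20), tn = rpois(1, 30))
    if (i %% 7 == 0) cc[sample(4, sample(1:3, 1))] <- 0
    if (sum(cc) == 0) next
    got <- unlist(computeMetrics(cc)[1, 1:5])
    want <- oracleMetrics(cc[["tp"]], cc[["fp"]], cc[["fn"]], cc[["tn"]])
    expect_identical(is.na(got), is.na(want))
    d <- abs(got - want)
    worst <- max(worst, d[!is.na(d)])
    nChecked <- nChecked + 1L
  }
  expect_gt(nChecked, 9000)
  expect_lt(worst, 1e-12)
  perfect <- computeMetrics(c(tp = 50, fp = 0, fn = 0, tn = 50))
  expect_equal(unlist(perfect[1, 1:5]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, mcc = 1))
  degenerate <- computeMetrics(c(tp = 0, fp = 0, fn = 10, tn = 10))
  expect_true(is.na(degenerate$precision))
  expect_true("precision" %in% attr(degenerate, "undefined"))
})

test_that("AUC equals pair counting and survives monotone transforms", {
  y <- rep(c("delayed", "non_delayed"), each = 50)
  sep <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  expect_equal(rocAuc(sep, y), 1)
  expect_equal(rocAuc(rep(0.5, 100), y), 0.5)

  s6 <- c(0.9, 0.8, 0.8, 0.3, 0.2, 0.8)
  y6 <- c("delayed", "delayed", "non_delayed", "non_delayed",
          "non_delayed", "delayed")
  expect_equal(rocAuc(s6, y6), oracleAuc(s6, y6))

  set.seed(103)
  s <- rnorm(100)
  y2 <- sample(c("delayed", "non_delayed"), 100, replace = TRUE,
               prob = c(0.4, 0.6))
  expect_equal(rocAuc(s, y2), oracleAuc(s, y2), tolerance = 1e-12)
  expect_equal(rocAuc(exp(2 * s) + 5, y2), rocAuc(s, y2), tolerance = 1e-12)
  expect_error(rocAuc(s, rep("delayed", 100)), "both classes")
})

test_that("AUC matches an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(104)
  s <- rnorm(200)
  y <- sample(c("delayed", "non_delayed"), 200, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = s, levels = c("non_delayed", "delayed"),
    direction = "<", quiet = TRUE)))
  expect_equal(rocAuc(s, y), ref, tolerance = 1e-12)
})

test_that("radar min-max scaling maps extremes and preserves order", {
  tab <- data.frame(accuracy = c(0.7, 0.9, 0.8), mcc = c(0.4, 0.9, 0.6))
  sc <- minmaxRadar(tab)
  expect_equal(range(sc$accuracy), c(0, 1))
  expect_equal(range(sc$mcc), c(0, 1))
  expect_identical(order(sc$accuracy), order(tab$accuracy))
  # two rows: everything maps to {0, 1}
  two <- minmaxRadar(tab[1:2, ])
  expect_true(all(unlist(two) %in% c(0, 1)))
  # invertibility
  lo <- vapply(tab, min, numeric(1)); hi <- vapply(tab, max, numeric(1))
  back <- sweep(sweep(as.matrix(sc), 2, hi - lo, "*"), 2, lo, "+")
  expect_equal(unname(back), unname(as.matrix(tab)), tolerance = 1e-12)
  expect_error(minmaxRadar(tab[1, , drop = FALSE]), "two rows")
  expect_warning(minmaxRadar(data.frame(a = c(1, 1), b = c(0, 1))),
                 "constant")
})

test_that("MAD gate excludes three-MAD outliers, unscaled", {
  expect_warning(out <- madFilter(c(10, 10, 10, 50)), "MAD is zero")
  expect_equal(out$kept, c(10, 10, 10))  # MAD = 0 path
  expect_equal(out$excluded, 4L)
  none <- madFilter(c(1, 2, 3, 4, 5))  # median 3, MAD 1, all within 3
  expect_length(none$excluded, 0)
  one <- madFilter(42)
  expect_equal(one$kept, 42)
  far <- madFilter(c(1, 2, 3, 4, 5, 30))
  expect_true(6L %in% far$excluded)
})

test_that("baseline correction is per replicate and offset invariant", {
  tab <- expand.grid(conc_nM = c(0, 1, 10), replicate = 1:3)
  tab$pct_delay <- 5 * tab$replicate + tab$conc_nM
  cor1 <- baselineCorrect(tab)
  expect_true(all(cor1$corrected[cor1$conc_nM == 0] == 0))
  expect_equal(cor1$corrected, rep(c(0, 1, 10), 3))
  # additive shift of one replicate leaves its corrected values unchanged
  tab2 <- tab
  tab2$pct_delay[tab2$replicate == 2] <-
    tab2$pct_delay[tab2$replicate == 2] + 7.3
  cor2 <- baselineCorrect(tab2)
  expect_equal(cor2$corrected, cor1$corrected, tolerance = 1e-12)
  # flat table: all-zero corrected column
  flat <- tab
  flat$pct_delay <- 4
  expect_true(all(baselineCorrect(flat)$corrected == 0))
  expect_error(baselineCorrect(tab[tab$conc_nM > 0, ]), "0 nM")
})

test_that("dose summaries report mean and SEM per concentration", {
  tab <- data.frame(conc_nM = rep(c(0, 1), each = 3), replicate = rep(1:3, 2),
                    pct_delay = c(2, 4, 6, 10, 10, 10))
  s <- summarizeDose(tab)
  expect_equal(s$mean, c(4, 10))
  expect_equal(s$sem[1], 2 / sqrt(3), tolerance = 1e-12)  # sd 2
  expect_equal(s$sem[2], 0)
  single <- summarizeDose(data.frame(conc_nM = 0, replicate = 1,
                                     pct_delay = 5))
  expect_true(is.na(single$sem))
  expect_false(single$sem_defined)
})

test_that("Hill fit recovers exact generating parameters on clean data", {
  conc <- c(0, 0.1, 0.5, 1, 2.5, 5, 10, 50, 100)
  resp <- 36.59 * conc^2.25 / (1.19^2.25 + conc^2.25)
  tab <- data.frame(conc_nM = rep(conc, 3), replicate = rep(1:3, each = 9),
                    pct_delay = rep(resp, 3) + 2)  # +2 baseline, removed by
  fit <- fitHill(tab)                              # correction
  expect_equal(fit@nh, 2.25, tolerance = 1e-6)
  expect_equal(fit@ke, 1.19, tolerance = 1e-6)
  expect_equal(fit@vmax, 36.59, tolerance = 1e-6)
  expect_gt(fit@r2, 1 - 1e-10)
  # Hill identity: fitted response at Ke is half of Vmax
  expect_equal(hillResponse(fit, fit@ke), fit@vmax / 2, tolerance = 1e-12)
  expect_error(fitHill(tab[tab$conc_nM %in% c(0, 1), ]), "4 distinct")
})

test_that("EC50 recovery bias vanishes as replicate noise does", {
  conc <- c(0, 0.1, 0.5, 1, 2.5, 5, 10, 50, 100)
  resp <- 36.59 * conc^2.25 / (1.19^2.25 + conc^2.25)
  for (noise in c(0, 0.5, 2)) {
    kes <- vapply(1:40, function(s) {
      set.seed(1000 + s)
      tab <- data.frame(conc_nM = rep(conc, 3),
                        replicate = rep(1:3, each = 9),
                        pct_delay = rep(resp, 3) + rnorm(27, 0, noise))
      tab$pct_delay[tab$conc_nM == 0] <- rnorm(3, 0, noise)
      fitHill(tab)@ke
    }, numeric(1))
    tolPct <- if (noise == 0) 1e-4 else if (noise == 0.5) 0.05 else 0.15
    expect_lt(abs(mean(kes) - 1.19) / 1.19, tolPct)
  }
})
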