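# Trace rendering, network training, prediction, Grad-CAM.

test_that("rendering geometry: a constant mid-band trace is a mid-height line", {
  img <- renderImage(rep(450, 2000), 56)
  px <- imagePixels(img)
  rows <- which(rowSums(px) > 0)
  # 450 pA on a [200, 700] axis sits at the vertical midpoint
  expect_true(all(abs(rows - 28.5) <= 1.5))
  expect_true(all(px >= 0 & px <= 1))
  expect_gt(sum(px[, 1]), 0)   # line spans the full width
  expect_gt(sum(px[, 56]), 0)
})

test_that("rendering is deterministic and honours the clipping contract", {
  ev <- generateEvent(simConfig(), "delayed", seed = 61)
  i1 <- renderImage(ev, 56)
  i2 <- renderImage(ev, 56)
  expect_identical(imagePixels(i1), imagePixels(i2))

  x <- traceSamples(ev)
  wild <- x
  wild[c(10, 500)] <- c(1e5, -1e5)
  clipped <- pmin(pmax(wild, 200), 700)
  # median recentering differs unless disabled; compare with it off
  expect_identical(imagePixels(renderImage(wild, 56, baseLevel = NA)),
                   imagePixels(renderImage(clipped, 56, baseLevel = NA)))
  expect_error(renderImage(x, 57), "unsupported resolution")
  expect_error(renderImage(numeric(0), 56), "empty")
})

test_that("parameter count follows the closed-form architecture arithmetic", {
  # conv1 16*(25+1); conv2 32*(16*25+1); fc 64*(11*11*32+1); out 2*(64+1)
  expect_equal(cnnParameterCount(cnnSpec(inputResolution = 56)), 261250)
  spec28 <- cnnSpec(inputResolution = 28)
  expect_equal(cnnParameterCount(spec28),
               16 * 26 + 32 * 401 + 64 * (4 * 4 * 32 + 1) + 2 * 65)
  expect_error(cnnSpec(inputResolution = 12), "too small")
})

test_that("training beats the majority baseline and is reproducible", {
  model <- fixtureSmallModel()
  hist <- trainHistory(model)
  expect_gt(hist$train_accuracy[nrow(hist)], 0.5)
  expect_true(all(c("train_loss", "val_loss") %in% names(hist)))

  te <- fixtureTestEvents()
  pred1 <- cnnPredict(model, renderImages(te, 56))
  pred2 <- cnnPredict(model, renderImages(te, 56))
  expect_identical(pred1$label, pred2$label)
  expect_equal(pred1$p_delayed + pred1$p_non_delayed,
               rep(1, nrow(pred1)), tolerance = 1e-6)
  # the simulated classes are cleanly separable at this scale
  expect_gt(mean(pred1$label == fixtureLabels(te)), 0.95)

  # duplicate image -> identical probabilities
  img <- renderImages(te[1], 56)
  p2 <- cnnPredict(model, c(img, img))
  expect_equal(p2$p_delayed[1], p2$p_delayed[2])

  wrongRes <- renderImages(te[1], 28)
  expect_error(cnnPredict(model, wrongRes), "resolution")
  expect_error(cnnTrain(img, "delayed", img, "delayed"), "both classes")
})

test_that("shuffled labels yield chance-level validation accuracy", {
  cfg <- simConfig(eventLenRange = c(1500L, 1800L))
  tr <- generateDataset(cfg, 40, 40, seed = 301, idPrefix = "nul")
  va <- generateDataset(cfg, 15, 15, seed = 302, idPrefix = "nuv")
  imTr <- renderImages(tr, 28)
  imVa <- renderImages(va, 28)
  yVa <- fixtureLabels(va)
  accs <- vapply(1:10, function(s) {
    yPerm <- withr::with_seed(400 + s, sample(fixtureLabels(tr)))
    m <- cnnTrain(imTr, yPerm, imVa, yVa,
                  spec = cnnSpec(inputResolution = 28),
                  cfg = trainConfig(epochsMax = 3, seed = 500 + s))
    h <- trainHistory(m)
    h$val_accuracy[nrow(h)]
  }, numeric(1))
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("Grad-CAM channel weights match finite-difference gradients", {
  spec <- cnnSpec(convFilters = c(2L, 2L), kernelSize = 3L, fcUnits = 4L,
                  inputResolution = 16L)
  w <- withr::with_seed(11, {
    w0 <- poreDelay:::.initWeights(spec)
    # nonzero biases keep every pre-activation away from the ReLU kink,
    # where the one-sided subgradient convention would bias the comparison
    for (nm in c("b1", "b2", "b3", "b4"))
      w0[[nm]] <- runif(length(w0[[nm]]), 0.05, 0.2)
    w0
  })
  x <- withr::with_seed(12, rnorm(16 * 16))
  args <- list(w, x, 16L, 3L, 2L, 2L, 4L, 2L)
  for (target in 0:1) {
    out <- do.call(poreDelay:::.cnn_gradcam_cpp, c(args, target))
    # analytic gradient dlogit/db2[f] = sum over active units of dA2
    act <- out$activations
    grad <- out$gradients
    analytic <- vapply(1:2, function(f)
      sum(grad[, , f][act[, , f] > 0]), numeric(1))
    h <- 1e-5
    fd <- vapply(1:2, function(f) {
      wp <- w; wm <- w
      wp$b2[f] <- wp$b2[f] + h
      wm$b2[f] <- wm$b2[f] - h
      lp <- do.call(poreDelay:::.cnn_logits_cpp,
                    c(list(wp), args[-1]))[target + 1]
      lm_ <- do.call(poreDelay:::.cnn_logits_cpp,
                     c(list(wm), args[-1]))[target + 1]
      (lp - lm_) / (2 * h)
    }, numeric(1))
    expect_equal(analytic, fd, tolerance = 1e-3)
  }
})

test_that("saliency maps are contracts-true and focus on the delay band", {
  model <- fixtureSmallModel()
  te <- fixtureTestEvents()
  labs <- fixtureLabels(te)
  imgs <- renderImages(te, 56)
  pred <- cnnPredict(model, imgs)
  hits <- which(labs == "delayed" & pred$label == "delayed")
  expect_gte(length(hits), 30)
  hits <- head(hits, 60)
  mass <- vapply(hits, function(i) {
    sal <- gradCam(model, imgs[[i]], 0L)
    expect_equal(dim(sal@heatmap), c(56, 56))
    expect_true(all(sal@heatmap >= 0 & sal@heatmap <= 1))
    if (!sal@zero) expect_equal(max(sal@heatmap), 1)
    saliencyBandMass(sal)
  }, numeric(1))
  # mean saliency mass in the [0.7, 1] band beats the uniform expectation
  expect_gt(mean(mass, na.rm = TRUE), 0.30)

  # degenerate zero-gradient model: all-zero heatmap, flagged
  zw <- model@weights
  zw$W4[] <- 0
  zw$b4[] <- 0
  zmodel <- new("CnnModel", spec = model@spec, weights = zw,
                history = model@history, normMean = model@normMean,
                normSd = model@normSd, trained = TRUE)
  zsal <- gradCam(zmodel, imgs[[1]], 0L)
  expect_true(zsal@zero)
  expect_true(all(zsal@heatmap == 0))
  expect_error(gradCam(new("CnnModel", spec = model@spec), imgs[[1]], 0L),
               "untrained")
})

test_that("a reduced resolution sweep emits one metric set per resolution", {
  cfg <- simConfig(eventLenRange = c(1500L, 1800L))
  tr <- generateDataset(cfg, 30, 30, seed = 311, idPrefix = "swt")
  va <- generateDataset(cfg, 10, 10, seed = 312, idPrefix = "swv")
  te <- generateDataset(cfg, 15, 15, seed = 313, idPrefix = "swe")
  sw <- suppressWarnings(resolutionSweep(tr, va, te, c(28, 56, 70),
                         cfg = trainConfig(epochsMax = 2, seed = 321)))
  expect_equal(nrow(sw$metrics), 3)
  expect_equal(sw$metrics$resolution, c(28, 56, 70))
  for (nm in c("accuracy", "mcc")) {
    col <- sw$radar[[nm]]
    if (!all(is.na(col))) {
      expect_equal(min(col), 0)
      expect_equal(max(col), 1)
    }
  }
  expect_error(resolutionSweep(tr, va, te, 56), "at least two")
})
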