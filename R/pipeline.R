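# End-to-end orchestration: benchmark of the three classifiers and
# dose-response quantification.

#' Assemble a run configuration
#'
#' A fully serializable description of an end-to-end run: simulator
#' settings, classifier parameters, network architecture and training
#' settings, dataset sizes, and the master seed. Re-running a saved
#' configuration reproduces every deterministic artifact.
#'
#' @param sim a [SimConfig-class].
#' @param msd an [MsdParams-class].
#' @param se an [SeParams-class].
#' @param cnn a [cnnSpec()] list.
#' @param train a [trainConfig()] list.
#' @param sizes named list with train/val/blind per-class counts.
#' @param seed master seed.
#' @return named list with class "poreDelayRunConfig".
#' @export
runConfig <- function(sim = simConfig(), msd = msdParams(), se = seParams(),
                      cnn = cnnSpec(), train = trainConfig(),
                      sizes = list(train = c(1000L, 1000L),
                                   val = c(250L, 250L),
                                   blind = c(1000L, 1000L)),
                      seed = 1L) {
  structure(list(sim = sim, msd = msd, se = se, cnn = cnn, train = train,
                 sizes = sizes, seed = as.integer(seed)),
            class = "poreDelayRunConfig")
}

.labelsOf <- function(events) vapply(events, eventLabel, character(1))
.idsOf <- function(events) vapply(events, eventId, character(1))

#' Benchmark the three classifiers on a simulated blind set
#'
#' Simulates training, validation and blind datasets (sized per
#' \code{cfg$sizes}; defaults 1000/1000, 250/250, 1000/1000 per class),
#' trains the convolutional classifier on rendered images, classifies the
#' blind set with all three methods, and reports per-method confusion
#' counts, metrics, the per-event call table, and the min-max radar table.
#' Blind events are generated from an independent seed stream and their
#' identifiers are audited to be disjoint from the training data - the
#' blind set never participates in training or labeling.
#'
#' @param cfg a [runConfig()].
#' @param verbose print stage progress.
#' @return list: \code{calls} (per-event, per-method), \code{confusion}
#'   (per method), \code{metrics} (data.frame, one row per method),
#'   \code{radar} (min-max scaled metrics), \code{model} (trained
#'   [CnnModel-class]), \code{truth} (blind labels).
#' @export
runBenchmark <- function(cfg = runConfig(), verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  seed <- cfg$seed
  res <- cfg$cnn$inputResolution

  say("simulating datasets")
  trainEv <- generateDataset(cfg$sim, cfg$sizes$train[1], cfg$sizes$train[2],
                             seed = seed + 1L, idPrefix = "train")
  valEv <- generateDataset(cfg$sim, cfg$sizes$val[1], cfg$sizes$val[2],
                           seed = seed + 2L, idPrefix = "val")
  blindEv <- generateDataset(cfg$sim, cfg$sizes$blind[1], cfg$sizes$blind[2],
                             seed = seed + 3L, idPrefix = "blind")
  if (length(intersect(.idsOf(blindEv), c(.idsOf(trainEv), .idsOf(valEv)))))
    stop("blind event ids overlap the training data")

  say("rendering images at ", res, "x", res)
  trainIm <- renderImages(trainEv, res)
  valIm <- renderImages(valEv, res)

  say("training the convolutional classifier")
  model <- cnnTrain(trainIm, .labelsOf(trainEv), valIm, .labelsOf(valEv),
                    spec = cfg$cnn, cfg = cfg$train)

  say("classifying the blind set")
  truth <- .labelsOf(blindEv)
  callsMsd <- classifyEvents(blindEv, "msd", cfg$msd)
  callsSe <- classifyEvents(blindEv, "se", cfg$se)
  callsCnn <- classifyCnn(model, blindEv)
  calls <- rbind(callsMsd, callsSe, callsCnn)

  methodMetrics <- function(callTab) {
    ok <- !callTab$indeterminate
    cc <- confusionCounts(truth[ok], callTab$label[ok])
    # scores are oriented lower = more delayed; negate for AUC
    met <- computeMetrics(cc, scores = -callTab$score[ok],
                          labels = truth[ok])
    list(confusion = cc, metrics = met)
  }
  perMethod <- list(msd = methodMetrics(callsMsd),
                    se = methodMetrics(callsSe),
                    cnn = methodMetrics(callsCnn))
  metrics <- do.call(rbind, lapply(names(perMethod), function(m)
    cbind(method = m, perMethod[[m]]$metrics)))
  radar <- minmaxRadar(metrics[, c("accuracy", "precision", "recall",
                                   "f1", "mcc", "auc")])
  radar <- cbind(method = metrics$method, radar)

  list(calls = calls,
       confusion = lapply(perMethod, `[[`, "confusion"),
       metrics = metrics, radar = radar, model = model, truth = truth)
}

#' Dose-response quantification with a chosen classifier
#'
#' Simulates a concentration cohort, classifies every
#' (concentration, replicate) cell with the chosen method, computes the
#' percentage of delayed calls per cell, MAD-filters and baseline-corrects
#' the resulting dose table, and fits the Hill equation.
#'
#' @param cohort a [CohortSpec-class].
#' @param simCfg a [SimConfig-class].
#' @param method "msd", "se", "cnn", or "oracle" (ground-truth labels; a
#'   control for the quantification chain itself).
#' @param seed integer seed for cohort simulation.
#' @param p rule parameter object ([MsdParams-class] / [SeParams-class])
#'   for the rule methods.
#' @param model trained [CnnModel-class], required for method "cnn".
#' @return list: \code{table} (conc_nM, replicate, pct_delay, corrected),
#'   \code{summary} (per-concentration mean and SEM), \code{fit}
#'   (a [HillFit-class]), \code{truth} (the simulator's ground-truth
#'   table).
#' @export
runDoseResponse <- function(cohort, simCfg = simConfig(),
                            method = c("msd", "se", "cnn", "oracle"),
                            seed = 1L, p = NULL, model = NULL) {
  method <- match.arg(method)
  if (method == "cnn" && (is.null(model) || !model@trained))
    stop("method 'cnn' requires a trained model")
  sim <- generateDoseResponse(cohort, simCfg, seed)
  rows <- lapply(names(sim$events), function(cell) {
    evs <- sim$events[[cell]]
    meta <- eventMeta(evs[[1]])
    callLabels <- switch(method,
      msd = classifyEvents(evs, "msd", p %||% msdParams())$label,
      se = classifyEvents(evs, "se", p %||% seParams())$label,
      cnn = classifyCnn(model, evs)$label,
      oracle = .labelsOf(evs))
    data.frame(conc_nM = meta$conc_nM, replicate = meta$replicate,
               pct_delay = 100 * mean(callLabels == "delayed", na.rm = TRUE))
  })
  table <- do.call(rbind, rows)
  corrected <- baselineCorrect(table)
  fit <- fitHill(corrected, correct = FALSE)
  list(table = corrected, summary = summarizeDose(corrected, "corrected"),
       fit = fit, truth = sim$truth)
}

#' Resolution sweep of the convolutional classifier
#'
#' Trains one model per input resolution under the same seed policy,
#' evaluates each on the test events, and reports the full metric set per
#' resolution together with its min-max scaling across resolutions (the
#' radar-plot normalization).
#'
#' @param trainEv,valEv,testEv lists of [EventTrace-class] objects.
#' @param resolutions integer vector (>= 2 values) drawn from the
#'   supported set.
#' @param spec base [cnnSpec()]; its inputResolution is overridden.
#' @param cfg a [trainConfig()].
#' @return list: \code{metrics} (one row per resolution), \code{radar}
#'   (min-max scaled), \code{models}.
#' @export
resolutionSweep <- function(trainEv, valEv, testEv, resolutions,
                            spec = cnnSpec(), cfg = trainConfig()) {
  resolutions <- as.integer(resolutions)
  if (length(resolutions) < 2L)
    stop("resolution sweep needs at least two resolutions")
  yTest <- .labelsOf(testEv)
  out <- lapply(resolutions, function(res) {
    sp <- spec
    sp$inputResolution <- res
    sp <- do.call(cnnSpec, sp)
    model <- cnnTrain(renderImages(trainEv, res), .labelsOf(trainEv),
                      renderImages(valEv, res), .labelsOf(valEv),
                      spec = sp, cfg = cfg)
    pred <- cnnPredict(model, renderImages(testEv, res))
    cc <- confusionCounts(yTest, pred$label)
    met <- computeMetrics(cc, scores = pred$p_delayed, labels = yTest)
    list(model = model, metrics = cbind(resolution = res, met))
  })
  metrics <- do.call(rbind, lapply(out, `[[`, "metrics"))
  radar <- minmaxRadar(metrics[, c("accuracy", "precision", "recall",
                                   "f1", "mcc", "auc")])
  radar <- cbind(resolution = metrics$resolution, radar)
  list(metrics = metrics, radar = radar,
       models = lapply(out, `[[`, "model"))
}
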