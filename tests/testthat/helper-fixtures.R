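# Shared fixtures built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixtureLabels <- function(events) vapply(events, eventLabel, character(1))

# A small trained classifier shared by the CNN behavior tests (not by the
# acceptance tests, which train at full scale themselves).
fixtureSmallModel <- function() {
  if (!is.null(.fixtures$model)) return(.fixtures$model)
  cfg <- simConfig()
  tr <- generateDataset(cfg, 150, 150, seed = 201, idPrefix = "fmtr")
  va <- generateDataset(cfg, 40, 40, seed = 202, idPrefix = "fmva")
  te <- generateDataset(cfg, 60, 60, seed = 203, idPrefix = "fmte")
  model <- cnnTrain(renderImages(tr, 56), fixtureLabels(tr),
                    renderImages(va, 56), fixtureLabels(va),
                    spec = cnnSpec(), cfg = trainConfig(epochsMax = 6,
                                                        seed = 77))
  .fixtures$model <- model
  .fixtures$testEvents <- te
  model
}

fixtureTestEvents <- function() {
  fixtureSmallModel()
  .fixtures$testEvents
}
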