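# Shared fixtures. Heavy study-scale runs are computed once per test session
# and cached, so several test blocks can assert on the same experiment.

.pugnnCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.pugnnCache[[key]])) .pugnnCache[[key]] <- force(expr)
  .pugnnCache[[key]]
}

# Desk-scale reference fixture (the default study conditions).
defaultFixture <- function() cached("fixture_default", simulatePUData(synthConfig()))

# Small fixture for fast unit tests of the training protocol.
tinyConfig <- function(seed = 7L) {
  synthConfig(nNodes = 250L, attachM = 2L, moduleSize = 25L,
              nFeatures = 12L, nInformative = 6L, effectSize = 1.5,
              labelFrac = 0.6, nTermsPerCategory = 6L, seed = seed)
}

tinyFixture <- function() cached("fixture_tiny", simulatePUData(tinyConfig()))

# Study-scale cached runs (shared across acceptance blocks).
fixtureModelRun <- function(loss, seed, prior = NULL) {
  if (!is.null(prior) && prior == 0.1) prior <- NULL  # the default prior
  key <- paste0("run_", loss, "_", seed, "_", if (is.null(prior)) "d" else prior)
  cached(key, {
    d <- defaultFixture()
    cfg <- puLossConfig(loss)
    if (!is.null(prior)) cfg$prior <- prior
    runPUModel(d$network, d$features, d$labels, cfg, seed = seed)
  })
}

fixtureBaselineRun <- function(kind, seed) {
  key <- paste0("baseline_", kind, "_", seed)
  cached(key, {
    d <- defaultFixture()
    switch(kind,
      mlp = featureOnlyScores(d$network, d$features, d$labels, seed = seed),
      topo = graphOnlyScores(d$network, d$labels, seed = seed),
      rwr = list(ranking = rwrRanking(d$network, d$labels)))
  })
}

fixtureRecallAt120 <- function(res) {
  d <- defaultFixture()
  recallAtK(res$ranking, nodeIds(d$network)[d$heldOut], 120L)
}
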