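test_that("spy folds partition the positives with balanced remainders", {
  mk <- function(nPos, nNodes) {
    methods::new("LabelSet", positives = seq_len(nPos),
                 unlabeled = seq.int(nPos + 1L, nNodes), nNodes = nNodes)
  }
  folds <- makeFolds(mk(10L, 40L), k = 5L, seed = 1L)
  spies <- lapply(folds, `[[`, "spies")
  expect_true(all(lengths(spies) == 2L))
  expect_equal(sort(unlist(spies)), 1:10)          # disjoint cover
  expect_identical(makeFolds(mk(10L, 40L), k = 5L, seed = 1L), folds)

  folds11 <- makeFolds(mk(11L, 40L), k = 5L, seed = 1L)
  expect_equal(sort(lengths(lapply(folds11, `[[`, "spies")),
                    decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))
  expect_equal(sort(unlist(lapply(folds11, `[[`, "spies"))), 1:11)
  for (f in folds11) {
    expect_length(intersect(f$spies, f$trainPositives), 0L)
    expect_true(all(f$spies %in% f$effectiveUnlabeled))
  }
  expect_error(makeFolds(mk(3L, 10L), k = 5L), "fewer positives")
})

test_that("spy recall uses a strict threshold", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.1)
  expect_equal(spyRecall(scores, spies = 1:5), 0.8)
  expect_equal(spyRecall(scores, spies = 1:4), 1.0)
  expect_equal(spyRecall(rep(0.5, 5), spies = 1:5), 0.0)  # ties not recovered
  expect_error(spyRecall(scores, integer()), "empty")
})

test_that("surrogate F1 combines recall with prior-derived precision", {
  # 20 nodes; spies 1:5, four recovered; only those four cross the threshold
  scores <- c(rep(0.9, 4), rep(0.2, 16))
  expect_equal(surrogateF1(scores, spies = 1:5, prior = 0.1),
               2 * 0.4 * 0.8 / (0.4 + 0.8), tolerance = 1e-12)
  # perfect recovery at exactly prior-sized positive fraction
  scores2 <- c(rep(0.9, 2), rep(0.1, 18))
  expect_equal(surrogateF1(scores2, spies = 1:2, prior = 0.1), 1)
  expect_equal(surrogateF1(rep(0.1, 20), spies = 1:5, prior = 0.1), 0)
})

test_that("consensus ranking weights folds by recall and breaks ties by ID", {
  labels <- methods::new("LabelSet", positives = 3L, unlabeled = c(1L, 2L),
                         nNodes = 3L)
  ids <- c("A", "B", "C")
  f1 <- list(scores = c(0.9, 0.2, 1), spyRecall = 1.0)
  f2 <- list(scores = c(0.6, 0.2, 1), spyRecall = 0.5)
  rk <- consensusRank(list(f1, f2), labels, ids)
  expect_equal(rk$score[rk$node == "A"], (1 * 0.9 + 0.5 * 0.6) / 1.5)
  expect_equal(nrow(rk), 2L)                    # unlabeled only
  # equal recalls: plain mean; single fold: verbatim
  f3 <- list(scores = c(0.4, 0.8, 1), spyRecall = 1.0)
  expect_equal(consensusRank(list(f1, f3), labels, ids)$score,
               sort(c(mean(c(0.9, 0.4)), mean(c(0.2, 0.8))),
                    decreasing = TRUE))
  expect_equal(consensusRank(list(f1), labels, ids)$score, c(0.9, 0.2))
  # ties broken by ascending node ID
  fTie <- list(scores = c(0.7, 0.7, 1), spyRecall = 1)
  expect_equal(consensusRank(list(fTie), labels, ids)$node, c("A", "B"))
  fZero <- list(scores = c(0.1, 0.2, 0.3), spyRecall = 0)
  expect_error(consensusRank(list(fZero), labels, ids), "no informative")
})

test_that("top-k union tracks per-model membership", {
  mkRank <- function(nodes) data.frame(rank = seq_along(nodes), node = nodes,
                                       score = rev(seq_along(nodes)) / 100)
  same <- mkRank(sprintf("P%02d", 1:10))
  u1 <- topKUnion(list(a = same, b = same, c = same, d = same), k = 5L)
  expect_length(u1$union, 5L)
  expect_true(all(u1$membership$nModels == 4L))

  disj <- list(a = mkRank(sprintf("A%02d", 1:5)),
               b = mkRank(sprintf("B%02d", 1:5)),
               c = mkRank(sprintf("C%02d", 1:5)),
               d = mkRank(sprintf("D%02d", 1:5)))
  u2 <- topKUnion(disj, k = 5L)
  expect_length(u2$union, 20L)
  expect_true(all(u2$membership$nModels == 1L))
  expect_error(topKUnion(list(a = mkRank(c("X", "Y"))), k = 5L), "shorter")
})

test_that("recall at K counts targets inside the ranking head", {
  rk <- data.frame(rank = 1:6, node = c("A", "B", "C", "D", "E", "F"),
                   score = 6:1 / 10)
  expect_equal(recallAtK(rk, c("A", "B"), 2), 1)
  expect_equal(recallAtK(rk, c("E", "F"), 2), 0)
  expect_equal(recallAtK(rk, c("A", "F"), 6), 1)
  expect_error(recallAtK(rk, character(), 2), "empty")
})

test_that("early stopping halts after the patience window when recall is flat", {
  d <- tinyFixture()
  sp <- makeFolds(d$labels, seed = 1L)[[1]]
  # zero learning rate: parameters never change, recall constant after epoch 1
  fr <- trainFold(d$network, d$features, sp, puLossConfig("nnpu"),
                  hiddenDims = c(6L, 5L, 4L), lr = 0, patience = 10L,
                  seed = 1L)
  expect_equal(fr$stoppedEpoch, 11L)
  expect_equal(fr$bestEpoch, 1L)
})

test_that("fold training is deterministic and recovers planted spies", {
  d <- tinyFixture()
  sp <- makeFolds(d$labels, seed = 3L)[[2]]
  run <- function() {
    trainFold(d$network, d$features, sp, puLossConfig("nnpu"),
              hiddenDims = c(32L, 16L, 8L), lr = 0.005, maxEpochs = 80L, seed = 5L)
  }
  a <- run(); b <- run()
  expect_identical(a$scores, b$scores)
  expect_identical(a$history, b$history)
  expect_gt(a$spyRecall, 0.5)
  expect_lte(a$stoppedEpoch, 60L)
})

test_that("a one-point sensitivity grid reproduces the plain run", {
  d <- tinyFixture()
  cfg <- puLossConfig("nnpu")
  base <- runPUModel(d$network, d$features, d$labels, cfg, seed = 5L,
                     hiddenDims = c(32L, 16L, 8L), lr = 0.005, maxEpochs = 60L)
  sw <- sensitivitySweep("prior", 0.1, d$network, d$features, d$labels, cfg,
                         seed = 5L, topK = 50L,
                         hiddenDims = c(32L, 16L, 8L), lr = 0.005, maxEpochs = 60L)
  expect_equal(sw$meanRecall, base$meanSpyRecall, tolerance = 1e-12)
  expect_equal(sw$fingerprint,
               paste(sort(head(base$ranking$node, 50L)), collapse = ","))
  # the default spy fraction entry reproduces the base folds exactly
  expect_identical(makeFolds(d$labels, seed = 5L, spyFraction = 0.2),
                   makeFolds(d$labels, seed = 5L))
})
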