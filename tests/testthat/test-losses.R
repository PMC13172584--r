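test_that("pointwise binary cross-entropy matches hand values and clips", {
  expect_equal(pointwiseLoss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(pointwiseLoss(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(pointwiseLoss(1.0, 0, clipEps = 1e-7), -log(1e-7),
               tolerance = 1e-9)
  expect_true(is.finite(pointwiseLoss(0, 1)))
})

test_that("generalized PU risk matches the decomposition by hand", {
  # at uniform 0.5 scores the corrected terms cancel to ln 2 for any prior
  for (prior in c(0.01, 0.1, 0.3, 0.9)) {
    r <- generalizedPURisk(rep(0.5, 4), rep(0.5, 9), prior)
    expect_equal(r$total, log(2), tolerance = 1e-9)
  }
  # prior -> 0 limit: plain unlabeled-as-negative loss
  r0 <- generalizedPURisk(c(0.7, 0.9), c(0.2, 0.4), 0)
  expect_equal(r0$total, mean(-log(1 - c(0.2, 0.4))), tolerance = 1e-12)
  # hand evaluation
  r <- generalizedPURisk(rep(0.8, 3), rep(0.3, 5), 0.1)
  expect_equal(r$total, 0.1 * (-log(0.8)) + (-log(0.7)) - 0.1 * (-log(0.2)),
               tolerance = 1e-12)
  expect_equal(r$total, 0.21804, tolerance = 1e-4)
})

test_that("nnPU clamps the surrogate negative risk at zero", {
  # overfit regime: generalized risk goes negative, nnPU stays >= 0
  gen <- generalizedPURisk(rep(0.99, 3), rep(0.01, 5), 0.5)
  expect_lt(gen$surrogateNegativeRisk, 0)
  expect_lt(gen$total, 0)
  nn <- nnpuLoss(rep(0.99, 3), rep(0.01, 5), 0.5)
  expect_true(nn$correctionApplied)
  expect_equal(nn$total, 0.5 * mean(-log(rep(0.99, 3))), tolerance = 1e-12)
  expect_gte(nn$total, 0)

  # equivalence region: identical to the generalized risk when neg >= 0
  gen2 <- generalizedPURisk(c(0.6, 0.8), c(0.2, 0.3, 0.4), 0.1)
  nn2 <- nnpuLoss(c(0.6, 0.8), c(0.2, 0.3, 0.4), 0.1)
  expect_gte(gen2$surrogateNegativeRisk, 0)
  expect_false(nn2$correctionApplied)
  expect_equal(nn2$total, gen2$total, tolerance = 1e-12)

  # property: nnPU total is nonnegative for random score configurations
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:6, 1)); u <- runif(sample(1:20, 1))
    expect_gte(nnpuLoss(p, u, runif(1, 0.01, 0.9))$total, 0)
  }
})

test_that("Dist-PU combines alignment, entropy and mixup as specified", {
  H <- function(p) -p * log(p) - (1 - p) * log(1 - p)
  r <- distpuLoss(0.9, c(0.2, 0.4), prior = 0.1, lambdaEntropy = 0.1,
                  lambdaMixup = 0)
  expect_equal(r$total, -log(0.9) + 0.2 + 0.1 * mean(c(H(0.2), H(0.4))),
               tolerance = 1e-12)
  expect_equal(r$total, 0.36403, tolerance = 1e-4)

  # alignment term vanishes when the unlabeled mean equals the prior
  rAlign <- distpuLoss(0.9, c(0.05, 0.15), prior = 0.1)
  expect_equal(rAlign$auxiliaryTerms$alignment, 0, tolerance = 1e-12)
  # entropy vanishes at score extremes
  rExt <- distpuLoss(0.9, c(1e-7, 1 - 1e-7), prior = 0.1)
  expect_lt(rExt$auxiliaryTerms$entropy, 1e-5)
  # mixup term
  rMix <- distpuLoss(0.9, 0.3, prior = 0.1, mixedScores = c(0.5, 0.8),
                     mixedTargets = c(0.7, 0.8), lambdaMixup = 0.1)
  expect_equal(rMix$auxiliaryTerms$mixup, mean(c(0.04, 0)), tolerance = 1e-12)
})

test_that("GRAB's dynamic prior is the capped fraction above threshold", {
  expect_equal(grabPrior(c(0.6, 0.7, 0.4, 0.3, 0.2)), 0.05)
  expect_equal(grabPrior(c(rep(0.1, 49), 0.9)), 0.02)
  expect_equal(grabPrior(rep(0.2, 10)), 0.001)
})

test_that("GRAB belief sweep pins positives and averages neighbors", {
  # star graph: center P1 labeled positive, raw scores all 0.5
  star <- makeNet(sprintf("P%d", 1:5),
                  cbind(rep(1, 4), 2:5))
  labels <- methods::new("LabelSet", positives = 1L, unlabeled = 2:5,
                         nNodes = 5L)
  scores <- rep(0.5, 5)
  gl <- grabLoss(scores, labels, star, puLossConfig("grab", grabBeta = 0.5))
  expect_equal(gl$beliefs[1], 1)            # pinned
  expect_equal(gl$beliefs[2:5], rep(0.75, 4), tolerance = 1e-12)

  # beta = 0 reduces to nnPU with the dynamic prior on raw scores
  set.seed(3)
  sc <- runif(5)
  gl0 <- grabLoss(sc, labels, star, puLossConfig("grab", grabBeta = 0))
  piHat <- gl0$risk$auxiliaryTerms$estimatedPrior
  effP <- gl0$risk$auxiliaryTerms$effectivePositives
  effU <- gl0$risk$auxiliaryTerms$effectiveUnlabeled
  expect_equal(gl0$risk$total,
               nnpuLoss(sc[effP], sc[effU], piHat)$total, tolerance = 1e-12)
  # with beta 0 beliefs equal raw scores except the pin
  expect_equal(gl0$beliefs[2:5], sc[2:5], tolerance = 1e-12)
})

test_that("PU-GNN schedules the dual prior and penalizes edge roughness", {
  cfg <- puLossConfig("pugnn", prior = 0.1, warmupPrior = 0.5,
                      warmupEpochs = 20L, lambdaGraph = 0.1)
  sP <- c(0.7, 0.8); sU <- c(0.2, 0.3, 0.4)
  pairs <- cbind(c(0.7, 0.2), c(0.8, 0.4))
  # warm-up epoch uses prior 0.5, main epoch 0.1
  rWarm <- pugnnLoss(sP, sU, pairs, epoch = 0L, cfg)
  rMain <- pugnnLoss(sP, sU, pairs, epoch = 20L, cfg)
  expect_equal(rWarm$auxiliaryTerms$scheduledPrior, 0.5)
  expect_equal(rMain$auxiliaryTerms$scheduledPrior, 0.1)
  smooth <- mean(c(0.01, 0.04))
  expect_equal(rMain$total, nnpuLoss(sP, sU, 0.1)$total + 0.1 * smooth,
               tolerance = 1e-12)
  # lambda 0: exactly nnPU at the scheduled prior
  cfg0 <- puLossConfig("pugnn", lambdaGraph = 0)
  expect_equal(pugnnLoss(sP, sU, pairs, 25L, cfg0)$total,
               nnpuLoss(sP, sU, 0.1)$total, tolerance = 1e-12)
  # equal scores: smoothness term vanishes
  rEq <- pugnnLoss(sP, sU, cbind(c(0.4, 0.4), c(0.4, 0.4)), 25L, cfg)
  expect_equal(rEq$auxiliaryTerms$smoothness, 0)
})

test_that("losses are permutation-invariant within score sets and always finite", {
  set.seed(17)
  sP <- runif(6); sU <- runif(15)
  perm <- sample(15)
  for (prior in c(0.05, 0.3)) {
    expect_equal(nnpuLoss(sample(sP), sU[perm], prior)$total,
                 nnpuLoss(sP, sU, prior)$total, tolerance = 1e-12)
    expect_equal(distpuLoss(sample(sP), sU[perm], prior)$total,
                 distpuLoss(sP, sU, prior)$total, tolerance = 1e-12)
  }
  extreme <- c(0, 1e-12, 0.5, 1 - 1e-12, 1)
  expect_true(is.finite(nnpuLoss(extreme, extreme, 0.1)$total))
  expect_true(is.finite(generalizedPURisk(extreme, extreme, 0.99)$total))
  expect_true(is.finite(distpuLoss(extreme, extreme, 0.5)$total))
})
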