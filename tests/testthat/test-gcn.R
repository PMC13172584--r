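test_that("normalized adjacency matches hand computation and is symmetric", {
  net <- makeNet(c("A", "B"), rbind(c(1, 2)))
  Ahat <- as.matrix(normalizedAdjacency(net))
  expect_equal(Ahat, matrix(0.5, 2, 2), ignore_attr = TRUE)

  d <- tinyFixture()
  Ah <- normalizedAdjacency(d$network)
  expect_true(Matrix::isSymmetric(Ah))
  expect_true(all(Matrix::rowSums(Ah) > 0))
})

test_that("relabeling nodes permutes the operator and the scores consistently", {
  # same abstract graph under two labelings whose sorted orders differ
  e <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4), c(2, 4))
  net1 <- makeNet(c("A", "B", "C", "D"), e)
  # reverse labeling: old index i -> new id so sorted order reverses
  relab <- c("D", "C", "B", "A")
  # node i of net1 is renamed so that net2's canonical order is the reverse
  net2 <- makeNet(sort(relab), cbind(5 - e[, 1], 5 - e[, 2]))
  A1 <- as.matrix(normalizedAdjacency(net1))
  A2 <- as.matrix(normalizedAdjacency(net2))
  expect_equal(A2, A1[4:1, 4:1], ignore_attr = TRUE)

  set.seed(1)
  X1 <- matrix(rnorm(4 * 3), 4, 3)
  params <- initGCN(3, hiddenDims = c(4L, 3L, 2L), dropout = 0, seed = 9L)
  params$wOut <- c(0.7, -0.4)
  s1 <- gcnForward(params, normalizedAdjacency(net1), X1, training = TRUE,
                   updateRunning = FALSE)
  s2 <- gcnForward(params, normalizedAdjacency(net2), X1[4:1, , drop = FALSE],
                   training = TRUE, updateRunning = FALSE)
  expect_equal(s2, s1[4:1], tolerance = 1e-12)
})

test_that("zeroed parameters score every node at 0.5 and inference is deterministic", {
  d <- tinyFixture()
  X <- d$features
  Ahat <- normalizedAdjacency(d$network)
  params <- initGCN(ncol(X), hiddenDims = c(5L, 4L, 3L), seed = 1L)
  zero <- params
  for (l in 1:3) {
    zero$W[[l]][] <- 0; zero$b[[l]][] <- 0; zero$beta[[l]][] <- 0
  }
  zero$wOut[] <- 0; zero$bOut <- 0
  expect_equal(gcnForward(zero, Ahat, X), rep(0.5, nrow(X)))

  s1 <- gcnForward(params, Ahat, X)
  s2 <- gcnForward(params, Ahat, X)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("initialization is seed-deterministic with chained shapes", {
  p1 <- initGCN(3587, hiddenDims = c(256L, 64L, 16L), seed = 42L)
  p2 <- initGCN(3587, hiddenDims = c(256L, 64L, 16L), seed = 42L)
  expect_identical(p1, p2)
  expect_equal(dim(p1$W[[1]]), c(3587L, 256L))
  expect_equal(dim(p1$W[[2]]), c(256L, 64L))
  expect_equal(dim(p1$W[[3]]), c(64L, 16L))
  expect_length(p1$wOut, 16L)
  p3 <- initGCN(3587, hiddenDims = c(256L, 64L, 16L), seed = 43L)
  expect_false(identical(p1$W[[1]], p3$W[[1]]))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- synthConfig(nNodes = 40L, attachM = 2L, moduleSize = 8L,
                     nFeatures = 6L, nInformative = 3L, seed = 7L)
  d <- simulatePUData(cfg)
  X <- d$features
  Ahat <- normalizedAdjacency(d$network)
  pos <- positives(d$labels)
  unl <- unlabeled(d$labels)
  params <- initGCN(ncol(X), hiddenDims = c(5L, 4L, 3L), dropout = 0,
                    seed = 3L)
  params$wOut <- c(0.8, -0.5, 0.3)
  params$bOut <- 0.1
  lossOf <- function(p) {
    s <- gcnForward(p, Ahat, X, training = TRUE, updateRunning = FALSE)
    nnpuLoss(s[pos], s[unl], 0.1)$total
  }
  fw <- gcnForward(params, Ahat, X, training = TRUE, cache = TRUE,
                   updateRunning = FALSE)
  g <- pugnn:::nnpuGradient(fw$scores, pos, unl, 0.1, 1e-7, TRUE)
  grads <- pugnn:::gcnBackward(params, fw$cache, g)

  numGrad <- function(mutate) {
    eps <- 1e-6
    (lossOf(mutate(params, eps)) - lossOf(mutate(params, -eps))) / (2 * eps)
  }
  cases <- list(
    list(a = grads$W[[1]][2, 3],
         m = function(p, e) { p$W[[1]][2, 3] <- p$W[[1]][2, 3] + e; p }),
    list(a = grads$W[[2]][4, 1],
         m = function(p, e) { p$W[[2]][4, 1] <- p$W[[2]][4, 1] + e; p }),
    list(a = grads$W[[3]][1, 2],
         m = function(p, e) { p$W[[3]][1, 2] <- p$W[[3]][1, 2] + e; p }),
    list(a = grads$gamma[[1]][2],
         m = function(p, e) { p$gamma[[1]][2] <- p$gamma[[1]][2] + e; p }),
    list(a = grads$beta[[3]][1],
         m = function(p, e) { p$beta[[3]][1] <- p$beta[[3]][1] + e; p }),
    list(a = grads$wOut[2],
         m = function(p, e) { p$wOut[2] <- p$wOut[2] + e; p }),
    list(a = grads$bOut,
         m = function(p, e) { p$bOut <- p$bOut + e; p }))
  for (cs in cases) {
    n <- numGrad(cs$m)
    expect_lt(abs(cs$a - n) / max(1e-6, abs(n)), 1e-4)
  }
})

test_that("parameters survive a serialization round trip", {
  d <- tinyFixture()
  X <- d$features
  params <- initGCN(ncol(X), hiddenDims = c(6L, 5L, 4L), seed = 11L)
  path <- withr::local_tempfile(fileext = ".json")
  writeGCNModel(params, path)
  back <- readGCNModel(path)
  Ahat <- normalizedAdjacency(d$network)
  expect_equal(gcnForward(back, Ahat, X), gcnForward(params, Ahat, X),
               tolerance = 1e-12)
})
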