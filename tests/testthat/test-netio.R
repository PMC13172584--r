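test_that("confidence filtering is strict, drops self-loops, collapses duplicates", {
  edges <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                      s = c(800, 650, 701))
  net <- loadNetwork(edges, minConfidence = 700)
  expect_equal(nodeIds(net), c("A", "B", "C", "D"))
  expect_equal(numEdges(net), 2L)
  ids <- nodeIds(net)
  got <- apply(edgeMatrix(net), 1, function(r) paste(ids[r], collapse = "-"))
  expect_setequal(got, c("A-B", "C-D"))

  dup <- data.frame(a = c("A", "B"), b = c("B", "A"), s = c(800, 750))
  net2 <- loadNetwork(dup)
  expect_equal(numEdges(net2), 1L)
  expect_equal(edgeWeights(net2), 800L)

  expect_error(loadNetwork(data.frame(a = "A", b = "A", s = 900)),
               "no edges above threshold")
  expect_error(loadNetwork(data.frame(a = "A", b = "B", s = "oops")),
               "malformed")
})

test_that("filtering is permutation-invariant and monotone in the threshold", {
  set.seed(11)
  n <- 40
  edges <- data.frame(a = sprintf("P%02d", sample(n, 150, TRUE)),
                      b = sprintf("P%02d", sample(n, 150, TRUE)),
                      s = sample(0:1000, 150, TRUE))
  edges <- edges[edges$a != edges$b, ]
  net1 <- loadNetwork(edges, 300)
  net2 <- loadNetwork(edges[sample(nrow(edges)), ], 300)
  expect_identical(nodeIds(net1), nodeIds(net2))
  expect_identical(edgeMatrix(net1), edgeMatrix(net2))
  expect_identical(edgeWeights(net1), edgeWeights(net2))

  counts <- vapply(c(0, 200, 400, 600, 800),
                   function(th) numEdges(loadNetwork(edges, th)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("largest connected component keeps the biggest (tie: smallest ID) part", {
  # components of sizes 5 and 3
  net <- makeNet(LETTERS[1:8],
                 rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(6, 7), c(7, 8)))
  lcc <- largestConnectedComponent(net)
  expect_equal(nodeIds(lcc), LETTERS[1:5])
  expect_equal(numEdges(lcc), 4L)

  # already connected: identity
  tri <- makeNet(c("X", "Y", "Z"), rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_identical(nodeIds(largestConnectedComponent(tri)), nodeIds(tri))
  expect_identical(edgeMatrix(largestConnectedComponent(tri)),
                   edgeMatrix(tri))

  # size tie: the component containing the lexicographically smallest ID wins
  tie <- makeNet(c("A1", "B1", "C1", "D1", "E1", "F1"),
                 rbind(c(1, 3), c(3, 5), c(2, 4), c(4, 6)))
  expect_equal(nodeIds(largestConnectedComponent(tie)), c("A1", "C1", "E1"))
})

test_that("edge-list round trip reproduces the network", {
  d <- tinyFixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(d$network, path)
  back <- loadNetwork(readEdgeList(path), minConfidence = 0)
  expect_identical(nodeIds(back), nodeIds(d$network))
  expect_identical(edgeMatrix(back), edgeMatrix(d$network))
  expect_identical(edgeWeights(back), edgeWeights(d$network))
})

test_that("feature alignment reorders to canonical order and checks coverage", {
  net <- makeNet(c("A", "B"), rbind(c(1, 2)))
  tab <- matrix(c(3, 4, 1, 2), 2, 2, byrow = TRUE,
                dimnames = list(c("B", "A"), c("f1", "f2")))
  X <- alignFeatures(net, tab)
  expect_equal(rownames(X), c("A", "B"))
  expect_equal(unname(X[1, ]), c(1, 2))

  # extra rows dropped with a message, missing rows fatal
  tab3 <- rbind(tab, C = c(9, 9))
  expect_message(alignFeatures(net, tab3), "dropping 1")
  net3 <- makeNet(c("A", "B", "C"), rbind(c(1, 2), c(2, 3)))
  expect_error(alignFeatures(net3, tab), "missing")
})

test_that("label sets partition the node indices", {
  net <- makeNet(c("A", "B", "C", "D"), rbind(c(1, 2), c(2, 3), c(3, 4)))
  ls <- makeLabelSet(net, c("B", "D", "ZZZ"))
  expect_equal(positives(ls), c(2L, 4L))
  expect_equal(unlabeled(ls), c(1L, 3L))
  expect_error(makeLabelSet(net, "QQ"), "no positive labels")
})

test_that("GMT files round-trip through the annotation reader", {
  d <- tinyFixture()
  dir <- withr::local_tempdir()
  cats <- categories(d$annotations)
  for (cat in names(cats)) {
    writeGMT(cats[[cat]], file.path(dir, paste0(cat, ".gmt")))
  }
  paths <- file.path(dir, paste0(names(cats), ".gmt"))
  names(paths) <- names(cats)
  back <- readAnnotations(paths)
  for (cat in names(cats)) {
    expect_identical(categories(back)[[cat]], cats[[cat]])
  }
})

test_that("ID mapping is applied to edge endpoints before filtering", {
  dir <- withr::local_tempdir()
  writeLines(c("x1\ty1\t900", "y1\tz1\t800"), file.path(dir, "e.tsv"))
  writeLines(c("x1\tP1", "y1\tP2", "z1\tP3"), file.path(dir, "map.tsv"))
  df <- readEdgeList(file.path(dir, "e.tsv"), file.path(dir, "map.tsv"))
  net <- loadNetwork(df)
  expect_equal(nodeIds(net), c("P1", "P2", "P3"))
})
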