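#' Symmetric-normalized adjacency operator with self-loops
#'
#' Builds the canonical graph-convolution propagation operator
#' \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}}, where \eqn{A} is
#' the unweighted adjacency in canonical node order, \eqn{I} the identity and
#' \eqn{\tilde D} the degree matrix of \eqn{A + I}. Confidence scores are not
#' used: aggregation is unweighted.
#'
#' @param net a connected \linkS4class{PPINetwork}.
#' @return a symmetric sparse \code{Matrix} of dimension nodes x nodes.
#' @export
normalizedAdjacency <- function(net) {
  n <- numNodes(net)
  e <- edgeMatrix(net)
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L], seq_len(n)),
                            j = c(e[, 2L], e[, 1L], seq_len(n)),
                            x = 1, dims = c(n, n))
  d <- Matrix::rowSums(A)
  s <- 1 / sqrt(d)
  Matrix::Diagonal(x = s) %*% A %*% Matrix::Diagonal(x = s)
}

#' Initialize a 3-layer graph-convolutional scorer
#'
#' Architecture: three graph-convolution layers, each followed by batch
#' normalization, ReLU and dropout, then a final fully connected layer with a
#' sigmoid producing one ranking score per node. Features are frozen inputs;
#' the learnable parameters are exactly the three conv layers (weights,
#' biases, batch-norm scale/shift) and the output layer. Weights use uniform
#' fan-scaled (Glorot) initialization, deterministic in \code{seed}.
#'
#' @param nFeatures input feature dimensionality.
#' @param hiddenDims integer triple of layer widths (default \code{c(128, 32,
#'   16)}, tapering toward the scalar output).
#' @param dropout dropout probability in [0, 1), default 0.5.
#' @param seed integer seed for initialization (default 42).
#' @return a parameter list of class \code{gcnParams}.
#' @export
initGCN <- function(nFeatures, hiddenDims = c(128L, 32L, 16L),
                    dropout = 0.5, seed = 42L) {
  stopifnot(length(hiddenDims) == 3L, all(hiddenDims >= 1L),
            dropout >= 0, dropout < 1)
  dims <- c(nFeatures, hiddenDims)
  withr::with_seed(as.integer(seed), {
    glorot <- function(fanIn, fanOut) {
      lim <- sqrt(6 / (fanIn + fanOut))
      matrix(stats::runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
    }
    params <- list(
      W = lapply(1:3, function(l) glorot(dims[l], dims[l + 1L])),
      b = lapply(1:3, function(l) numeric(dims[l + 1L])),
      gamma = lapply(1:3, function(l) rep(1, dims[l + 1L])),
      beta = lapply(1:3, function(l) numeric(dims[l + 1L])),
      runMean = lapply(1:3, function(l) numeric(dims[l + 1L])),
      runVar = lapply(1:3, function(l) rep(1, dims[l + 1L])),
      wOut = as.numeric(glorot(dims[4L], 1L)),
      bOut = 0,
      dropout = dropout, dims = dims,
      bnEps = 1e-5, bnMomentum = 0.1, seed = as.integer(seed)
    )
    class(params) <- "gcnParams"
    params
  })
}

#' @noRd
propagate <- function(Ahat, H) {
  if (is.null(Ahat)) H else as.matrix(Ahat %*% H)
}

#' Forward pass of the graph-convolutional scorer
#'
#' Full-batch evaluation: \eqn{H_0 = X}; for \eqn{l = 1..3},
#' \eqn{H_l = \mathrm{Drop}(\mathrm{ReLU}(\mathrm{BN}(\hat A H_{l-1} W_l +
#' b_l)))}; output \eqn{\sigma(H_3 w + b)}. In training mode batch norm uses
#' batch statistics (and updates running statistics) and dropout is active;
#' at inference batch norm uses running statistics and dropout is off, so
#' inference is deterministic. Passing \code{Ahat = NULL} substitutes the
#' identity operator, degenerating to a pure feature model (used by the
#' feature-only baseline and for mixup virtual nodes, which have no graph
#' position).
#'
#' @param params a \code{gcnParams} list from \code{\link{initGCN}}.
#' @param Ahat the operator from \code{\link{normalizedAdjacency}}, or
#'   \code{NULL} for identity.
#' @param X numeric feature matrix, rows in canonical node order.
#' @param training logical; enables batch statistics and dropout.
#' @param cache logical; if TRUE, returns intermediates for backprop.
#' @param updateRunning logical; update running batch-norm statistics
#'   (training mode only; the trainer disables it for auxiliary passes).
#' @return if \code{cache = FALSE}, the numeric score vector in (0, 1);
#'   otherwise a list with \code{scores}, \code{cache} and \code{params}
#'   (with refreshed running statistics).
#' @export
gcnForward <- function(params, Ahat, X, training = FALSE, cache = FALSE,
                       updateRunning = training) {
  n <- nrow(X)
  keep <- 1 - params$dropout
  H <- X
  cc <- list(layers = vector("list", 3L))
  for (l in 1:3) {
    M <- propagate(Ahat, H)
    Z <- M %*% params$W[[l]]
    Z <- Z + rep(params$b[[l]], each = n)
    dl <- ncol(Z)
    if (training) {
      mu <- .colMeans(Z, n, dl)
      v <- .colMeans(Z * Z, n, dl) - mu * mu   # population variance
      if (updateRunning) {
        mom <- params$bnMomentum
        params$runMean[[l]] <- (1 - mom) * params$runMean[[l]] + mom * mu
        params$runVar[[l]] <- (1 - mom) * params$runVar[[l]] + mom * v
      }
    } else {
      mu <- params$runMean[[l]]
      v <- params$runVar[[l]]
    }
    invStd <- 1 / sqrt(v + params$bnEps)
    # fused affine: Y = gamma * (Z - mu) * invStd + beta
    sc <- params$gamma[[l]] * invStd
    Y <- Z * rep(sc, each = n) +
      rep(params$beta[[l]] - sc * mu, each = n)
    R <- Y * (Y > 0)
    if (training && params$dropout > 0) {
      mask <- matrix(stats::runif(length(R)) < keep, n) / keep
      Hnext <- R * mask
    } else {
      mask <- NULL
      Hnext <- R
    }
    if (cache) {
      cc$layers[[l]] <- list(M = M, Z = Z, mu = mu, invStd = invStd,
                             reluMask = (Y > 0), dropMask = mask)
    }
    H <- Hnext
  }
  z <- as.numeric(H %*% params$wOut) + params$bOut
  s <- 1 / (1 + exp(-z))
  if (any(!is.finite(s))) stop("numerical blow-up in forward pass")
  if (!cache) return(s)
  cc$Hout <- H
  cc$scores <- s
  cc$Ahat <- Ahat
  list(scores = s, cache = cc, params = params)
}

#' @noRd
#' Backward pass: gradient of a scalar loss w.r.t. all trainable parameters,
#' given dL/dscore. Mirrors gcnForward in training mode with batch statistics.
gcnBackward <- function(params, cache, dLds) {
  n <- length(dLds)
  s <- cache$scores
  dz <- dLds * s * (1 - s)
  grads <- list(W = vector("list", 3L), b = vector("list", 3L),
                gamma = vector("list", 3L), beta = vector("list", 3L))
  grads$wOut <- as.numeric(crossprod(cache$Hout, dz))
  grads$bOut <- sum(dz)
  dH <- outer(dz, params$wOut)
  for (l in 3:1) {
    ly <- cache$layers[[l]]
    dl <- length(ly$invStd)
    dR <- if (!is.null(ly$dropMask)) dH * ly$dropMask else dH
    dY <- dR * ly$reluMask
    xhat <- (ly$Z - rep(ly$mu, each = n)) * rep(ly$invStd, each = n)
    dYx <- dY * xhat
    grads$gamma[[l]] <- .colSums(dYx, n, dl)
    grads$beta[[l]] <- .colSums(dY, n, dl)
    g1 <- params$gamma[[l]] * ly$invStd
    dZ <- dY * rep(g1, each = n) -
      rep(g1 * grads$beta[[l]] / n, each = n) -
      xhat * rep(g1 * grads$gamma[[l]] / n, each = n)
    grads$W[[l]] <- crossprod(ly$M, dZ)
    grads$b[[l]] <- .colSums(dZ, n, dl)
    if (l > 1L) {
      dM <- dZ %*% t(params$W[[l]])
      dH <- propagate(cache$Ahat, dM)  # Ahat symmetric
    }
  }
  grads
}

#' @noRd
#' Evaluation forward pass for full-batch training: dropout off, batch norm
#' normalized by the full-graph statistics (in full-batch training the batch
#' is the whole population, so these are the correct inference statistics;
#' the exponential running averages lag the fast-moving early-training
#' statistics and would distort model selection). Running statistics are
#' synced to the full-graph statistics so that a later
#' \code{gcnForward(params, ..., training = FALSE)} reproduces these scores.
gcnEvaluate <- function(params, Ahat, X) {
  n <- nrow(X)
  H <- X
  for (l in 1:3) {
    Z <- propagate(Ahat, H) %*% params$W[[l]]
    Z <- Z + rep(params$b[[l]], each = n)
    dl <- ncol(Z)
    mu <- .colMeans(Z, n, dl)
    v <- .colMeans(Z * Z, n, dl) - mu * mu
    params$runMean[[l]] <- mu
    params$runVar[[l]] <- v
    sc <- params$gamma[[l]] / sqrt(v + params$bnEps)
    Y <- Z * rep(sc, each = n) + rep(params$beta[[l]] - sc * mu, each = n)
    H <- Y * (Y > 0)
  }
  s <- 1 / (1 + exp(-(as.numeric(H %*% params$wOut) + params$bOut)))
  if (any(!is.finite(s))) stop("numerical blow-up in forward pass")
  list(scores = s, params = params)
}

#' Serialize trained parameters to a portable JSON file
#'
#' Flat numeric arrays plus a shape manifest; round-trips exactly via
#' \code{\link{readGCNModel}}.
#'
#' @param params a \code{gcnParams} list.
#' @param path output file.
#' @export
writeGCNModel <- function(params, path) {
  out <- list(
    dims = params$dims, dropout = params$dropout, seed = params$seed,
    bnEps = params$bnEps, bnMomentum = params$bnMomentum,
    W = lapply(params$W, as.numeric), b = params$b,
    gamma = params$gamma, beta = params$beta,
    runMean = params$runMean, runVar = params$runVar,
    wOut = params$wOut, bOut = params$bOut)
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

#' Read parameters written by \code{\link{writeGCNModel}}
#' @param path JSON file.
#' @return a \code{gcnParams} list.
#' @export
readGCNModel <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(raw$dims)
  params <- list(
    W = lapply(1:3, function(l) matrix(raw$W[[l]], dims[l], dims[l + 1L])),
    b = lapply(raw$b, as.numeric),
    gamma = lapply(raw$gamma, as.numeric),
    beta = lapply(raw$beta, as.numeric),
    runMean = lapply(raw$runMean, as.numeric),
    runVar = lapply(raw$runVar, as.numeric),
    wOut = as.numeric(raw$wOut), bOut = as.numeric(raw$bOut),
    dropout = raw$dropout, dims = dims, bnEps = raw$bnEps,
    bnMomentum = raw$bnMomentum, seed = as.integer(raw$seed))
  class(params) <- "gcnParams"
  params
}
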