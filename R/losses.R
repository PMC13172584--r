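#' PU loss configuration
#'
#' Bundles the hyperparameters of the four positive-unlabeled objectives.
#' Per-loss prior policy: nnPU and Dist-PU use a fixed class prior of 0.10;
#' the PU-GNN objective uses a dual prior (0.5 during a warm-up phase, 0.1
#' afterwards); GRAB estimates its prior per epoch from the unlabeled scores,
#' capped at 0.05.
#'
#' @param lossName one of \code{"nnpu"}, \code{"distpu"}, \code{"pugnn"},
#'   \code{"grab"}.
#' @param prior class prior \eqn{\pi_p} (main-phase prior for pugnn).
#' @param warmupPrior pugnn prior during warm-up.
#' @param warmupEpochs pugnn warm-up length in epochs.
#' @param grabCap,grabFloor clamp bounds for GRAB's dynamic prior estimate.
#' @param grabBeta neighbor-averaging weight of GRAB's belief sweep.
#' @param clipEps probability clipping for the pointwise loss.
#' @param lambdaGraph weight of pugnn's edge-smoothness term.
#' @param lambdaEntropy,lambdaMixup,mixupAlpha Dist-PU regularizer weights and
#'   the Beta interpolation parameter for mixup.
#' @param defensive logical; when the nnPU surrogate negative risk goes
#'   negative, follow the defensive update direction that shrinks the
#'   violation (TRUE, default) rather than a plain zero-gradient clamp.
#' @return a validated list of class \code{PULossConfig}.
#' @export
puLossConfig <- function(lossName = c("nnpu", "distpu", "pugnn", "grab"),
                         prior = 0.1, warmupPrior = 0.5, warmupEpochs = 20L,
                         grabCap = 0.05, grabFloor = 0.001, grabBeta = 0.5,
                         clipEps = 1e-7, lambdaGraph = 0.1,
                         lambdaEntropy = 0.1, lambdaMixup = 0.1,
                         mixupAlpha = 1.0, defensive = TRUE) {
  lossName <- match.arg(lossName)
  stopifnot(prior > 0, prior < 1, clipEps > 0, clipEps < 0.5,
            grabFloor <= grabCap)
  structure(list(lossName = lossName, prior = prior,
                 warmupPrior = warmupPrior,
                 warmupEpochs = as.integer(warmupEpochs),
                 grabCap = grabCap, grabFloor = grabFloor,
                 grabBeta = grabBeta, clipEps = clipEps,
                 lambdaGraph = lambdaGraph, lambdaEntropy = lambdaEntropy,
                 lambdaMixup = lambdaMixup, mixupAlpha = mixupAlpha,
                 defensive = defensive),
            class = "PULossConfig")
}

#' @noRd
clipProb <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Pointwise binary cross-entropy on clipped scores
#'
#' \eqn{-y \log p - (1-y) \log(1-p)} after clipping \eqn{p} to
#' \eqn{[\epsilon, 1-\epsilon]}; clipping keeps every PU risk finite.
#'
#' @param p score(s) in (0, 1).
#' @param y label 0 or 1 (recycled).
#' @param clipEps clipping constant, default 1e-7.
#' @return numeric loss value(s).
#' @export
pointwiseLoss <- function(p, y, clipEps = 1e-7) {
  p <- clipProb(p, clipEps)
  -y * log(p) - (1 - y) * log(1 - p)
}

#' @noRd
riskBreakdown <- function(positiveRisk, surrogateNegativeRisk,
                          correctionApplied, total, aux = list()) {
  structure(list(positiveRisk = positiveRisk,
                 surrogateNegativeRisk = surrogateNegativeRisk,
                 correctionApplied = correctionApplied,
                 total = total, auxiliaryTerms = aux),
            class = "riskBreakdown")
}

#' Generalized (unbiased) PU risk
#'
#' \deqn{R_{PU} = \pi_p E_P[\ell(f,1)] + \{E_U[\ell(f,0)] -
#'   \pi_p E_P[\ell(f,0)]\}}
#' The second bracket is the surrogate negative risk: the unlabeled loss
#' corrected for the hidden positives it contains. It can go negative when the
#' model overfits the positives — the motivation for the nonnegative
#' correction in \code{\link{nnpuLoss}}.
#'
#' @param scoresP scores of labeled positives.
#' @param scoresU scores of unlabeled nodes.
#' @param prior class prior \eqn{\pi_p}.
#' @param clipEps probability clipping.
#' @return a \code{riskBreakdown} list.
#' @export
generalizedPURisk <- function(scoresP, scoresU, prior, clipEps = 1e-7) {
  stopifnot(length(scoresP) > 0, length(scoresU) > 0)
  posRisk <- mean(pointwiseLoss(scoresP, 1, clipEps))
  neg <- mean(pointwiseLoss(scoresU, 0, clipEps)) -
    prior * mean(pointwiseLoss(scoresP, 0, clipEps))
  riskBreakdown(posRisk, neg, FALSE, prior * posRisk + neg)
}

#' Nonnegative PU (nnPU) loss
#'
#' The generalized PU risk with the surrogate negative risk clamped at zero:
#' \eqn{\pi_p E_P[\ell(f,1)] + \max(0, \cdot)}. The clamp prevents the
#' estimator from rewarding overfit models whose corrected negative risk goes
#' negative. The defensive gradient convention (optimize the violation back
#' toward zero when clamped) is handled by the trainer.
#'
#' @inheritParams generalizedPURisk
#' @return a \code{riskBreakdown}; \code{correctionApplied} flags the clamp.
#' @export
nnpuLoss <- function(scoresP, scoresU, prior, clipEps = 1e-7) {
  r <- generalizedPURisk(scoresP, scoresU, prior, clipEps)
  neg <- r$surrogateNegativeRisk
  riskBreakdown(r$positiveRisk, neg, neg < 0,
                prior * r$positiveRisk + max(0, neg))
}

#' @noRd
binaryEntropy <- function(p, eps) {
  p <- clipProb(p, eps)
  -p * log(p) - (1 - p) * log(1 - p)
}

#' Dist-PU loss: label-distribution alignment with consistency regularizers
#'
#' \eqn{E_P[\ell(f,1)] + |E_U[\sigma] - \pi_p| + \lambda_{ent} E_U[H(\sigma)]
#' + \lambda_{mix} E[(\sigma_{mix} - \tilde y)^2]}. The alignment term pulls
#' the mean unlabeled score toward the class prior, entropy minimization
#' sharpens unlabeled predictions, and mixup regularization penalizes
#' deviation of interpolated virtual nodes from their interpolated
#' pseudo-labels (virtual nodes are built by the trainer; pass their scores
#' and pseudo-labels here).
#'
#' @inheritParams generalizedPURisk
#' @param mixedScores scores of mixup virtual nodes (optional).
#' @param mixedTargets their interpolated pseudo-labels (same length).
#' @param lambdaEntropy,lambdaMixup regularizer weights.
#' @return a \code{riskBreakdown}; components recorded in
#'   \code{auxiliaryTerms}.
#' @export
distpuLoss <- function(scoresP, scoresU, prior, mixedScores = NULL,
                       mixedTargets = NULL, lambdaEntropy = 0.1,
                       lambdaMixup = 0.1, clipEps = 1e-7) {
  stopifnot(length(scoresP) > 0, length(scoresU) > 0)
  posRisk <- mean(pointwiseLoss(scoresP, 1, clipEps))
  align <- abs(mean(scoresU) - prior)
  ent <- mean(binaryEntropy(scoresU, clipEps))
  mix <- if (length(mixedScores)) {
    mean((mixedScores - mixedTargets)^2)
  } else 0
  total <- posRisk + align + lambdaEntropy * ent + lambdaMixup * mix
  riskBreakdown(posRisk, align, FALSE, total,
                aux = list(alignment = align, entropy = ent, mixup = mix))
}

#' Dynamic class-prior estimate from unlabeled scores (GRAB)
#'
#' Proportion of unlabeled scores exceeding the 0.5 sigmoid threshold,
#' clamped to \code{[floor, cap]} (cap 0.05 by default; the floor guards
#' degenerate epochs where nothing crosses the threshold).
#'
#' @param scoresU unlabeled scores (or refined beliefs).
#' @param cap upper clamp, default 0.05.
#' @param floor lower clamp, default 0.001.
#' @return the clamped fraction.
#' @export
grabPrior <- function(scoresU, cap = 0.05, floor = 0.001) {
  stopifnot(length(scoresU) > 0)
  min(max(mean(scoresU > 0.5), floor), cap)
}

#' @noRd
#' Row-stochastic neighbor-averaging operator (no self-loops).
rowStochasticAdjacency <- function(net) {
  n <- numNodes(net)
  e <- edgeMatrix(net)
  A <- Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]),
                            j = c(e[, 2L], e[, 1L]),
                            x = 1, dims = c(n, n))
  d <- pmax(Matrix::rowSums(A), 1)
  Matrix::Diagonal(x = 1 / d) %*% A
}

#' GRAB loss: belief-refined labels with a dynamic prior
#'
#' One belief-propagation sweep \eqn{b_i \leftarrow (1-\beta)\sigma(f_i) +
#' \beta\,\mathrm{mean}_{j \in N(i)} b_j} with labeled positives pinned at 1,
#' then a dynamic prior from \code{\link{grabPrior}} on the refined unlabeled
#' beliefs. Unlabeled nodes whose refined belief exceeds 0.5 are treated as
#' provisional positives in the nnPU risk; no assumed prior is required.
#' Beliefs are constants with respect to the model parameters (no gradient
#' flows through the sweep).
#'
#' @param scores full score vector in canonical node order.
#' @param labels a \linkS4class{LabelSet} (training-time effective labels).
#' @param net the \linkS4class{PPINetwork} (or a precomputed row-stochastic
#'   operator via \code{P}).
#' @param cfg a \code{\link{puLossConfig}}.
#' @param beliefState belief vector from the previous epoch; defaults to the
#'   current scores.
#' @param P optional precomputed row-stochastic adjacency.
#' @return list with \code{risk} (a \code{riskBreakdown}; the estimated prior,
#'   provisional-positive count and effective sets in \code{auxiliaryTerms})
#'   and \code{beliefs} (the refined state to carry forward).
#' @export
grabLoss <- function(scores, labels, net, cfg = puLossConfig("grab"),
                     beliefState = NULL, P = NULL) {
  pos <- positives(labels)
  unl <- unlabeled(labels)
  if (is.null(P)) P <- rowStochasticAdjacency(net)
  b <- if (is.null(beliefState)) scores else beliefState
  b[pos] <- 1
  b <- (1 - cfg$grabBeta) * scores + cfg$grabBeta * as.numeric(P %*% b)
  b[pos] <- 1
  piHat <- grabPrior(b[unl], cfg$grabCap, cfg$grabFloor)
  provisional <- unl[b[unl] > 0.5]
  # provisional positives join the positive-side means but remain in the
  # unlabeled means: they gain a prior-weighted upward pull while still
  # feeling the unlabeled-as-negative push, so transient belief errors decay
  # instead of ratcheting
  effP <- c(pos, provisional)
  effU <- unl
  risk <- nnpuLoss(scores[effP], scores[effU], piHat, cfg$clipEps)
  risk$auxiliaryTerms <- c(risk$auxiliaryTerms,
                           list(estimatedPrior = piHat,
                                nProvisional = length(provisional),
                                effectivePositives = effP,
                                effectiveUnlabeled = effU))
  list(risk = risk, beliefs = b)
}

#' PU-GNN loss: nnPU with a dual prior schedule and edge smoothness
#'
#' nnPU under a scheduled prior (\code{warmupPrior} while
#' \code{epoch < warmupEpochs}, then the main prior) plus a graph-smoothness
#' regularizer \eqn{\lambda \, \mathrm{mean}_{(i,j) \in E} (\sigma_i -
#' \sigma_j)^2} that propagates positive signal along interactions.
#'
#' @inheritParams generalizedPURisk
#' @param edgeScorePairs two-column matrix of score pairs, one row per network
#'   edge.
#' @param epoch zero-based training epoch (drives the prior schedule).
#' @param cfg a \code{\link{puLossConfig}}.
#' @return a \code{riskBreakdown}; the scheduled prior and smoothness term are
#'   recorded in \code{auxiliaryTerms}.
#' @export
pugnnLoss <- function(scoresP, scoresU, edgeScorePairs, epoch,
                      cfg = puLossConfig("pugnn")) {
  prior <- if (epoch < cfg$warmupEpochs) cfg$warmupPrior else cfg$prior
  base <- nnpuLoss(scoresP, scoresU, prior, cfg$clipEps)
  smooth <- if (NROW(edgeScorePairs)) {
    mean((edgeScorePairs[, 1L] - edgeScorePairs[, 2L])^2)
  } else 0
  riskBreakdown(base$positiveRisk, base$surrogateNegativeRisk,
                base$correctionApplied,
                base$total + cfg$lambdaGraph * smooth,
                aux = list(scheduledPrior = prior, smoothness = smooth))
}

# ---- gradients w.r.t. scores (used by the trainer) --------------------------

#' @noRd
#' d/dp of pointwiseLoss(p, 1): -1/p inside the clip window, 0 where clipped.
gradBCE1 <- function(p, eps) ifelse(p > eps & p < 1 - eps, -1 / p, 0)

#' @noRd
gradBCE0 <- function(p, eps) ifelse(p > eps & p < 1 - eps, 1 / (1 - p), 0)

#' @noRd
#' Gradient of the nnPU objective w.r.t. the full score vector. Under the
#' defensive convention a clamped epoch descends on the violation -neg.
nnpuGradient <- function(scores, posIdx, unlIdx, prior, clipEps,
                         defensive = TRUE) {
  g <- numeric(length(scores))
  sP <- scores[posIdx]; sU <- scores[unlIdx]
  neg <- mean(pointwiseLoss(sU, 0, clipEps)) -
    prior * mean(pointwiseLoss(sP, 0, clipEps))
  dNegP <- -prior * gradBCE0(sP, clipEps) / length(sP)
  dNegU <- gradBCE0(sU, clipEps) / length(sU)
  if (neg >= 0) {
    g[posIdx] <- prior * gradBCE1(sP, clipEps) / length(sP) + dNegP
    g[unlIdx] <- dNegU
  } else if (defensive) {
    g[posIdx] <- -dNegP
    g[unlIdx] <- -dNegU
  } else {
    g[posIdx] <- prior * gradBCE1(sP, clipEps) / length(sP)
  }
  g
}
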