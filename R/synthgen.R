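#' Synthetic-data configuration
#'
#' Desk-scale surrogate for the real inputs: a connected scale-free-like
#' network with a planted, denser disease module; node features whose mean is
#' shifted on informative columns for true positives; SCAR-style partial
#' labeling of the positives; and per-category annotation sets with one
#' module-carrying signal term each.
#'
#' Defaults define the reference synthetic study conditions: 2,000 nodes grown
#' by preferential attachment with 3 edges per node, a 60-node planted module
#' with one extra intra-module edge per module node, 64 features of which 16
#' are informative with a +1.0 mean shift, 60\% of true positives labeled,
#' seed 42.
#'
#' @param nNodes number of proteins.
#' @param attachM edges added per node during preferential-attachment growth.
#' @param moduleSize number of true-positive (planted-module) nodes.
#' @param rewireIntoModule fraction in [0,1]; \code{ceiling(rewireIntoModule *
#'   moduleSize)} extra uniformly-sampled intra-module edges are added so the
#'   module is denser than background.
#' @param nFeatures feature dimensionality.
#' @param nInformative number of leading feature columns that carry signal.
#' @param effectSize mean shift added to informative columns of true positives.
#' @param labelFrac fraction in (0,1] of true positives that receive labels
#'   (selected completely at random — the SCAR assumption holds by
#'   construction).
#' @param nTermsPerCategory annotation terms emitted per category.
#' @param seed integer master seed; every generator derives its stream from it.
#' @return a validated list of class \code{SynthConfig}.
#' @export
synthConfig <- function(nNodes = 2000L, attachM = 3L, moduleSize = 60L,
                        rewireIntoModule = 1.0, nFeatures = 64L,
                        nInformative = 16L, effectSize = 1.0,
                        labelFrac = 0.6, nTermsPerCategory = 8L,
                        seed = 42L) {
  cfg <- list(nNodes = as.integer(nNodes), attachM = as.integer(attachM),
              moduleSize = as.integer(moduleSize),
              rewireIntoModule = rewireIntoModule,
              nFeatures = as.integer(nFeatures),
              nInformative = as.integer(nInformative),
              effectSize = effectSize, labelFrac = labelFrac,
              nTermsPerCategory = as.integer(nTermsPerCategory),
              seed = as.integer(seed))
  stopifnot(cfg$moduleSize < cfg$nNodes, cfg$nInformative <= cfg$nFeatures,
            cfg$attachM >= 1L, cfg$rewireIntoModule >= 0,
            cfg$rewireIntoModule <= 1, cfg$labelFrac > 0, cfg$labelFrac <= 1)
  class(cfg) <- "SynthConfig"
  cfg
}

#' @noRd
synthIds <- function(n) sprintf("P%05d", seq_len(n))

#' Planted-module node indices for a configuration
#'
#' Deterministic in \code{cfg$seed}; shared by the network, feature and
#' annotation generators so the module is consistent across artifacts.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return sorted integer node indices of the true positives.
#' @export
plantedModule <- function(cfg) {
  withr::with_seed(cfg$seed + 1L,
    sort(sample.int(cfg$nNodes, cfg$moduleSize)))
}

#' Generate a connected scale-free-like network with a planted module
#'
#' Grows a preferential-attachment graph (connected by construction, heavy
#' degree tail as in PPI networks), then adds \code{ceiling(rewireIntoModule *
#' moduleSize)} extra edges sampled uniformly among planted-module node pairs
#' (skipping pairs already present) so the module is cohesive. Node IDs are
#' zero-padded so lexicographic order equals generation order.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return a \linkS4class{PPINetwork}; synthetic edges carry confidence 999.
#' @export
simulateNetwork <- function(cfg) {
  g <- withr::with_seed(cfg$seed,
    igraph::sample_pa(cfg$nNodes, m = cfg$attachM, directed = FALSE))
  e <- igraph::as_edgelist(g, names = FALSE)
  lo <- pmin(e[, 1L], e[, 2L]); hi <- pmax(e[, 1L], e[, 2L])
  keep <- lo != hi
  e <- unique(cbind(lo[keep], hi[keep]))
  mod <- plantedModule(cfg)
  nExtra <- ceiling(cfg$rewireIntoModule * cfg$moduleSize)
  if (nExtra > 0 && cfg$moduleSize >= 2L) {
    pairs <- t(utils::combn(mod, 2L))
    have <- paste0(e[, 1L], "_", e[, 2L])
    avail <- pairs[!(paste0(pairs[, 1L], "_", pairs[, 2L]) %in% have), ,
                   drop = FALSE]
    nExtra <- min(nExtra, nrow(avail))
    if (nExtra > 0) {
      pick <- withr::with_seed(cfg$seed + 2L,
        sample.int(nrow(avail), nExtra))
      e <- rbind(e, avail[pick, , drop = FALSE])
    }
  }
  o <- order(e[, 1L], e[, 2L])
  methods::new("PPINetwork",
    nodeIds = synthIds(cfg$nNodes),
    edges = matrix(as.integer(e[o, ]), ncol = 2L),
    weights = rep(999L, nrow(e)))
}

#' Generate node features with a mean shift on the planted module
#'
#' Background entries are i.i.d. standard normal; the first
#' \code{nInformative} columns of true-positive rows are shifted by
#' \code{+effectSize}. This emulates informative frozen embeddings without
#' claiming any language-model geometry.
#'
#' @param net the \linkS4class{PPINetwork} from \code{\link{simulateNetwork}}.
#' @param cfg the same \code{\link{synthConfig}}.
#' @return list with \code{features} (matrix aligned to \code{nodeIds(net)})
#'   and \code{truePositives} (integer node indices of the planted module).
#' @export
simulateFeatures <- function(net, cfg) {
  stopifnot(numNodes(net) == cfg$nNodes)
  X <- withr::with_seed(cfg$seed + 3L,
    matrix(stats::rnorm(cfg$nNodes * cfg$nFeatures),
           nrow = cfg$nNodes, ncol = cfg$nFeatures))
  mod <- plantedModule(cfg)
  if (cfg$nInformative > 0L) {
    X[mod, seq_len(cfg$nInformative)] <-
      X[mod, seq_len(cfg$nInformative)] + cfg$effectSize
  }
  rownames(X) <- nodeIds(net)
  colnames(X) <- sprintf("f%03d", seq_len(cfg$nFeatures))
  list(features = X, truePositives = mod)
}

#' SCAR labeling of true positives
#'
#' Selects \code{ceiling(labelFrac * |TP|)} true positives via a seeded
#' shuffle — labeled positives are a uniform random subset of the positives,
#' so the selected-completely-at-random assumption underlying the PU losses
#' and spy evaluation holds exactly.
#'
#' @param truePositives integer node indices of all true positives.
#' @param labelFrac fraction in (0, 1].
#' @param nNodes total node count.
#' @param seed integer seed.
#' @return a \linkS4class{LabelSet}; unlabeled = hidden positives plus all
#'   background nodes.
#' @export
labelSCAR <- function(truePositives, labelFrac, nNodes, seed) {
  stopifnot(labelFrac > 0, labelFrac <= 1)
  nLab <- ceiling(labelFrac * length(truePositives))
  lab <- withr::with_seed(as.integer(seed) + 4L,
    sample(truePositives)[seq_len(nLab)])
  if (!length(lab)) stop("labeled set is empty")
  lab <- sort(lab)
  methods::new("LabelSet", positives = as.integer(lab),
               unlabeled = setdiff(seq_len(nNodes), lab),
               nNodes = as.integer(nNodes))
}

#' Generate annotation sets with one module-carrying signal term per category
#'
#' Emits five categories (tissue, GO_BP, GO_MF, GO_CC, pathway). In each, one
#' "signal" term contains the full planted module plus random noise members;
#' the remaining terms are random node subsets whose sizes straddle the
#' background-count retention cap scaled to this network
#' (\code{round(nNodes * 500 / 8300)}), so the enrichment filters have both
#' passing and failing background sizes to act on.
#'
#' @param net the synthetic \linkS4class{PPINetwork}.
#' @param truePositives integer node indices of the planted module.
#' @param cfg the \code{\link{synthConfig}}.
#' @return an \linkS4class{AnnotationSets}.
#' @export
simulateAnnotations <- function(net, truePositives, cfg) {
  ids <- nodeIds(net)
  cats <- c("tissue", "GO_BP", "GO_MF", "GO_CC", "pathway")
  scaledCap <- max(20L, round(cfg$nNodes * 500 / 8300))
  withr::with_seed(cfg$seed + 5L, {
    categories <- list()
    termNames <- character()
    for (ci in seq_along(cats)) {
      sets <- list()
      noise <- sample(setdiff(seq_len(cfg$nNodes), truePositives),
                      max(5L, round(cfg$moduleSize / 3)))
      signalTerm <- sprintf("%s:0001", cats[ci])
      sets[[signalTerm]] <- ids[sort(c(truePositives, noise))]
      termNames[signalTerm] <- paste(cats[ci], "signal term")
      for (ti in seq_len(max(0L, cfg$nTermsPerCategory - 1L))) {
        sz <- if (ti %% 2L == 0L) {
          sample(seq(5L, scaledCap), 1L)
        } else {
          sample(seq(scaledCap + 1L, 2L * scaledCap), 1L)
        }
        term <- sprintf("%s:%04d", cats[ci], ti + 1L)
        sets[[term]] <- ids[sort(sample.int(cfg$nNodes, sz))]
        termNames[term] <- paste(cats[ci], "random term", ti + 1L)
      }
      categories[[cats[ci]]] <- sets
    }
    methods::new("AnnotationSets", categories = categories,
                 termNames = termNames)
  })
}

#' Generate the full synthetic study bundle
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return list with \code{network}, \code{features}, \code{truePositives}
#'   (indices), \code{labels} (\linkS4class{LabelSet}), \code{heldOut}
#'   (true positives without labels — the recovery targets),
#'   \code{annotations}, and the echoed \code{config}.
#' @export
simulatePUData <- function(cfg = synthConfig()) {
  net <- simulateNetwork(cfg)
  fx <- simulateFeatures(net, cfg)
  labels <- labelSCAR(fx$truePositives, cfg$labelFrac, cfg$nNodes, cfg$seed)
  ann <- simulateAnnotations(net, fx$truePositives, cfg)
  list(network = net, features = fx$features,
       truePositives = fx$truePositives, labels = labels,
       heldOut = setdiff(fx$truePositives, positives(labels)),
       annotations = ann, config = cfg)
}

#' Write a synthetic bundle to disk in the package's external formats
#'
#' Writes edges.tsv, features.tsv, labels.txt, truth.txt (held-out true
#' positives), one GMT per annotation category, and config.json.
#'
#' @param data result of \code{\link{simulatePUData}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSyntheticData <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- nodeIds(data$network)
  writeEdgeList(data$network, file.path(dir, "edges.tsv"))
  writeFeatureTable(data$features, file.path(dir, "features.tsv"))
  writeLines(ids[positives(data$labels)], file.path(dir, "labels.txt"))
  writeLines(ids[data$heldOut], file.path(dir, "truth.txt"))
  for (cat in names(categories(data$annotations))) {
    writeGMT(categories(data$annotations)[[cat]],
             file.path(dir, paste0(cat, ".gmt")),
             descriptions = data$annotations@termNames)
  }
  jsonlite::write_json(unclass(data$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
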