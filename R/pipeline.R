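#' Load a pipeline input bundle from a directory
#'
#' Expects \code{edges.tsv} (3-column TSV), \code{features.tsv},
#' \code{labels.txt} and any number of \code{*.gmt} annotation files
#' (category = file name without extension). Applies the confidence filter,
#' extracts the largest connected component, aligns features and maps labels.
#'
#' @param dir input directory.
#' @param minConfidence edge confidence threshold (strict), default 700.
#' @param mappingPath optional ID-harmonization table for the edge list.
#' @return list with \code{network}, \code{features}, \code{labels},
#'   \code{annotations} (or NULL if no GMT files).
#' @export
loadPipelineData <- function(dir, minConfidence = 700, mappingPath = NULL) {
  need <- file.path(dir, c("edges.tsv", "features.tsv", "labels.txt"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stop("missing input file(s): ",
                            paste(missing, collapse = ", "))
  net <- loadNetwork(readEdgeList(need[1L], mappingPath), minConfidence)
  net <- largestConnectedComponent(net)
  X <- alignFeatures(net, readFeatureTable(need[2L]))
  labels <- makeLabelSet(net, readLabels(need[3L]))
  gmts <- list.files(dir, pattern = "\\.gmt$", full.names = TRUE)
  ann <- NULL
  if (length(gmts)) {
    names(gmts) <- sub("\\.gmt$", "", basename(gmts))
    ann <- readAnnotations(gmts)
  }
  list(network = net, features = X, labels = labels, annotations = ann)
}

#' @noRd
writeTSV <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", seed), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
stageLog <- function(stage, seed, verbose = TRUE) {
  if (verbose) {
    message(sprintf("[%s] stage=%s seed=%d",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, seed))
  }
}

#' Run the end-to-end prioritization pipeline
#'
#' Executes, writing each stage's artifacts before the next begins: for each
#' requested PU objective a 5-fold spy cross-validation and recall-weighted
#' consensus ranking; the top-k union across models with per-model membership
#' flags; hypergeometric enrichment of the union against the full network
#' with intersection-based refinement; and a topology report on the refined
#' candidates. All randomness derives from \code{seed}, which is recorded in
#' every output header, so two runs with the same configuration produce
#' byte-identical artifacts.
#'
#' @param data a bundle from \code{\link{loadPipelineData}} or
#'   \code{\link{simulatePUData}}, or a directory path to load from.
#' @param outDir output directory (created if needed).
#' @param losses PU objectives to run; default all four.
#' @param seed run seed, default 42.
#' @param topK per-model retention depth, default 100.
#' @param threshold spy-recovery threshold, default 0.5.
#' @param maxBgCount enrichment background-count cap; \code{NULL} (default)
#'   scales the reference cap of 500-on-8300 to this network's size.
#' @param allowTerms optional enrichment-term allowlist.
#' @param verbose log stage lines to stderr.
#' @param ... passed to \code{\link{runPUModel}} (e.g. \code{hiddenDims},
#'   \code{maxEpochs}).
#' @return invisibly, a list with \code{models}, \code{union},
#'   \code{enrichment}, \code{refined}, \code{topology}, \code{metrics}.
#' @export
runPipeline <- function(data, outDir, losses = c("nnpu", "distpu", "pugnn",
                                                 "grab"),
                        seed = 42L, topK = 100L, threshold = 0.5,
                        maxBgCount = NULL, allowTerms = NULL,
                        verbose = TRUE, ...) {
  if (is.character(data)) data <- loadPipelineData(data)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  net <- data$network
  ids <- nodeIds(net)
  if (is.null(maxBgCount)) maxBgCount <- round(numNodes(net) * 500 / 8300)

  stageLog("adjacency", seed, verbose)
  Ahat <- normalizedAdjacency(net)

  models <- list()
  rankings <- list()
  for (loss in losses) {
    stageLog(paste0("train:", loss), seed, verbose)
    res <- runPUModel(net, data$features, data$labels, puLossConfig(loss),
                      seed = seed, Ahat = Ahat, threshold = threshold, ...)
    models[[loss]] <- res
    rankings[[loss]] <- res$ranking
    hist <- do.call(rbind, lapply(res$folds, function(f) {
      cbind(fold = f$foldId, f$history)
    }))
    writeTSV(hist, file.path(outDir, paste0("history_", loss, ".tsv")), seed)
    writeTSV(res$ranking, file.path(outDir, paste0("ranking_", loss, ".tsv")),
             seed)
  }

  stageLog("union", seed, verbose)
  union <- topKUnion(rankings, k = topK)
  writeTSV(union$membership, file.path(outDir, "union_membership.tsv"), seed)

  metrics <- lapply(models, function(m) {
    list(meanSpyRecall = m$meanSpyRecall, sdSpyRecall = m$sdSpyRecall,
         meanTrainRecall = m$meanTrainRecall,
         meanSurrogateF1 = m$meanSurrogateF1)
  })
  metrics$unionSize <- length(union$union)
  metrics$seed <- seed
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  enrichment <- NULL
  refined <- NULL
  if (!is.null(data$annotations)) {
    stageLog("enrichment", seed, verbose)
    enrichment <- enrichAll(union$union, data$annotations, ids,
                            allowTerms = allowTerms,
                            maxBgCount = maxBgCount)
    writeTSV(enrichment, file.path(outDir, "enrichment.tsv"), seed)
    refined <- refineCandidates(union$union, enrichment, data$annotations)
    writeTSV(data.frame(node = refined$refined),
             file.path(outDir, "refined_candidates.tsv"), seed)
    if (nrow(refined$coverage)) {
      writeTSV(refined$coverage, file.path(outDir, "refined_coverage.tsv"),
               seed)
    }
  }

  stageLog("topology", seed, verbose)
  topoNodes <- if (!is.null(refined) && length(refined$refined)) {
    refined$refined
  } else union$union
  topo <- topologyReport(net, data$labels, topoNodes)
  writeTSV(topo, file.path(outDir, "topology.tsv"), seed)

  invisible(list(models = models, union = union, enrichment = enrichment,
                 refined = refined, topology = topo, metrics = metrics))
}
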